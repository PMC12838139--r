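# shared fixture family + design artefacts, built once per file
fam_d <- generate_family(seed = 11)
aln_d <- codon_aware_align(fam_d$records)
prof_d <- site_profile(aln_d)
wins_d <- hypervariable_windows(prof_d)
cfg_d <- design_config()

test_that("candidates anchor their 3' ends on diagnostic columns", {
  for (sp in c("sp1", "sp3")) {
    cd <- enumerate_candidates(aln_d, sp, windows = wins_d, config = cfg_d,
                               profile = prof_d)
    expect_gt(nrow(cd), 0)
    dsites <- diagnostic_sites(prof_d, sp)
    three_prime_col <- ifelse(cd$orientation == "forward", cd$end, cd$start)
    expect_true(all(three_prime_col %in% dsites))  # strict_terminal default
    # offsets annotation: terminal offset present
    expect_true(all(vapply(strsplit(cd$diagnostic_offsets, ","),
                           function(x) "0" %in% x, logical(1))))
    # all filters honoured
    expect_true(all(cd$tm >= cfg_d$tm_range[1] & cd$tm <= cfg_d$tm_range[2]))
    expect_true(all(cd$gc >= cfg_d$gc_range[1] & cd$gc <= cfg_d$gc_range[2]))
    expect_true(all(cd$nontarget_min_mismatches >=
                      cfg_d$min_nontarget_mismatches))
    expect_true(all(cd$nontarget_3prime_mismatch))
  }
})

test_that("every emitted candidate passes the independent validator (closure)", {
  cd <- enumerate_candidates(aln_d, "sp2", windows = wins_d, config = cfg_d,
                             profile = prof_d)
  expect_gt(nrow(cd), 0)
  ok <- vapply(seq_len(nrow(cd)), function(i) {
    validate_candidate(cd[i, ], aln_d, cfg_d, prof_d)
  }, logical(1))
  expect_true(all(ok))
})

test_that("reverse candidates are the reverse complement of the consensus span", {
  cd <- enumerate_candidates(aln_d, "sp1", windows = wins_d, config = cfg_d,
                             profile = prof_d)
  rev_cd <- cd[cd$orientation == "reverse", ]
  expect_gt(nrow(rev_cd), 0)
  cons <- species_consensus(aln_d)
  cchars <- strsplit(cons$alignment[cons$species == "sp1"], "")[[1]]
  for (i in seq_len(nrow(rev_cd))) {
    span <- paste(cchars[rev_cd$start[i]:rev_cd$end[i]], collapse = "")
    expect_identical(rev_cd$sequence[i], revcomp(span))
  }
})

test_that("specificity profile equals a brute-force per-row comparison", {
  m <- diagprimer:::aln_matrix(aln_d)
  cons <- species_consensus(aln_d)
  cd <- enumerate_candidates(aln_d, "sp4", windows = wins_d, config = cfg_d,
                             profile = prof_d)
  expect_gt(nrow(cd), 0)
  for (i in seq_len(min(nrow(cd), 10))) {
    ref <- strsplit(cd$span_seq[i], "")[[1]]
    span <- cd$start[i]:cd$end[i]
    mm <- vapply(which(aln_d$species != "sp4"), function(r) {
      row <- m[r, span]
      sum(row != ref | !row %in% c("A", "C", "G", "T"))
    }, integer(1))
    expect_equal(cd$nontarget_min_mismatches[i], min(mm))
  }
})

test_that("a primer from a conserved region has zero non-target mismatches", {
  aln <- toy_alignment(rep(c(strrep("ACGT", 10)), 4),
                       species = paste0("s", 1:4))
  cand <- tibble::tibble(target_species = "s1", orientation = "forward",
                         start = 1L, end = 20L,
                         span_seq = substr(strrep("ACGT", 10), 1, 20))
  out <- specificity_profile(cand, aln)
  expect_equal(out$nontarget_min_mismatches, 0L)
  expect_false(out$nontarget_3prime_mismatch)
})

test_that("a target without diagnostic sites yields an empty set with a warning", {
  aln <- toy_alignment(rep(strrep("ACGT", 20), 4), species = paste0("s", 1:4))
  prof <- site_profile(aln)
  expect_warning(
    cd <- enumerate_candidates(aln, "s1", windows = NULL,
                               config = design_config(restrict_to_windows = FALSE),
                               profile = prof),
    "no diagnostic sites")
  expect_equal(nrow(cd), 0L)
})

test_that("pairing respects amplicon range, emits a total order, and caps top_n", {
  cd <- enumerate_candidates(aln_d, "sp1", windows = wins_d, config = cfg_d,
                             profile = prof_d)
  pr <- pair_and_rank(cd, aln_d, cfg_d)
  expect_gt(nrow(pr), 0)
  expect_true(all(pr$amplicon_length >= cfg_d$amplicon_length_range[1] &
                    pr$amplicon_length <= cfg_d$amplicon_length_range[2]))
  expect_true(all(pr$tm_diff <= cfg_d$max_pair_tm_diff))
  expect_true(all(pr$forward_end < pr$reverse_start))
  expect_equal(pr$rank, seq_len(nrow(pr)))
  # permuting candidate input order leaves the ranked output unchanged
  withr::local_seed(8)
  pr2 <- pair_and_rank(cd[sample(nrow(cd)), ], aln_d, cfg_d)
  expect_equal(as.data.frame(pr), as.data.frame(pr2))
  # screening depth
  pr3 <- pair_and_rank(cd, aln_d, cfg_d, top_n = 3)
  expect_lte(nrow(pr3), 3L)
  expect_equal(as.data.frame(pr3), as.data.frame(pr[1:nrow(pr3), ]))
  # empty input
  expect_equal(nrow(pair_and_rank(empty <- cd[0, ], aln_d, cfg_d)), 0L)
})

test_that("a single compatible forward/reverse pair yields exactly one pair", {
  cd <- enumerate_candidates(aln_d, "sp2", windows = wins_d, config = cfg_d,
                             profile = prof_d)
  pr_all <- pair_and_rank(cd, aln_d, cfg_d)
  one <- dplyr::bind_rows(
    cd[cd$orientation == "forward" & cd$start == pr_all$forward_start[1], ][1, ],
    cd[cd$orientation == "reverse" & cd$start == pr_all$reverse_start[1], ][1, ])
  pr <- pair_and_rank(one, aln_d, cfg_d)
  expect_equal(nrow(pr), 1L)
})

test_that("designed pairs amplify their own target once and non-targets never", {
  for (seed in c(11, 12, 13)) {
    fam <- generate_family(seed = seed)
    aln <- codon_aware_align(fam$records)
    prof <- site_profile(aln)
    wins <- hypervariable_windows(prof)
    cons <- species_consensus(aln)
    cons_rec <- tibble::tibble(id = cons$species, species = cons$species,
                               sequence = gsub("-", "", cons$alignment,
                                               fixed = TRUE))
    for (sp in unique(aln$species)) {
      cd <- enumerate_candidates(aln, sp, windows = wins, config = cfg_d,
                                 profile = prof)
      pr <- pair_and_rank(cd, aln, cfg_d, top_n = 3)
      for (k in seq_len(nrow(pr))) {
        amp <- predict_amplicons(pr[k, ], cons_rec)
        on_target <- amp[amp$species == sp, ]
        expect_equal(nrow(on_target), 1L)
        expect_equal(on_target$length, pr$amplicon_length[k])
        expect_equal(nrow(amp[amp$species != sp, ]), 0L)
      }
    }
  }
})

test_that("design config files round-trip with overrides", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "tm_range = 52, 62", "strict_terminal = true",
               "primer_length_range = 20,22"), f)
  cfg <- read_design_config(f)
  expect_equal(cfg$tm_range, c(52, 62))
  expect_true(cfg$strict_terminal)
  expect_equal(cfg$primer_length_range, c(20L, 22L))
  expect_equal(cfg$gc_range, design_config()$gc_range)
  writeLines("nonsense_key = 4", f)
  expect_error(read_design_config(f), "unknown config key")
})
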