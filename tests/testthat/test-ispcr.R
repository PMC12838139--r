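test_that("exact and 3'-mutated primers behave as the extension-block rule demands", {
  withr::local_seed(14)
  tmpl <- rand_dna(300)
  primer <- substr(tmpl, 101, 120)
  sites <- find_binding_sites(primer, tmpl)
  plus <- sites[sites$strand == "+", ]
  expect_gte(nrow(plus), 1L)
  expect_true(any(plus$start == 101 & plus$mismatch_total == 0))
  expect_equal(plus$three_prime_position[plus$start == 101], 120)

  # flip the 3'-terminal base: the block rule abolishes that site
  chars <- strsplit(primer, "")[[1]]
  chars[20] <- setdiff(c("A", "C", "G", "T"), chars[20])[1]
  mut <- paste(chars, collapse = "")
  sites2 <- find_binding_sites(mut, tmpl)
  expect_false(any(sites2$strand == "+" & sites2$start == 101))
})

test_that("binding-site sets equal the naive scan oracle on random fixtures", {
  withr::local_seed(15)
  for (trial in 1:200) {
    tmpl <- rand_dna(sample(60:150, 1),
                     bases = c(rep(c("A", "C", "G", "T"), 8), "N"))
    primer <- rand_dna(sample(10:16, 1))
    mm <- sample(0:4, 1)
    bs <- sample(1:3, 1)
    got <- find_binding_sites(primer, tmpl, max_mismatch = mm,
                              block_size = bs)
    want <- oracle_binding_sites(primer, tmpl, max_mismatch = mm,
                                 block_size = bs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatch_total, want$mismatch_total)
    }
  }
})

test_that("strand symmetry: sites map 1:1 under reverse complement of everything", {
  withr::local_seed(16)
  for (trial in 1:30) {
    tmpl <- rand_dna(120)
    primer <- rand_dna(12)
    s1 <- find_binding_sites(primer, tmpl, max_mismatch = 2)
    s2 <- find_binding_sites(primer, revcomp(tmpl), max_mismatch = 2)
    n <- nchar(tmpl); plen <- nchar(primer)
    # a + site at start s becomes a - site at n - (s + plen - 1) + 1
    plus1 <- sort(s1$start[s1$strand == "+"])
    minus2 <- sort(n - (s2$start[s2$strand == "-"] + plen - 1) + 1)
    expect_equal(plus1, minus2)
    minus1 <- sort(s1$start[s1$strand == "-"])
    plus2 <- sort(n - (s2$start[s2$strand == "+"] + plen - 1) + 1)
    expect_equal(minus1, plus2)
  }
})

test_that("raising max_mismatch never removes a binding site", {
  withr::local_seed(17)
  for (trial in 1:20) {
    tmpl <- rand_dna(150)
    primer <- rand_dna(12)
    keys <- function(mm) {
      s <- find_binding_sites(primer, tmpl, max_mismatch = mm)
      paste(s$strand, s$start)
    }
    expect_true(all(keys(1) %in% keys(2)))
    expect_true(all(keys(2) %in% keys(3)))
    expect_true(all(keys(3) %in% keys(4)))
  }
})

test_that("amplicons are predicted between planted facing binding sites", {
  withr::local_seed(18)
  fwd <- rand_dna(20)
  rev <- rand_dna(20)
  insert_len <- 360  # between the primer footprints
  tmpl_seq <- paste0(rand_dna(50), fwd, rand_dna(insert_len), revcomp(rev),
                     rand_dna(50))
  tmpl <- tibble::tibble(id = "t1", species = "X", sequence = tmpl_seq)
  amp <- predict_amplicons(list(forward = fwd, reverse = rev), tmpl)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 20 + insert_len + 20)
  expect_equal(amp$start, 51)
  # no forward site anywhere -> no amplicon
  amp2 <- predict_amplicons(list(forward = revcomp(fwd), reverse = rev), tmpl)
  expect_equal(nrow(amp2), 0L)
  # scan cap excludes over-long products
  amp3 <- predict_amplicons(list(forward = fwd, reverse = rev), tmpl,
                            max_amplicon_scan = 300)
  expect_equal(nrow(amp3), 0L)
})

test_that("specificity matrix reproduces single, mixture and gradient semantics", {
  fam <- generate_family(seed = 19)
  aln <- codon_aware_align(fam$records)
  prof <- site_profile(aln)
  wins <- hypervariable_windows(prof)
  cfg <- design_config()
  pairs <- dplyr::bind_rows(lapply(unique(aln$species), function(sp) {
    cd <- enumerate_candidates(aln, sp, windows = wins, config = cfg,
                               profile = prof)
    pair_and_rank(cd, aln, cfg, top_n = 1)
  }))
  expect_equal(nrow(pairs), 4L)
  mat <- specificity_matrix(pairs, fam$records)

  singles <- mat[mat$set_type == "single", ]
  expect_true(all(singles$positive ==
                    (singles$template_set == singles$target_species)))
  # "+" mixtures amplify, "-" mixtures never do
  mixes <- mat[mat$set_type == "mixture", ]
  expect_true(all(mixes$positive == mixes$contains_target))
  # every mixture cell is the union of its member single-species cells
  for (i in which(mat$set_type == "mixture")) {
    members <- sub(":.*$", "", strsplit(mat$dose[i], ",")[[1]])
    member_rows <- mat[mat$set_type == "single" &
                         mat$target_species == mat$target_species[i] &
                         mat$template_set %in% members, ]
    expect_equal(mat$positive[i], any(member_rows$positive))
    expect_equal(mat$n_amplicons[i], sum(member_rows$n_amplicons))
  }
  # gradient doses annotate but never flip outcomes
  grads <- mat[grepl("^gradient", mat$template_set), ]
  expect_true(all(grads$positive == grads$contains_target))
})

test_that("primer tables drive validation-only in-silico PCR", {
  fam <- generate_family(seed = 19)
  aln <- codon_aware_align(fam$records)
  prof <- site_profile(aln)
  wins <- hypervariable_windows(prof)
  cfg <- design_config()
  pairs <- dplyr::bind_rows(lapply(unique(aln$species), function(sp) {
    cd <- enumerate_candidates(aln, sp, windows = wins, config = cfg,
                               profile = prof)
    pair_and_rank(cd, aln, cfg, top_n = 1)
  }))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_primer_table(pairs, tsv)
  rows <- read_primer_table(tsv)
  expect_equal(nrow(rows), 8L)
  mat <- specificity_matrix(rows, fam$records)
  singles <- mat[mat$set_type == "single", ]
  expect_true(all(singles$positive ==
                    (singles$template_set == singles$target_species)))
})
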