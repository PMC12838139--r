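rec1 <- function(seq, sp = "X") {
  tibble::tibble(id = paste0(sp, "_1"), species = sp, sequence = seq,
                 frame_offset = 0L)
}

test_that("base composition on forced examples", {
  comp <- base_composition(rec1("ACGT"), by_codon_position = FALSE)
  expect_equal(comp$A_pct, 25)
  expect_equal(comp$T_pct, 25)
  expect_equal(comp$G_pct, 25)
  expect_equal(comp$C_pct, 25)
  expect_equal(comp$GC_pct, 50)

  comp2 <- base_composition(rec1("AAATTT"))
  for (p in c("pos1", "pos2", "pos3")) {
    row <- comp2[comp2$position == p, ]
    expect_equal(row$A_pct, 50)
    expect_equal(row$T_pct, 50)
    expect_equal(row$counted_bases, 2L)
  }
})

test_that("percentages sum to 100 and positional rows recombine to the all row", {
  withr::local_seed(21)
  recs <- tibble::tibble(id = paste0("r", 1:3), species = paste0("S", 1:3),
                         sequence = vapply(c(301, 300, 302), rand_dna,
                                           character(1)),
                         frame_offset = c(0L, 1L, 2L))
  comp <- base_composition(recs)
  expect_true(all(abs(comp$A_pct + comp$T_pct + comp$G_pct + comp$C_pct -
                        100) < 1e-9))
  for (sp in unique(comp$species)) {
    sub <- comp[comp$species == sp, ]
    all_row <- sub[sub$position == "all", ]
    pos <- sub[sub$position != "all", ]
    expect_equal(sum(pos$counted_bases), all_row$counted_bases)
    for (b in c("A_pct", "T_pct", "G_pct", "C_pct")) {
      expect_equal(sum(pos[[b]] * pos$counted_bases) / all_row$counted_bases,
                   all_row[[b]])
    }
  }
})

test_that("ambiguity codes are excluded from numerator and denominator", {
  comp <- base_composition(rec1("ACGTNNNN"), by_codon_position = FALSE)
  expect_equal(comp$counted_bases, 4L)
  expect_equal(comp$A_pct, 25)
})

test_that("composition converges to generating frequencies at large n", {
  withr::local_seed(31)
  probs <- c(A = 0.35, C = 0.15, G = 0.12, T = 0.38)
  seq <- paste(sample(names(probs), 1e5, replace = TRUE, prob = probs),
               collapse = "")
  comp <- base_composition(rec1(seq), by_codon_position = FALSE)
  expect_lt(abs(comp$A_pct - 35), 0.5)
  expect_lt(abs(comp$T_pct - 38), 0.5)
  expect_lt(abs(comp$G_pct - 12), 0.5)
})

test_that("p-distance on forced examples", {
  aln <- toy_alignment(c("ACGTACGT", "ACGTACGT"), species = c("a", "b"))
  pd <- p_distance_matrix(aln)
  expect_equal(pd$p[pd$a == "a" & pd$b == "b"], 0)

  aln2 <- toy_alignment(c("ACGTACGT", "ACGTACGA"), species = c("a", "b"))
  pd2 <- p_distance_matrix(aln2)
  expect_equal(pd2$p[pd2$a == "a" & pd2$b == "b"], 1 / 8)
  expect_equal(pd2$n_sites[pd2$a == "a" & pd2$b == "b"], 8L)
})

test_that("pairwise deletion drops gaps and ambiguity codes per pair", {
  aln <- toy_alignment(c("ACGTACGT", "-CGTACGA", "NCGTACGT"),
                       species = c("a", "b", "c"))
  pd <- p_distance_matrix(aln, collapse = "per_record")
  m <- as.matrix(pd)
  expect_equal(pd$n_sites[pd$a == "r1" & pd$b == "r2"], 7L)
  expect_equal(m["r1", "r2"], 1 / 7)
  expect_equal(m["r1", "r3"], 0)
  # a pair with nothing comparable is an error naming the pair
  aln2 <- toy_alignment(c("AAAA", "NNNN"), species = c("a", "b"))
  expect_error(p_distance_matrix(aln2, collapse = "per_record"),
               "comparable")
})

test_that("species consensus uses majority rule with ties as N", {
  aln <- toy_alignment(c("AAAT", "AATT", "CCCC"),
                       species = c("x", "x", "y"))
  cons <- species_consensus(aln)
  # column 3 is an A/T tie within species x -> N; columns 1, 2, 4 majority
  expect_equal(unname(cons$alignment[cons$species == "x"]), "AANT")
  # consensus collapse yields one row per species; the N column is deleted
  # pairwise, so x vs y compares 3 sites, all mismatching
  pd <- p_distance_matrix(aln, collapse = "per_species_consensus")
  expect_equal(attr(pd, "labels"), c("x", "y"))
  expect_equal(as.matrix(pd)["x", "y"], 1)
  expect_equal(pd$n_sites[pd$a == "x" & pd$b == "y"], 3L)
})

test_that("p-distance is symmetric with zero diagonal and revcomp-invariant", {
  withr::local_seed(77)
  for (trial in 1:1000) {
    n <- sample(3:5, 1)
    len <- sample(c(12L, 24L), 1)
    rows <- vapply(seq_len(n), function(i) {
      rand_dna(len, bases = c("A", "C", "G", "T", "N"))
    }, character(1))
    aln <- toy_alignment(rows, species = paste0("s", seq_len(n)))
    pd <- tryCatch(p_distance_matrix(aln, collapse = "per_record"),
                   error = function(e) NULL)
    if (is.null(pd)) next  # pair with no comparable sites
    m <- as.matrix(pd)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
    # reverse-complementing every row leaves all pairwise p unchanged
    rc <- toy_alignment(revcomp(rows), species = paste0("s", seq_len(n)))
    m2 <- as.matrix(p_distance_matrix(rc, collapse = "per_record"))
    expect_equal(m, m2)
  }
})

test_that("tidy and glance summarise distance results", {
  fam <- generate_family(seed = 2)
  pd <- p_distance_matrix(as_alignment(fam$records))
  td <- tidy(pd)
  expect_equal(nrow(td), 6L)  # unordered pairs of 4 taxa, no self-pairs
  gl <- glance(pd)
  expect_equal(gl$n_taxa, 4L)
  expect_true(gl$min_p <= gl$mean_p && gl$mean_p <= gl$max_p)
})
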