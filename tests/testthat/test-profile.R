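# a 4 x 12 toy family where column 6 is diagnostic for the target species
toy4 <- function() {
  toy_alignment(c("ACGTACATACGT",
                  "ACGTACGTACGT",
                  "ACGTACGTACGT",
                  "ACGTACGTACGT"),
                species = c("target", "o1", "o2", "o3"))
}

test_that("identical rows produce zero polymorphic columns", {
  aln <- toy_alignment(rep("ACGTACGTACGT", 4))
  prof <- site_profile(aln)
  expect_equal(sum(prof$is_polymorphic), 0L)
  expect_true(all(is.na(prof$diagnostic_for)))
  expect_length(diagnostic_sites(prof, "s1"), 0L)
})

test_that("a one-species-differs column is called diagnostic for that species", {
  prof <- site_profile(toy4())
  expect_equal(which(!is.na(prof$diagnostic_for)), 7L)  # A vs G at col 7
  expect_equal(prof$diagnostic_for[7], "target")
  expect_equal(diagnostic_sites(prof, "target"), 7L)
  expect_length(diagnostic_sites(prof, "o1"), 0L)
  # per-column counts always sum to the number of rows
  expect_true(all(prof$n_A + prof$n_C + prof$n_G + prof$n_T +
                    prof$n_gap + prof$n_ambig == 4L))
})

test_that("three distinct bases in one column are polymorphic but not diagnostic", {
  aln <- toy_alignment(c("AAAA", "AAAA", "AGAA", "ATAA"),
                       species = c("s1", "s2", "s3", "s4"))
  prof <- site_profile(aln)
  expect_true(prof$is_polymorphic[2])
  expect_true(is.na(prof$diagnostic_for[2]))
})

test_that("gap or ambiguity in a column blocks a diagnostic call", {
  aln <- toy_alignment(c("TCGA", "ACGA", "ACGA", "ACG-"),
                       species = paste0("s", 1:4))
  prof <- site_profile(aln)
  expect_equal(prof$diagnostic_for[1], "s1")
  expect_true(prof$has_gap_or_ambig[4])
  aln2 <- toy_alignment(c("TCGA", "NCGA", "ACGA", "ACGA"),
                        species = paste0("s", 1:4))
  expect_true(is.na(site_profile(aln2)$diagnostic_for[1]))
})

test_that("diagnostic calls are disjoint across species and match planted truth", {
  fam <- generate_family(seed = 9, target_p = 0)
  prof <- site_profile(as_alignment(
    fam$records |> dplyr::rename(alignment = "sequence")))
  per_sp <- lapply(unique(fam$records$species),
                   function(s) diagnostic_sites(prof, s))
  expect_equal(anyDuplicated(unlist(per_sp)), 0L)
  # with no background divergence the calls equal the planted truth exactly
  got <- sort(unlist(per_sp))
  expect_equal(got, sort(fam$truth$column))
  for (s in unique(fam$truth$species)) {
    expect_equal(diagnostic_sites(prof, s),
                 sort(fam$truth$column[fam$truth$species == s]))
  }
  expect_error(diagnostic_sites(prof, "nope"), "available")
})

test_that("window scan finds, merges and ranks dense intervals", {
  # polymorphism only between columns 601 and 1300
  base <- strrep("ACGT", 400)          # 1600 columns
  r2 <- strsplit(base, "")[[1]]
  poly_cols <- seq(601, 1300, by = 2)
  r2[poly_cols] <- ifelse(r2[poly_cols] == "A", "G", "A")
  aln <- toy_alignment(c(base, paste(r2, collapse = ""), base, base),
                       species = paste0("s", 1:4))
  prof <- site_profile(aln)
  wins <- hypervariable_windows(prof, window = 100, step = 50,
                                min_density = 0.25)
  expect_equal(nrow(wins), 1L)
  expect_lte(wins$start, 601)
  expect_gte(wins$end, 1300)
  expect_equal(wins$width, wins$end - wins$start + 1L)

  # no polymorphism at all
  prof0 <- site_profile(toy_alignment(rep(base, 3)))
  expect_equal(nrow(hypervariable_windows(prof0, 100, 50, 0.01)), 0L)
  expect_error(hypervariable_windows(prof0, window = 1e6), "wider")
})

test_that("window densities are invariant under row permutation", {
  fam <- generate_family(seed = 5)
  aln <- as_alignment(fam$records |> dplyr::rename(alignment = "sequence"))
  w1 <- hypervariable_windows(site_profile(aln))
  perm <- aln[c(3, 1, 4, 2), ]
  w2 <- hypervariable_windows(site_profile(as_alignment(perm)))
  expect_equal(as.data.frame(w1), as.data.frame(w2))
})
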