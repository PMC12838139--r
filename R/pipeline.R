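pkg_version <- function() {
  as.character(utils::packageVersion("diagprimer"))
}

report_header <- function(seed = NA, config = NULL) {
  c(sprintf("tool=diagprimer version=%s", pkg_version()),
    sprintf("seed=%s", ifelse(is.na(seed), "NA", as.character(seed))),
    sprintf("config_hash=%s", rlang::hash(config)))
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Sequence characterization: composition and p-distance reports
#'
#' Reads a species-labelled FASTA, computes base composition (overall and
#' per codon position) and the uncorrected p-distance matrix on the
#' codon-aware alignment, and writes `composition.tsv` and `distances.tsv`
#' (square matrix) to `out_dir`. Outputs are byte-identical across reruns
#' on the same inputs.
#'
#' @param fasta path to the input FASTA.
#' @param out_dir output directory (created if missing).
#' @param collapse distance collapse mode, see [p_distance_matrix()].
#' @return invisibly, `list(composition, distances, alignment)`.
#' @export
run_stats <- function(fasta, out_dir,
                      collapse = "per_species_consensus") {
  records <- read_fasta(fasta)
  ensure_dir(out_dir)
  comp <- base_composition(records, by_codon_position = TRUE)
  aln <- codon_aware_align(records)
  dist <- p_distance_matrix(aln, collapse = collapse)
  hdr <- report_header(config = list(collapse = collapse))
  write_report_tsv(comp, file.path(out_dir, "composition.tsv"), hdr)
  dm <- as.matrix(dist)
  sq <- data.frame(species = rownames(dm), dm, check.names = FALSE)
  write_report_tsv(sq, file.path(out_dir, "distances.tsv"), hdr)
  invisible(list(composition = comp, distances = dist, alignment = aln))
}

#' Design species-specific primer pairs for every species
#'
#' Full design pipeline: codon-aware alignment, site profile, hypervariable
#' windows, candidate enumeration and pair ranking per species. Writes
#' `aligned.fasta`, `windows.tsv`, `candidates.tsv`, `pairs.tsv` and
#' `primers.tsv` (primer-table schema) to `out_dir`. Species without
#' diagnostic sites yield no rows (with a warning), not an error.
#'
#' @param fasta path to the input FASTA.
#' @param out_dir output directory.
#' @param config a `design_config` or a path to a key-value config file.
#' @param top_n pairs retained per species (the screening depth).
#' @param window,step,min_density window-scan parameters, see
#'   [hypervariable_windows()].
#' @return invisibly, `list(alignment, profile, windows, candidates,
#'   pairs)`.
#' @export
run_design <- function(fasta, out_dir, config = design_config(),
                       top_n = 3L, window = 100L, step = 10L,
                       min_density = 0.15) {
  if (is.character(config)) config <- read_design_config(config)
  records <- read_fasta(fasta)
  ensure_dir(out_dir)
  aln <- codon_aware_align(records)
  prof <- site_profile(aln)
  wins <- hypervariable_windows(prof, window = window, step = step,
                                min_density = min_density)
  cands <- list(); pairs <- list()
  for (sp in unique(aln$species)) {
    cd <- enumerate_candidates(aln, sp, windows = wins, config = config,
                               profile = prof)
    cands[[sp]] <- cd
    pairs[[sp]] <- pair_and_rank(cd, aln, config = config, top_n = top_n)
  }
  all_cands <- bind_rows(cands)
  all_pairs <- bind_rows(pairs)
  hdr <- report_header(config = config)
  write_alignment(aln, file.path(out_dir, "aligned.fasta"))
  write_report_tsv(wins, file.path(out_dir, "windows.tsv"), hdr)
  write_report_tsv(all_cands, file.path(out_dir, "candidates.tsv"), hdr)
  write_report_tsv(all_pairs, file.path(out_dir, "pairs.tsv"), hdr)
  write_primer_table(all_pairs, file.path(out_dir, "primers.tsv"))
  invisible(list(alignment = aln, profile = prof, windows = wins,
                 candidates = all_cands, pairs = all_pairs))
}

#' In-silico PCR validation of a primer table against templates
#'
#' Validation-only entry point: takes a primer table (TSV) and template
#' FASTA, predicts amplicons for every pair on every template, and builds
#' the single-species / mock-community specificity matrix. Writes
#' `amplicons.tsv` (one row per predicted amplicon) and `matrix.tsv` to
#' `out_dir`.
#'
#' @param primer_tsv path to a primer table, see [read_primer_table()].
#' @param fasta path to template FASTA (species-labelled).
#' @param out_dir output directory.
#' @param max_mismatch,block_size,max_amplicon_scan see
#'   [find_binding_sites()] and [predict_amplicons()].
#' @return invisibly, `list(amplicons, matrix)`.
#' @export
run_ispcr <- function(primer_tsv, fasta, out_dir, max_mismatch = 3L,
                      block_size = 2L, max_amplicon_scan = 3000L) {
  primers <- read_primer_table(primer_tsv)
  if (nrow(primers) == 0L) abort("primer table is empty")
  templates <- read_fasta(fasta)
  ensure_dir(out_dir)
  pairs <- normalise_pairs(primers)
  amps <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- predict_amplicons(pairs[k, ], templates, max_mismatch, block_size,
                           max_amplicon_scan)
    if (nrow(a)) a$target_species <- pairs$target_species[k]
    amps[[k]] <- a
  }
  amps <- bind_rows(amps)
  mat <- specificity_matrix(pairs, templates, max_mismatch = max_mismatch,
                            block_size = block_size,
                            max_amplicon_scan = max_amplicon_scan)
  hdr <- report_header(config = list(max_mismatch = max_mismatch,
                                     block_size = block_size,
                                     max_amplicon_scan = max_amplicon_scan))
  write_report_tsv(amps, file.path(out_dir, "amplicons.tsv"), hdr)
  write_report_tsv(mat, file.path(out_dir, "matrix.tsv"), hdr)
  invisible(list(amplicons = amps, matrix = mat))
}

#' Simulate a synthetic marker family to disk
#'
#' Wraps [generate_family()] and writes `family.fasta` plus the planted
#' diagnostic ground truth `truth.tsv` to `out_dir`. Identical arguments
#' (including `seed`) produce byte-identical files.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param ... passed to [generate_family()].
#' @return invisibly, the `generate_family()` result.
#' @export
run_simulate <- function(out_dir, seed = 1L, ...) {
  fam <- generate_family(seed = seed, ...)
  ensure_dir(out_dir)
  write_fasta(fam$records, file.path(out_dir, "family.fasta"))
  write_report_tsv(fam$truth, file.path(out_dir, "truth.tsv"),
                   report_header(seed = seed, config = list(...)))
  invisible(fam)
}
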