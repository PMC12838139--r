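#' Primer design constraints
#'
#' Collects the tunable constraints used by [enumerate_candidates()] and
#' [pair_and_rank()]. Defaults implement the four classic design principles
#' for species-specific assays on a divergent coding marker: place primers
#' in the most variable regions, keep amplicons in a gel-resolvable
#' 550-800 bp range, avoid spans homologous to non-target species, and
#' screen out hairpin/dimer-prone oligos, with the added requirement that a
#' primer's 3'-terminal base sits on a species-diagnostic site.
#'
#' @param primer_length_range integer `c(min, max)` primer length in nt.
#' @param amplicon_length_range integer `c(min, max)` product length in nt.
#' @param tm_range numeric `c(min, max)` melting temperature in deg C.
#' @param max_pair_tm_diff maximum Tm difference within a pair, deg C.
#' @param gc_range numeric `c(min, max)` GC percentage.
#' @param diagnostic_3prime_window nt from the 3' end that must contain at
#'   least one diagnostic site.
#' @param strict_terminal logical; require the 3'-terminal base itself to be
#'   diagnostic.
#' @param min_nontarget_mismatches minimum full-length mismatches against
#'   every non-target row.
#' @param max_hairpin,max_self_dimer,max_cross_dimer structure-score
#'   ceilings (match-run heuristics, see [structure_scores()]).
#' @param monovalent_salt_mM,primer_conc_nM Tm model conditions.
#' @param restrict_to_windows logical; only design inside hypervariable
#'   windows.
#' @param max_amplicon_scan in-silico PCR scan limit in nt.
#' @param w_tm,w_diag,w_mm,w_struct composite-score weights: Tm closeness
#'   to the range midpoint, 3'-window diagnostic-site count (both primers),
#'   worst-case non-target mismatches, and structure-score penalty.
#' @return a `design_config` list.
#' @export
design_config <- function(primer_length_range = c(18L, 24L),
                          amplicon_length_range = c(550L, 800L),
                          tm_range = c(55, 65),
                          max_pair_tm_diff = 3,
                          gc_range = c(35, 65),
                          diagnostic_3prime_window = 5L,
                          strict_terminal = TRUE,
                          min_nontarget_mismatches = 2L,
                          max_hairpin = 4L,
                          max_self_dimer = 8L,
                          max_cross_dimer = 8L,
                          monovalent_salt_mM = 50,
                          primer_conc_nM = 500,
                          restrict_to_windows = TRUE,
                          max_amplicon_scan = 3000L,
                          w_tm = 1, w_diag = 2, w_mm = 1, w_struct = 0.5) {
  cfg <- list(primer_length_range = as.integer(primer_length_range),
              amplicon_length_range = as.integer(amplicon_length_range),
              tm_range = tm_range, max_pair_tm_diff = max_pair_tm_diff,
              gc_range = gc_range,
              diagnostic_3prime_window = as.integer(diagnostic_3prime_window),
              strict_terminal = isTRUE(strict_terminal),
              min_nontarget_mismatches = as.integer(min_nontarget_mismatches),
              max_hairpin = as.integer(max_hairpin),
              max_self_dimer = as.integer(max_self_dimer),
              max_cross_dimer = as.integer(max_cross_dimer),
              monovalent_salt_mM = monovalent_salt_mM,
              primer_conc_nM = primer_conc_nM,
              restrict_to_windows = isTRUE(restrict_to_windows),
              max_amplicon_scan = as.integer(max_amplicon_scan),
              w_tm = w_tm, w_diag = w_diag, w_mm = w_mm, w_struct = w_struct)
  for (f in c("primer_length_range", "amplicon_length_range", "tm_range",
              "gc_range")) {
    if (length(cfg[[f]]) != 2L || diff(cfg[[f]]) < 0) {
      abort(paste0(f, " must be an ordered c(min, max)"))
    }
  }
  structure(cfg, class = "design_config")
}

#' Read a design configuration from a key-value file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and blank
#' lines ignored. Two-element ranges are comma-separated. Unknown keys are
#' an error; omitted keys keep their defaults.
#'
#' @param path file path.
#' @return a `design_config`.
#' @export
read_design_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- design_config()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", perl = TRUE)[[1]]
    if (length(kv) < 2L) abort(paste0("cannot parse config line: ", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (!key %in% names(defaults)) {
      abort(paste0("unknown config key '", key, "'"))
    }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    args[[key]] <- if (!anyNA(num)) num else as.logical(toupper(parts))
  }
  do.call(design_config, args)
}

gc_percent <- function(sequence) {
  chars <- seq_chars(sequence)
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Non-target specificity profile of a primer candidate
#'
#' Compares the primer's template-sense sequence (the target consensus over
#' its alignment span) with every non-target row over the same columns and
#' records the worst case: the minimum total mismatch count and whether
#' every non-target row shows at least one mismatch inside the candidate's
#' 3'-terminal window. Gaps and ambiguity codes in a non-target row count
#' as mismatches.
#'
#' @param candidate one-row candidate tibble (from
#'   [enumerate_candidates()]), needing `target_species`, `orientation`,
#'   `start`, `end` and the template-sense span sequence in `span_seq`.
#' @param alignment the `codon_alignment` the candidate was designed on.
#' @param config a `design_config` (for the 3'-window width).
#' @return the candidate row with `nontarget_min_mismatches` and
#'   `nontarget_3prime_mismatch` filled in.
#' @export
specificity_profile <- function(candidate, alignment,
                                config = design_config()) {
  m <- aln_matrix(alignment)
  w <- config$diagnostic_3prime_window
  span <- candidate$start:candidate$end
  ref <- seq_chars(candidate$span_seq)
  w3 <- min(w, length(span))
  block_idx <- if (candidate$orientation == "forward") {
    (length(span) - w3 + 1L):length(span)
  } else {
    1:w3
  }
  non_rows <- which(alignment$species != candidate$target_species)
  mm_tot <- integer(0); mm_blk <- logical(0)
  for (r in non_rows) {
    row <- m[r, span]
    bad <- row != ref | !row %in% UNAMBIGUOUS
    mm_tot <- c(mm_tot, sum(bad))
    mm_blk <- c(mm_blk, any(bad[block_idx]))
  }
  candidate$nontarget_min_mismatches <- min(mm_tot)
  candidate$nontarget_3prime_mismatch <- all(mm_blk)
  candidate
}

#' Enumerate species-specific primer candidates
#'
#' Slides every allowed primer length over the target species' consensus
#' inside the hypervariable windows (or the whole alignment when
#' `restrict_to_windows = FALSE`), in both orientations, and keeps spans
#' that are gap-free and unambiguous, satisfy the 3'-terminal diagnostic
#' requirement, and pass the Tm, GC, structure and non-target-specificity
#' filters in `config`. A target with no diagnostic sites yields an empty
#' set with a warning.
#'
#' @param alignment a `codon_alignment`.
#' @param target species label to design for.
#' @param windows a `window_score` tibble from [hypervariable_windows()];
#'   required unless `config$restrict_to_windows` is `FALSE`.
#' @param config a `design_config`.
#' @param profile optional precomputed [site_profile()] of `alignment`.
#' @return a `primer_candidates` tibble, one row per passing candidate:
#'   sequence (5'->3' on the primer's own strand), orientation, alignment
#'   span, Tm, GC, diagnostic 3'-offsets, structure scores and non-target
#'   mismatch fields.
#' @export
enumerate_candidates <- function(alignment, target, windows = NULL,
                                 config = design_config(), profile = NULL) {
  if (!target %in% alignment$species) {
    abort(paste0("unknown species '", target, "'; available: ",
                 paste(unique(alignment$species), collapse = ", ")))
  }
  profile <- profile %||% site_profile(alignment)
  nc <- nrow(profile)
  dsites <- diagnostic_sites(profile, target)
  if (!length(dsites)) {
    warn(paste0("no diagnostic sites for species '", target, "'"))
    return(empty_candidates())
  }
  if (config$restrict_to_windows) {
    if (is.null(windows) || nrow(windows) == 0L) {
      abort("windows are required when restrict_to_windows = TRUE")
    }
    in_window <- rep(FALSE, nc)
    for (i in seq_len(nrow(windows))) {
      in_window[windows$start[i]:windows$end[i]] <- TRUE
    }
  } else {
    in_window <- rep(TRUE, nc)
  }
  cons <- species_consensus(alignment)
  cchars <- seq_chars(cons$alignment[cons$species == target])
  usable <- cchars %in% UNAMBIGUOUS & in_window
  is_diag <- rep(FALSE, nc); is_diag[dsites] <- TRUE
  w <- config$diagnostic_3prime_window
  lens <- config$primer_length_range[1]:config$primer_length_range[2]

  out <- list()
  for (L in lens) {
    for (s in seq_len(nc - L + 1L)) {
      e <- s + L - 1L
      if (!all(usable[s:e])) next
      for (orient in c("forward", "reverse")) {
        # 3' end sits at the right edge for forward primers, left for reverse
        d_off <- if (orient == "forward") e - dsites else dsites - s
        d_off <- sort(d_off[d_off >= 0L & d_off < L])
        if (config$strict_terminal) {
          if (!length(d_off) || d_off[1] != 0L) next
        } else {
          if (!length(d_off) || d_off[1] >= w) next
        }
        span_seq <- paste0(cchars[s:e], collapse = "")
        pseq <- if (orient == "forward") span_seq else revcomp(span_seq)
        gc <- gc_percent(pseq)
        if (gc < config$gc_range[1] || gc > config$gc_range[2]) next
        tm <- melting_temperature(pseq, config$monovalent_salt_mM,
                                  config$primer_conc_nM)
        if (tm < config$tm_range[1] || tm > config$tm_range[2]) next
        st <- structure_scores(pseq)
        if (st[["hairpin"]] > config$max_hairpin ||
            st[["self_dimer"]] > config$max_self_dimer) next
        cand <- tibble(target_species = target, orientation = orient,
                       sequence = pseq, span_seq = span_seq,
                       start = s, end = e, length = L,
                       tm = tm, gc = gc,
                       hairpin_score = st[["hairpin"]],
                       self_dimer_score = st[["self_dimer"]],
                       diagnostic_offsets = paste(d_off, collapse = ","),
                       n_diag_3prime = sum(d_off < w))
        cand <- specificity_profile(cand, alignment, config)
        if (cand$nontarget_min_mismatches < config$min_nontarget_mismatches) next
        if (!cand$nontarget_3prime_mismatch) next
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  if (!length(out)) return(empty_candidates())
  structure(bind_rows(out) |> arrange(.data$start, .data$length,
                                      .data$orientation),
            class = c("primer_candidates", class(tibble())))
}

empty_candidates <- function() {
  structure(
    tibble(target_species = character(), orientation = character(),
           sequence = character(), span_seq = character(),
           start = integer(), end = integer(), length = integer(),
           tm = numeric(), gc = numeric(),
           hairpin_score = integer(), self_dimer_score = integer(),
           diagnostic_offsets = character(), n_diag_3prime = integer(),
           nontarget_min_mismatches = integer(),
           nontarget_3prime_mismatch = logical()),
    class = c("primer_candidates", class(tibble())))
}

#' Validate one candidate against the design constraints
#'
#' Independent re-check of every constraint [enumerate_candidates()]
#' enforces; used to assert closure of the enumeration.
#'
#' @param candidate one-row `primer_candidates` tibble.
#' @param alignment,config,profile as in [enumerate_candidates()].
#' @return `TRUE` when every constraint holds, else `FALSE`.
#' @export
validate_candidate <- function(candidate, alignment,
                               config = design_config(), profile = NULL) {
  profile <- profile %||% site_profile(alignment)
  L <- nchar(candidate$sequence)
  if (L < config$primer_length_range[1] ||
      L > config$primer_length_range[2]) return(FALSE)
  tm <- melting_temperature(candidate$sequence, config$monovalent_salt_mM,
                            config$primer_conc_nM)
  if (tm < config$tm_range[1] || tm > config$tm_range[2]) return(FALSE)
  gc <- gc_percent(candidate$sequence)
  if (gc < config$gc_range[1] || gc > config$gc_range[2]) return(FALSE)
  st <- structure_scores(candidate$sequence)
  if (st[["hairpin"]] > config$max_hairpin ||
      st[["self_dimer"]] > config$max_self_dimer) return(FALSE)
  dsites <- diagnostic_sites(profile, candidate$target_species)
  d_off <- if (candidate$orientation == "forward") {
    candidate$end - dsites
  } else {
    dsites - candidate$start
  }
  d_off <- d_off[d_off >= 0L & d_off < L]
  ok3 <- if (config$strict_terminal) any(d_off == 0L) else
    any(d_off < config$diagnostic_3prime_window)
  if (!ok3) return(FALSE)
  prof <- specificity_profile(candidate, alignment, config)
  prof$nontarget_min_mismatches >= config$min_nontarget_mismatches &&
    prof$nontarget_3prime_mismatch
}

#' Pair, score and rank primer candidates
#'
#' Forms every forward x reverse combination of one species' candidates
#' whose predicted amplicon (ungapped target-consensus length between the
#' outer primer ends) lies in the configured range, whose Tm difference and
#' cross-dimer score pass, and ranks them by a composite score:
#' `w_tm * closeness(mean Tm, range midpoint) + w_diag * (3'-window
#' diagnostic sites, both primers) + w_mm * worst-case non-target
#' mismatches - w_struct * (hairpin + self-dimer + cross-dimer)`.
#' Ties are broken by ascending amplicon start, then ascending length, so
#' the ranking is a total order independent of input order.
#'
#' @param candidates a `primer_candidates` tibble for a single target
#'   species.
#' @param alignment the `codon_alignment` designed on.
#' @param config a `design_config`.
#' @param top_n keep at most this many pairs (default all).
#' @return a `primer_pairs` tibble sorted by rank: primer sequences, spans,
#'   predicted amplicon length, Tm statistics, cross-dimer score,
#'   `composite_score` and `rank`.
#' @export
pair_and_rank <- function(candidates, alignment, config = design_config(),
                          top_n = Inf) {
  if (nrow(candidates) == 0L) return(empty_pairs())
  if (length(unique(candidates$target_species)) != 1L) {
    abort("pair_and_rank takes candidates of a single target species")
  }
  cons <- species_consensus(alignment)
  cchars <- seq_chars(cons$alignment[cons$species ==
                                       candidates$target_species[1]])
  not_gap <- cumsum(cchars != "-")
  fwd <- candidates[candidates$orientation == "forward", ]
  rev <- candidates[candidates$orientation == "reverse", ]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty_pairs())
  tm_mid <- mean(config$tm_range)
  tm_half <- diff(config$tm_range) / 2
  out <- list()
  for (f in seq_len(nrow(fwd))) {
    for (r in seq_len(nrow(rev))) {
      if (fwd$end[f] >= rev$start[r]) next  # forward strictly 5' of reverse
      amp_len <- not_gap[rev$end[r]] - not_gap[fwd$start[f]] + 1L
      if (amp_len < config$amplicon_length_range[1] ||
          amp_len > config$amplicon_length_range[2]) next
      tm_diff <- abs(fwd$tm[f] - rev$tm[r])
      if (tm_diff > config$max_pair_tm_diff) next
      cd <- cross_dimer_score(fwd$sequence[f], rev$sequence[r])
      if (cd > config$max_cross_dimer) next
      mean_tm <- (fwd$tm[f] + rev$tm[r]) / 2
      closeness <- max(0, 1 - abs(mean_tm - tm_mid) / tm_half)
      struct_pen <- fwd$hairpin_score[f] + rev$hairpin_score[r] +
        fwd$self_dimer_score[f] + rev$self_dimer_score[r] + cd
      score <- config$w_tm * closeness +
        config$w_diag * (fwd$n_diag_3prime[f] + rev$n_diag_3prime[r]) +
        config$w_mm * min(fwd$nontarget_min_mismatches[f],
                          rev$nontarget_min_mismatches[r]) -
        config$w_struct * struct_pen
      out[[length(out) + 1L]] <- tibble(
        target_species = fwd$target_species[f],
        forward_seq = fwd$sequence[f], reverse_seq = rev$sequence[r],
        forward_start = fwd$start[f], forward_end = fwd$end[f],
        reverse_start = rev$start[r], reverse_end = rev$end[r],
        amplicon_length = amp_len,
        tm_forward = fwd$tm[f], tm_reverse = rev$tm[r], tm_diff = tm_diff,
        cross_dimer = cd, composite_score = score)
    }
  }
  if (!length(out)) return(empty_pairs())
  res <- bind_rows(out) |>
    arrange(desc(.data$composite_score), .data$forward_start,
            .data$amplicon_length) |>
    mutate(rank = row_number())
  if (is.finite(top_n)) res <- res[seq_len(min(top_n, nrow(res))), ]
  structure(res, class = c("primer_pairs", class(tibble())))
}

empty_pairs <- function() {
  structure(
    tibble(target_species = character(), forward_seq = character(),
           reverse_seq = character(), forward_start = integer(),
           forward_end = integer(), reverse_start = integer(),
           reverse_end = integer(), amplicon_length = integer(),
           tm_forward = numeric(), tm_reverse = numeric(),
           tm_diff = numeric(), cross_dimer = integer(),
           composite_score = numeric(), rank = integer()),
    class = c("primer_pairs", class(tibble())))
}

#' One-row summary of a ranked pair table
#' @param x a `primer_pairs`.
#' @param ... ignored.
#' @return one-row tibble of pair counts and score/length ranges.
#' @method glance primer_pairs
#' @export
glance.primer_pairs <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_species = length(unique(x$target_species)),
         best_score = if (nrow(x)) max(x$composite_score) else NA_real_,
         amplicon_min = if (nrow(x)) min(x$amplicon_length) else NA_integer_,
         amplicon_max = if (nrow(x)) max(x$amplicon_length) else NA_integer_)
}

#' Ranked pair table as a plain tibble
#' @param x a `primer_pairs`.
#' @param ... ignored.
#' @return a tibble.
#' @method tidy primer_pairs
#' @export
tidy.primer_pairs <- function(x, ...) as_tibble(x)
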