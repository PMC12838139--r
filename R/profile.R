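#' Per-column site profile of an alignment
#'
#' Scans every alignment column and reports base counts, polymorphism and
#' species-diagnostic status. A column is *polymorphic* when at least two
#' distinct unambiguous bases occur across the rows. A column is *diagnostic*
#' for a species when (i) no row shows a gap or ambiguity code there, (ii)
#' every row of that species carries one base, (iii) all rows of all other
#' species share a single different base. Columns containing any gap or
#' ambiguity are never called diagnostic.
#'
#' @param alignment a `codon_alignment` (see [codon_aware_align()]).
#' @return a `site_profile` tibble with one row per alignment column:
#'   `column`, `n_A`, `n_C`, `n_G`, `n_T`, `n_gap`, `n_ambig`,
#'   `has_gap_or_ambig`, `is_polymorphic`, `diagnostic_for` (NA when none).
#' @export
site_profile <- function(alignment) {
  m <- aln_matrix(alignment)
  species <- alignment$species
  nc <- ncol(m)
  is_base <- m == "A" | m == "C" | m == "G" | m == "T"
  is_gap <- m == "-"
  n_A <- colSums(m == "A"); n_C <- colSums(m == "C")
  n_G <- colSums(m == "G"); n_T <- colSums(m == "T")
  n_gap <- colSums(is_gap)
  n_ambig <- nrow(m) - (n_A + n_C + n_G + n_T + n_gap)
  has_bad <- n_gap + n_ambig > 0L
  n_distinct_base <- (n_A > 0L) + (n_C > 0L) + (n_G > 0L) + (n_T > 0L)
  is_poly <- n_distinct_base >= 2L

  sp_list <- unique(species)
  diag_for <- rep(NA_character_, nc)
  cand <- which(is_poly & !has_bad)
  for (j in cand) {
    col <- m[, j]
    # one base per species, constant within species
    sp_base <- vapply(sp_list, function(s) {
      b <- unique(col[species == s])
      if (length(b) == 1L) b else NA_character_
    }, character(1))
    if (anyNA(sp_base)) next
    tabs <- table(sp_base)
    if (length(tabs) == 2L && min(tabs) == 1L && length(sp_list) >= 3L) {
      # exactly one species differs from the base shared by all the others
      rare <- names(tabs)[tabs == 1L]
      diag_for[j] <- names(sp_base)[sp_base == rare]
    } else if (length(sp_list) == 2L && length(tabs) == 2L) {
      # two-species alignments: a fixed difference separates both; it is not
      # "one species differs from the rest" so no diagnostic call is made
      diag_for[j] <- NA_character_
    }
  }

  structure(
    tibble(column = seq_len(nc),
           n_A = as.integer(n_A), n_C = as.integer(n_C),
           n_G = as.integer(n_G), n_T = as.integer(n_T),
           n_gap = as.integer(n_gap), n_ambig = as.integer(n_ambig),
           has_gap_or_ambig = unname(has_bad),
           is_polymorphic = unname(is_poly),
           diagnostic_for = diag_for),
    species = sp_list, n_rows = nrow(m),
    class = c("site_profile", class(tibble()))
  )
}

#' Columns diagnostic for one species
#'
#' @param profile a `site_profile`.
#' @param target species label present in the alignment.
#' @return ascending integer vector of 1-based alignment columns at which
#'   `target` carries a base differing from the single base shared by all
#'   other species.
#' @export
diagnostic_sites <- function(profile, target) {
  sp <- attr(profile, "species")
  if (!target %in% sp) {
    abort(paste0("unknown species '", target, "'; available: ",
                 paste(sp, collapse = ", ")))
  }
  sort(profile$column[!is.na(profile$diagnostic_for) &
                        profile$diagnostic_for == target])
}

#' Hypervariable windows of an alignment
#'
#' Slides a fixed-width window along the columns, keeps windows whose density
#' of polymorphic columns reaches `min_density`, merges overlapping keepers
#' and recomputes the density of each merged interval. The defaults recover
#' contiguous polymorphism-rich regions of the scale seen in interspecific
#' barcode comparisons.
#'
#' @param profile a `site_profile`.
#' @param window window width in columns.
#' @param step slide step in columns.
#' @param min_density minimum fraction of polymorphic columns per window.
#' @return a `window_score` tibble with `start`, `end` (1-based inclusive),
#'   `width`, `density`, sorted by decreasing density then increasing start.
#' @export
hypervariable_windows <- function(profile, window = 100L, step = 10L,
                                  min_density = 0.15) {
  nc <- nrow(profile)
  if (window > nc) abort("window is wider than the alignment")
  if (window < 1L || step < 1L) abort("window and step must be >= 1")
  poly <- as.integer(profile$is_polymorphic)
  cs <- c(0L, cumsum(poly))
  starts <- seq(1L, nc - window + 1L, by = step)
  dens <- (cs[starts + window] - cs[starts]) / window
  keep <- which(dens >= min_density)
  if (!length(keep)) {
    return(empty_windows())
  }
  ivals <- tibble(start = starts[keep], end = starts[keep] + window - 1L)
  merged <- merge_overlapping(ivals)
  merged$width <- merged$end - merged$start + 1L
  merged$density <- (cs[merged$end + 1L] - cs[merged$start]) / merged$width
  out <- merged |>
    arrange(desc(.data$density), .data$start) |>
    select("start", "end", "width", "density")
  structure(out, class = c("window_score", class(tibble())))
}

empty_windows <- function() {
  structure(tibble(start = integer(), end = integer(), width = integer(),
                   density = numeric()),
            class = c("window_score", class(tibble())))
}

# merge 1-based inclusive intervals that overlap
merge_overlapping <- function(ivals) {
  ivals <- ivals[order(ivals$start, ivals$end), , drop = FALSE]
  out_start <- ivals$start[1]; out_end <- ivals$end[1]
  res_s <- integer(); res_e <- integer()
  for (i in seq_len(nrow(ivals))[-1]) {
    if (ivals$start[i] <= out_end) {
      out_end <- max(out_end, ivals$end[i])
    } else {
      res_s <- c(res_s, out_start); res_e <- c(res_e, out_end)
      out_start <- ivals$start[i]; out_end <- ivals$end[i]
    }
  }
  tibble(start = c(res_s, out_start), end = c(res_e, out_end))
}
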