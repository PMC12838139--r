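#' Base composition, overall and by codon position
#'
#' Computes A/T/G/C percentages and GC content per species, over all counted
#' bases and (optionally) separately for each codon position. Only
#' unambiguous A/C/G/T count: ambiguity codes are excluded from both the
#' numerator and the denominator. Codon positions are indexed on each
#' ungapped sequence from its `frame_offset` (a trailing partial codon is
#' ignored for the positional rows); alignment columns play no role.
#' When a species has several records their counts are pooled.
#'
#' @param records tibble of sequence records (see [read_fasta()]).
#' @param by_codon_position logical; add `pos1`/`pos2`/`pos3` rows.
#' @return a `composition_table` tibble with columns `species`, `position`
#'   (`all`, `pos1`, `pos2`, `pos3`), `A_pct`, `T_pct`, `G_pct`, `C_pct`,
#'   `GC_pct`, `counted_bases`.
#' @export
#' @examples
#' base_composition(tibble::tibble(id = "x", species = "X",
#'                                 sequence = "ACGT", frame_offset = 0L))
base_composition <- function(records, by_codon_position = TRUE) {
  records <- validate_records(records)
  count_bases <- function(chars) {
    c(A = sum(chars == "A"), T = sum(chars == "T"),
      G = sum(chars == "G"), C = sum(chars == "C"))
  }
  rows <- list()
  for (sp in unique(records$species)) {
    idx <- which(records$species == sp)
    all_counts <- c(A = 0L, T = 0L, G = 0L, C = 0L)
    pos_counts <- list(`1` = all_counts, `2` = all_counts, `3` = all_counts)
    for (i in idx) {
      chars <- seq_chars(records$sequence[i])
      off <- records$frame_offset[i]
      n_codon <- (length(chars) - off) %/% 3L
      if (by_codon_position && n_codon > 0L) {
        for (p in 1:3) {
          at <- off + p + 3L * (seq_len(n_codon) - 1L)
          pos_counts[[p]] <- pos_counts[[p]] + count_bases(chars[at])
        }
        # `all` pools exactly the positionally classed bases so that the
        # three positional denominators sum to the `all` denominator
        counted <- chars[(off + 1L):(off + 3L * n_codon)]
      } else {
        counted <- chars
      }
      all_counts <- all_counts + count_bases(counted)
    }
    mk_row <- function(pos, cnt) {
      tot <- sum(cnt)
      pct <- if (tot > 0) 100 * cnt / tot else rep(NA_real_, 4)
      tibble(species = sp, position = pos,
             A_pct = pct[["A"]], T_pct = pct[["T"]],
             G_pct = pct[["G"]], C_pct = pct[["C"]],
             GC_pct = if (tot > 0) 100 * (cnt[["G"]] + cnt[["C"]]) / tot else NA_real_,
             counted_bases = as.integer(tot))
    }
    rows[[length(rows) + 1L]] <- mk_row("all", all_counts)
    if (by_codon_position) {
      for (p in 1:3) {
        rows[[length(rows) + 1L]] <- mk_row(paste0("pos", p), pos_counts[[p]])
      }
    }
  }
  structure(bind_rows(rows),
            class = c("composition_table", class(tibble())))
}

#' Uncorrected p-distance matrix with pairwise deletion
#'
#' For each pair of rows, p is the fraction of mismatching sites over the
#' sites *comparable* in that pair: both rows must carry an unambiguous
#' non-gap base there (pairwise deletion of gaps, ambiguity codes and Ns).
#' With `collapse = "per_species_consensus"` each species is first collapsed
#' to a majority-rule consensus of its rows (ties become N, hence excluded),
#' yielding one row/column per species.
#'
#' @param alignment a `codon_alignment`.
#' @param collapse `"per_species_consensus"` (default) or `"per_record"`.
#' @return a `p_distance` tibble in long form: `a`, `b`, `p`, `n_sites`
#'   for every unordered pair including self-pairs (p = 0). Use
#'   [as.matrix()] for the square matrix.
#' @export
p_distance_matrix <- function(alignment,
                              collapse = c("per_species_consensus",
                                           "per_record")) {
  collapse <- match.arg(collapse)
  m <- aln_matrix(alignment)
  if (collapse == "per_species_consensus") {
    m <- consensus_matrix(m, alignment$species)
    labels <- rownames(m)
  } else {
    labels <- alignment$id
  }
  if (nrow(m) < 2L) abort("need at least 2 rows for a distance matrix")
  comparable <- matrix(m %in% UNAMBIGUOUS, nrow = nrow(m))
  n <- nrow(m)
  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) next
      ok <- comparable[i, ] & comparable[j, ]
      ns <- sum(ok)
      if (i != j && ns == 0L) {
        abort(paste0("no comparable sites between '", labels[i], "' and '",
                     labels[j], "'"))
      }
      p <- if (i == j) 0 else sum(m[i, ok] != m[j, ok]) / ns
      res[[length(res) + 1L]] <- tibble(a = labels[i], b = labels[j],
                                        p = p, n_sites = as.integer(ns))
    }
  }
  structure(bind_rows(res), labels = labels,
            class = c("p_distance", class(tibble())))
}

# majority-rule consensus per species over an alignment matrix; ties and
# columns with no unambiguous base become N; a gap majority stays a gap
consensus_matrix <- function(m, species) {
  sp_list <- unique(species)
  out <- matrix("N", nrow = length(sp_list), ncol = ncol(m),
                dimnames = list(sp_list, NULL))
  for (s in seq_along(sp_list)) {
    rows <- m[species == sp_list[s], , drop = FALSE]
    out[s, ] <- apply(rows, 2L, function(col) {
      cnt <- table(col[col %in% c(UNAMBIGUOUS, "-")])
      if (!length(cnt)) return("N")
      top <- names(cnt)[cnt == max(cnt)]
      if (length(top) > 1L) "N" else top
    })
  }
  out
}

#' Majority-rule species consensus sequences
#'
#' @param alignment a `codon_alignment`.
#' @return tibble with `species` and gapped consensus `alignment` rows
#'   (ties and all-ambiguous columns are N).
#' @export
species_consensus <- function(alignment) {
  m <- consensus_matrix(aln_matrix(alignment), alignment$species)
  tibble(species = rownames(m),
         alignment = apply(m, 1L, paste0, collapse = ""))
}

#' @export
as.matrix.p_distance <- function(x, ...) {
  labels <- attr(x, "labels")
  out <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  for (k in seq_len(nrow(x))) {
    out[x$a[k], x$b[k]] <- x$p[k]
    out[x$b[k], x$a[k]] <- x$p[k]
  }
  out
}

#' Long tidy form of a p-distance result
#' @param x a `p_distance`.
#' @param ... ignored.
#' @return tibble of off-diagonal pairs.
#' @method tidy p_distance
#' @export
tidy.p_distance <- function(x, ...) {
  x |> filter(.data$a != .data$b) |> as_tibble()
}

#' One-row summary of a p-distance result
#' @param x a `p_distance`.
#' @param ... ignored.
#' @return one-row tibble: `n_taxa`, `min_p`, `max_p`, `mean_p`.
#' @method glance p_distance
#' @export
glance.p_distance <- function(x, ...) {
  off <- x$p[x$a != x$b]
  tibble(n_taxa = length(attr(x, "labels")),
         min_p = min(off), max_p = max(off), mean_p = mean(off))
}

#' One-row summary of a composition table
#' @param x a `composition_table`.
#' @param ... ignored.
#' @return one-row tibble: `n_species`, `min_AT_pct`, `max_GC_pct`.
#' @method glance composition_table
#' @export
glance.composition_table <- function(x, ...) {
  all_rows <- x[x$position == "all", ]
  tibble(n_species = length(unique(x$species)),
         min_AT_pct = min(all_rows$A_pct + all_rows$T_pct),
         max_GC_pct = max(all_rows$GC_pct))
}
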