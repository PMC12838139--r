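#' Codon-aware progressive alignment of coding sequences
#'
#' Aligns protein-coding DNA sequences in codon units, so that indels are
#' whole codons and the reading frame is preserved across the alignment.
#' Pairwise alignment is global (Needleman-Wunsch with affine gaps) over
#' codon units; a codon-vs-codon score is the summed nucleotide identity
#' (+1 match / -1 mismatch per position) and a gap run of k codons costs
#' `gap_open + (k - 1) * gap_extend`. Sequences are joined progressively:
#' the first input record seeds the profile and the remaining records join
#' in order of decreasing pairwise identity to it.
#'
#' A record's leading bases before `frame_offset` and any trailing partial
#' codon are carried as short alignment units so that ungapping any row
#' reproduces its input sequence exactly. For in-frame inputs whose length
#' is a multiple of three, every gap run in the output has a length that is
#' a multiple of three.
#'
#' @param records tibble of sequence records (see [read_fasta()]).
#' @param gap_open,gap_extend per-codon gap penalties on the +1/-1
#'   nucleotide identity scale.
#' @return a `codon_alignment` tibble with columns `id`, `species`,
#'   `alignment` (gapped sequence); the number of alignment columns is in
#'   `attr(, "n_columns")`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   id = c("a", "b"), species = c("A", "B"),
#'   sequence = c("ATGAAACCCGGG", "ATGAAAGGG"), frame_offset = 0L)
#' codon_aware_align(recs)
codon_aware_align <- function(records, gap_open = 8, gap_extend = 2) {
  records <- validate_records(records)
  if (nrow(records) < 2L) abort("need at least 2 records to align")
  units <- lapply(seq_len(nrow(records)), function(i) {
    split_units(records$sequence[i], records$frame_offset[i])
  })
  too_short <- nchar(records$sequence) - records$frame_offset < 3L
  if (any(too_short)) {
    abort(paste0("record(s) shorter than one codon after frame_offset: ",
                 paste(records$id[too_short], collapse = ", ")))
  }

  # guide order: record 1 first, then decreasing nucleotide identity to it
  if (nrow(records) > 2L) {
    idents <- vapply(2:nrow(records), function(i) {
      pairwise_identity(units[[1]], units[[i]], gap_open, gap_extend)
    }, numeric(1))
    ord <- c(1L, (2:nrow(records))[order(-idents)])
  } else {
    ord <- seq_len(nrow(records))
  }

  # profile: matrix of unit strings, rows x unit-columns; gap cells are "-"^w
  prof <- matrix(units[[ord[1]]], nrow = 1L)
  for (k in ord[-1]) {
    prof <- profile_join(prof, units[[k]], gap_open, gap_extend)
  }
  rows <- apply(prof, 1L, paste0, collapse = "")
  out <- tibble(id = records$id[ord], species = records$species[ord],
                alignment = rows)
  # restore input order
  out <- out[match(records$id, out$id), ]
  stopifnot(length(unique(nchar(out$alignment))) == 1L)
  structure(out, n_columns = nchar(out$alignment[1]),
            class = c("codon_alignment", class(tibble())))
}

# split a sequence into codon units from frame_offset; leading offset bases
# and any trailing partial codon become short units
split_units <- function(seq, frame_offset = 0L) {
  n <- nchar(seq)
  out <- character(0)
  if (frame_offset > 0L) out <- substr(seq, 1L, frame_offset)
  starts <- seq(frame_offset + 1L, n, by = 3L)
  ends <- pmin(starts + 2L, n)
  c(out, substring(seq, starts, ends))
}

# score matrix between two unit vectors: +1 identical base / -1 otherwise,
# positions padded to width 3 with '.' (absent vs absent scores 0)
unit_score_matrix <- function(ua, ub) {
  pad <- function(u) {
    w <- nchar(u)
    ifelse(w < 3L, paste0(u, strrep(".", 3L - w)), u)
  }
  ua <- pad(ua); ub <- pad(ub)
  A <- matrix(unlist(strsplit(ua, "", fixed = TRUE)), nrow = 3L)
  B <- matrix(unlist(strsplit(ub, "", fixed = TRUE)), nrow = 3L)
  S <- matrix(0, length(ua), length(ub))
  for (k in 1:3) {
    a <- A[k, ]; b <- B[k, ]
    eq <- outer(a, b, "==")
    real_a <- !a %in% c(".", "-"); real_b <- !b %in% c(".", "-")
    match <- eq & outer(real_a, real_b, "&")
    both_pad <- outer(a == ".", b == ".", "&")
    S <- S + ifelse(match, 1, ifelse(both_pad, 0, -1))
  }
  S
}

# profile score matrix: mean over profile rows of unit scores
profile_score_matrix <- function(prof, ub) {
  S <- matrix(0, ncol(prof), length(ub))
  for (r in seq_len(nrow(prof))) {
    S <- S + unit_score_matrix(prof[r, ], ub)
  }
  S / nrow(prof)
}

# align unit vector `ub` against the profile and merge it in as a new row
profile_join <- function(prof, ub, gap_open, gap_extend) {
  S <- profile_score_matrix(prof, ub)
  al <- .affine_align(S, gap_open, gap_extend)
  a_idx <- al$a_idx; b_idx <- al$b_idx
  ncol_out <- length(a_idx)
  out <- matrix("", nrow = nrow(prof) + 1L, ncol = ncol_out)
  for (c in seq_len(ncol_out)) {
    old <- if (a_idx[c] > 0L) prof[, a_idx[c]] else NULL
    new <- if (b_idx[c] > 0L) ub[b_idx[c]] else NULL
    w <- max(nchar(c(old, new)))
    if (is.null(old)) old <- rep(strrep("-", w), nrow(prof))
    if (is.null(new)) new <- strrep("-", w)
    cell <- c(old, new)
    short <- nchar(cell) < w
    cell[short] <- paste0(cell[short], strrep("-", w - nchar(cell[short])))
    out[, c] <- cell
  }
  out
}

# fraction of identically aligned nucleotides between two unit sequences
pairwise_identity <- function(ua, ub, gap_open, gap_extend) {
  S <- unit_score_matrix(ua, ub)
  al <- .affine_align(S, gap_open, gap_extend)
  matched <- 0L; total <- 0L
  for (c in seq_along(al$a_idx)) {
    if (al$a_idx[c] > 0L && al$b_idx[c] > 0L) {
      a <- seq_chars(ua[al$a_idx[c]]); b <- seq_chars(ub[al$b_idx[c]])
      w <- max(length(a), length(b))
      length(a) <- w; length(b) <- w
      matched <- matched + sum(!is.na(a) & !is.na(b) & a == b)
    }
    total <- total + max(nchar(c(
      if (al$a_idx[c] > 0L) ua[al$a_idx[c]] else NULL,
      if (al$b_idx[c] > 0L) ub[al$b_idx[c]] else NULL)))
  }
  matched / total
}

#' Coerce aligned records to a codon_alignment
#'
#' Wraps an already-aligned set of rows (e.g. read from aligned FASTA with
#' `read_fasta(aligned = TRUE)`) in the alignment container used by the
#' profiling and design functions.
#'
#' @param records tibble with `id`, `species` and gapped sequences in
#'   `sequence` or `alignment`.
#' @return a `codon_alignment` tibble.
#' @export
as_alignment <- function(records) {
  if (!"alignment" %in% colnames(records)) {
    records$alignment <- records$sequence
  }
  lens <- nchar(records$alignment)
  if (length(unique(lens)) != 1L) {
    abort("aligned rows must all have the same length")
  }
  out <- tibble(id = records$id, species = records$species,
                alignment = toupper(records$alignment))
  structure(out, n_columns = lens[1],
            class = c("codon_alignment", class(tibble())))
}

#' Remove gaps from alignment rows
#'
#' @param alignment a `codon_alignment`.
#' @return tibble of ungapped records (`id`, `species`, `sequence`).
#' @export
ungap <- function(alignment) {
  tibble(id = alignment$id, species = alignment$species,
         sequence = gsub("-", "", alignment$alignment, fixed = TRUE),
         frame_offset = 0L)
}

# alignment as a character matrix (rows x columns)
aln_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$alignment, "", fixed = TRUE))
  rownames(m) <- alignment$id
  m
}

#' Write an alignment to aligned FASTA
#'
#' @param alignment a `codon_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  write_fasta(tibble(id = alignment$id, species = alignment$species,
                     sequence = alignment$alignment), path)
}
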