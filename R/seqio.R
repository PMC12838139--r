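#' Read species-labelled DNA sequences from FASTA
#'
#' Parses a (plain or aligned) FASTA file into a tibble of sequence records.
#' The species label of each record is taken from a `species=<label>` token in
#' the header if present, else from `species_map`, else the full header line
#' is used as the label. Sequences are stored uppercase and validated against
#' the IUPAC DNA alphabet; gaps (`-`) are only allowed when `aligned = TRUE`.
#'
#' @param path path to a FASTA file.
#' @param species_map optional named character vector mapping record id to
#'   species label; overrides the full-header fallback but not an explicit
#'   `species=` token.
#' @param aligned logical; allow `-` gap characters (aligned FASTA).
#' @param frame_offset integer 0, 1 or 2: position of the first complete codon
#'   in each record (0 = sequence starts in frame). Recycled to all records.
#' @return a tibble with columns `id`, `species`, `sequence`, `frame_offset`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 species=Fint", "ACGTACGT", ">s2 species=Focc", "ACGTACGA"), fa)
#' read_fasta(fa)
read_fasta <- function(path, species_map = NULL, aligned = FALSE,
                       frame_offset = 0L) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) abort(paste0("no FASTA records in ", path))
  headers <- names(set)
  seqs <- unname(toupper(as.character(set)))
  ids <- sub("\\s.*$", "", headers)
  species <- vapply(seq_along(headers), function(i) {
    m <- regmatches(headers[i], regexpr("species=\\S+", headers[i]))
    if (length(m)) return(sub("^species=", "", m))
    if (!is.null(species_map) && ids[i] %in% names(species_map)) {
      return(unname(species_map[[ids[i]]]))
    }
    headers[i]
  }, character(1))
  allowed <- if (aligned) c(IUPAC_CODES, "-") else IUPAC_CODES
  for (i in seq_along(seqs)) {
    bad <- which(!seq_chars(seqs[i]) %in% allowed)
    if (length(bad)) {
      abort(sprintf(
        "record '%s': invalid character '%s' at sequence position %d (not an IUPAC DNA code%s)",
        ids[i], seq_chars(seqs[i])[bad[1]], bad[1],
        if (aligned) " or gap" else ""))
    }
  }
  records <- tibble(
    id = ids, species = species, sequence = seqs,
    frame_offset = as.integer(rep_len(frame_offset, length(seqs)))
  )
  validate_records(records, aligned = aligned)
  records
}

#' Validate a sequence-record tibble
#'
#' Checks the record invariants: non-empty uppercase IUPAC sequences, unique
#' ids, non-empty species labels, frame offsets in 0..2.
#'
#' @param records tibble with columns `id`, `species`, `sequence` and
#'   optionally `frame_offset`.
#' @param aligned logical; allow gap characters.
#' @return the validated tibble, invisibly (with `frame_offset` filled in).
#' @export
validate_records <- function(records, aligned = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("id", "species", "sequence")
  miss <- setdiff(need, colnames(records))
  if (length(miss)) abort(paste0("missing record columns: ",
                                 paste(miss, collapse = ", ")))
  if (!"frame_offset" %in% colnames(records)) records$frame_offset <- 0L
  if (nrow(records) == 0L) abort("empty record set")
  if (anyDuplicated(records$id)) {
    abort(paste0("duplicate record ids: ",
                 paste(unique(records$id[duplicated(records$id)]), collapse = ", ")))
  }
  if (any(!nzchar(records$species))) abort("empty species label")
  if (any(!nzchar(records$sequence))) abort("empty sequence")
  if (any(!records$frame_offset %in% 0:2)) abort("frame_offset must be 0, 1 or 2")
  allowed <- if (aligned) c(IUPAC_CODES, "-") else IUPAC_CODES
  for (i in seq_len(nrow(records))) {
    s <- toupper(records$sequence[i])
    bad <- which(!seq_chars(s) %in% allowed)
    if (length(bad)) {
      abort(sprintf("record '%s': invalid character '%s' at position %d",
                    records$id[i], seq_chars(s)[bad[1]], bad[1]))
    }
    records$sequence[i] <- s
  }
  invisible(records)
}

#' Write sequence records to FASTA
#'
#' Headers are written as `<id> species=<label>`; sequence lines are wrapped
#' at 60 columns, so `write_fasta(read_fasta(f))` round-trips byte-identically
#' for files using that convention.
#'
#' @param records tibble with `id`, `species`, `sequence`.
#' @param path output file path.
#' @param width line-wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(sprintf(">%s species=%s", records$id[i], records$species[i]),
               con, sep = "\n")
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a primer table (TSV)
#'
#' Expects a tab-separated file with header
#' `name<TAB>species<TAB>orientation<TAB>sequence`. Orientation tokens are
#' normalised to lowercase; only `forward` and `reverse` are accepted.
#' An empty body (header only) yields an empty tibble.
#'
#' @param path path to the TSV file.
#' @return tibble with columns `primer_name`, `target_species`,
#'   `orientation`, `sequence`.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) abort(paste0("primer table not found: ", path))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE)
  need <- c("name", "species", "orientation", "sequence")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    abort(paste0("primer table must have columns name, species, orientation, ",
                 "sequence; missing: ", paste(miss, collapse = ", ")))
  }
  out <- tibble(
    primer_name = tab$name,
    target_species = tab$species,
    orientation = tolower(tab$orientation),
    sequence = toupper(tab$sequence)
  )
  if (nrow(out) == 0L) return(out)
  bad_or <- setdiff(unique(out$orientation), c("forward", "reverse"))
  if (length(bad_or)) {
    abort(paste0("unknown orientation token(s): ",
                 paste(bad_or, collapse = ", "),
                 "; accepted tokens are 'forward' and 'reverse'"))
  }
  if (any(nchar(out$sequence) < 10L)) abort("primer sequences must be >= 10 nt")
  for (i in seq_len(nrow(out))) {
    bad <- which(!seq_chars(out$sequence[i]) %in% IUPAC_CODES)
    if (length(bad)) {
      abort(sprintf("primer '%s': invalid character at position %d",
                    out$primer_name[i], bad[1]))
    }
  }
  out
}

#' Write a primer table (TSV)
#'
#' Inverse of [read_primer_table()]; also accepts the pair table produced by
#' [pair_and_rank()], exporting each pair as two rows (forward and reverse).
#'
#' @param primers tibble with `primer_name`, `target_species`, `orientation`,
#'   `sequence`, or a pair table with `forward_seq`/`reverse_seq` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(primers, path) {
  if (all(c("forward_seq", "reverse_seq") %in% colnames(primers))) {
    primers <- pairs_to_primer_rows(primers)
  }
  out <- data.frame(name = primers$primer_name,
                    species = primers$target_species,
                    orientation = primers$orientation,
                    sequence = primers$sequence)
  write_report_tsv(out, path)
}

# flatten a ranked pair table into primer-table rows (two per pair)
pairs_to_primer_rows <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble(primer_name = character(), target_species = character(),
                  orientation = character(), sequence = character()))
  }
  bind_rows(
    tibble(primer_name = sprintf("%s_r%d_F", pairs$target_species, pairs$rank),
           target_species = pairs$target_species,
           orientation = "forward", sequence = pairs$forward_seq),
    tibble(primer_name = sprintf("%s_r%d_R", pairs$target_species, pairs$rank),
           target_species = pairs$target_species,
           orientation = "reverse", sequence = pairs$reverse_seq)
  ) |> arrange(.data$target_species, .data$primer_name)
}
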