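#' Mismatch-tolerant primer binding sites with a 3'-extension-block rule
#'
#' Scans both strands of a template for positions where the primer can
#' anneal and be extended. A position qualifies when the total number of
#' mismatches does not exceed `max_mismatch` *and* the terminal
#' `block_size` bases at the primer's 3' end match perfectly: a mismatch at
#' or immediately next to the 3' terminus blocks polymerase extension, which
#' is the property species-specific primers with 3'-terminal diagnostic
#' bases exploit. Ambiguous template bases always count as mismatches.
#'
#' @param primer primer sequence 5'->3'.
#' @param template a single sequence record (one-row tibble with `id` and
#'   `sequence`) or a plain character string.
#' @param max_mismatch maximum total mismatches tolerated.
#' @param block_size width in nt of the 3'-terminal block that must match
#'   perfectly.
#' @return tibble of binding sites: `template_id`, `strand` (`+`/`-`),
#'   `start`, `end` (1-based footprint on the + strand),
#'   `three_prime_position`, `mismatch_total`, `mismatches_in_3prime_block`.
#'   On the `+` strand the primer extends rightward from
#'   `three_prime_position`; on the `-` strand leftward.
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 3L,
                               block_size = 2L) {
  if (is.character(template)) {
    template <- tibble(id = "template", sequence = toupper(template))
  }
  stopifnot(nrow(template) == 1L)
  primer <- toupper(primer)
  tch <- seq_chars(toupper(template$sequence))
  n <- length(tch)
  plen <- nchar(primer)
  if (plen > n) abort("primer longer than template")
  t_ok <- tch %in% UNAMBIGUOUS

  scan_strand <- function(pch, block_positions) {
    ns <- n - plen + 1L
    mism <- integer(ns)
    mism_block <- integer(ns)
    for (k in seq_len(plen)) {
      idx <- k:(ns + k - 1L)
      bad <- (tch[idx] != pch[k]) | !t_ok[idx]
      mism <- mism + bad
      if (k %in% block_positions) mism_block <- mism_block + bad
    }
    keep <- which(mism <= max_mismatch & mism_block == 0L)
    list(start = keep, mism = mism[keep], mism_block = mism_block[keep])
  }

  pch <- seq_chars(primer)
  plus <- scan_strand(pch, block_positions = (plen - block_size + 1L):plen)
  # minus strand: the primer anneals to the + strand read as its reverse
  # complement; its 3' terminus maps to the leftmost footprint position
  rch <- seq_chars(revcomp(primer))
  minus <- scan_strand(rch, block_positions = 1:block_size)

  bind_rows(
    tibble(template_id = template$id, strand = "+",
           start = plus$start, end = plus$start + plen - 1L,
           three_prime_position = plus$start + plen - 1L,
           mismatch_total = plus$mism,
           mismatches_in_3prime_block = plus$mism_block),
    tibble(template_id = template$id, strand = "-",
           start = minus$start, end = minus$start + plen - 1L,
           three_prime_position = minus$start,
           mismatch_total = minus$mism,
           mismatches_in_3prime_block = minus$mism_block)
  ) |> arrange(.data$strand, .data$start)
}

# normalise the many accepted "pair" shapes to list(forward=, reverse=)
pair_sequences <- function(pair) {
  if (is.list(pair) && !is.data.frame(pair) &&
      all(c("forward", "reverse") %in% names(pair))) {
    return(list(forward = toupper(pair$forward),
                reverse = toupper(pair$reverse)))
  }
  if (is.data.frame(pair) && all(c("forward_seq", "reverse_seq") %in%
                                 colnames(pair))) {
    stopifnot(nrow(pair) == 1L)
    return(list(forward = pair$forward_seq, reverse = pair$reverse_seq))
  }
  if (is.data.frame(pair) && "orientation" %in% colnames(pair)) {
    fwd <- pair$sequence[pair$orientation == "forward"]
    rev <- pair$sequence[pair$orientation == "reverse"]
    if (length(fwd) != 1L || length(rev) != 1L) {
      abort("primer-table pair must contain exactly one forward and one reverse row")
    }
    return(list(forward = fwd, reverse = rev))
  }
  abort("cannot interpret primer pair")
}

#' Predict PCR amplicons of a primer pair on a set of templates
#'
#' For each template, combines every forward-primer site on the + strand
#' with every reverse-primer site on the - strand whose footprints face each
#' other, yielding amplicons of `0 < length <= max_amplicon_scan` nt. The
#' amplicon span includes both primer footprints (gel-size convention).
#'
#' @param pair a one-row pair table from [pair_and_rank()], a two-row primer
#'   table (one forward, one reverse), or `list(forward =, reverse =)`.
#' @param templates tibble of sequence records.
#' @param max_mismatch,block_size binding-site tolerance
#'   (see [find_binding_sites()]).
#' @param max_amplicon_scan maximum amplicon length considered.
#' @return tibble of predictions ordered by template then start: `template_id`,
#'   `species` (when present in `templates`), `start`, `end`, `length`,
#'   `forward_mismatches`, `reverse_mismatches`.
#' @export
predict_amplicons <- function(pair, templates, max_mismatch = 3L,
                              block_size = 2L, max_amplicon_scan = 3000L) {
  pr <- pair_sequences(pair)
  res <- list()
  for (i in seq_len(nrow(templates))) {
    tmpl <- templates[i, ]
    if (nchar(pr$forward) > nchar(tmpl$sequence) ||
        nchar(pr$reverse) > nchar(tmpl$sequence)) next
    fsites <- find_binding_sites(pr$forward, tmpl, max_mismatch, block_size)
    fsites <- fsites[fsites$strand == "+", ]
    if (nrow(fsites) == 0L) next
    rsites <- find_binding_sites(pr$reverse, tmpl, max_mismatch, block_size)
    rsites <- rsites[rsites$strand == "-", ]
    if (nrow(rsites) == 0L) next
    for (f in seq_len(nrow(fsites))) {
      for (r in seq_len(nrow(rsites))) {
        len <- rsites$end[r] - fsites$start[f] + 1L
        if (len > 0L && len <= max_amplicon_scan) {
          res[[length(res) + 1L]] <- tibble(
            template_id = tmpl$id,
            species = if ("species" %in% colnames(tmpl)) tmpl$species else NA_character_,
            start = fsites$start[f], end = rsites$end[r], length = len,
            forward_mismatches = fsites$mismatch_total[f],
            reverse_mismatches = rsites$mismatch_total[r])
        }
      }
    }
  }
  if (!length(res)) {
    return(tibble(template_id = character(), species = character(),
                  start = integer(), end = integer(), length = integer(),
                  forward_mismatches = integer(),
                  reverse_mismatches = integer()))
  }
  bind_rows(res) |> arrange(.data$template_id, .data$start, .data$end)
}

#' Specificity matrix over single species and mock-community mixtures
#'
#' Screens every primer pair against each single-species template set and
#' against mixed-template mock communities: an all-species mixture, a
#' per-pair mixture of the non-target species only, and a gradient series
#' in which one target-species template is combined with 1 to 4 copies of
#' each non-target (1:1:1:1 ... 1:4:4:4). Copy counts are a reported dose
#' annotation only; amplification is presence/absence, so a mixture cell is
#' always the union of its member species' cells.
#'
#' @param pairs a pair table from [pair_and_rank()] (columns
#'   `target_species`, `forward_seq`, `reverse_seq`) or a primer table from
#'   [read_primer_table()] (grouped into pairs per `target_species`).
#' @param templates tibble of sequence records with a `species` column.
#' @param mixtures optional named list of mixtures; each element is a named
#'   numeric vector of copy counts per species. When `NULL`, the default
#'   mock-community design described above is built.
#' @param max_mismatch,block_size,max_amplicon_scan see
#'   [predict_amplicons()].
#' @return a `specificity_matrix` tibble, one row per pair x template set:
#'   `target_species`, `pair_rank`, `template_set`, `set_type`
#'   (`single`/`mixture`), `contains_target`, `dose`, `n_amplicons`,
#'   `amplicon_lengths` (comma-separated), `positive`.
#' @export
specificity_matrix <- function(pairs, templates, mixtures = NULL,
                               max_mismatch = 3L, block_size = 2L,
                               max_amplicon_scan = 3000L) {
  pairs <- normalise_pairs(pairs)
  if (!"species" %in% colnames(templates)) {
    abort("templates need a species column")
  }
  species <- unique(templates$species)
  res <- list()
  for (k in seq_len(nrow(pairs))) {
    pr <- pairs[k, ]
    mix <- mixtures %||% default_mixtures(species, pr$target_species)
    # per-species amplicon sets, computed once per pair
    per_sp <- lapply(setNames(species, species), function(s) {
      predict_amplicons(pr, templates[templates$species == s, ],
                        max_mismatch, block_size, max_amplicon_scan)
    })
    add_cell <- function(set_name, set_type, members) {
      amps <- bind_rows(per_sp[names(members)[members > 0]])
      dose <- paste(sprintf("%s:%g", names(members)[members > 0],
                            members[members > 0]), collapse = ",")
      res[[length(res) + 1L]] <<- tibble(
        target_species = pr$target_species,
        pair_rank = pr$rank,
        template_set = set_name, set_type = set_type,
        contains_target = pr$target_species %in% names(members)[members > 0],
        dose = dose,
        n_amplicons = nrow(amps),
        amplicon_lengths = paste(sort(amps$length), collapse = ","),
        positive = nrow(amps) > 0L)
    }
    for (s in species) add_cell(s, "single", setNames(1, s))
    for (mname in names(mix)) add_cell(mname, "mixture", mix[[mname]])
  }
  structure(bind_rows(res),
            class = c("specificity_matrix", class(tibble())))
}

# the validation mixtures: all species, non-targets only, and the gradient
# series (one target : 1..4 of each non-target) with its negative controls
default_mixtures <- function(species, target) {
  others <- setdiff(species, target)
  mix <- list(
    all_species = setNames(rep(1, length(species)), species),
    nontarget_only = setNames(rep(1, length(others)), others)
  )
  for (d in 1:4) {
    mix[[sprintf("gradient_1to%d", d)]] <-
      setNames(c(1, rep(d, length(others))), c(target, others))
    mix[[sprintf("gradient_1to%d_neg", d)]] <-
      setNames(rep(d, length(others)), others)
  }
  mix
}

# coerce a primer table (rows) into a pair table if needed
normalise_pairs <- function(pairs) {
  if (all(c("forward_seq", "reverse_seq") %in% colnames(pairs))) {
    if (!"rank" %in% colnames(pairs)) pairs$rank <- seq_len(nrow(pairs))
    return(pairs)
  }
  if ("orientation" %in% colnames(pairs)) {
    out <- pairs |>
      group_by(.data$target_species) |>
      summarise(
        forward_seq = .data$sequence[.data$orientation == "forward"][1],
        reverse_seq = .data$sequence[.data$orientation == "reverse"][1],
        .groups = "drop")
    if (anyNA(out$forward_seq) || anyNA(out$reverse_seq)) {
      abort("each target_species needs one forward and one reverse primer")
    }
    out$rank <- 1L
    return(out)
  }
  abort("cannot interpret pairs input")
}
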