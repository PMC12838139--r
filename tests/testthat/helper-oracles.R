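# Independent oracles, deliberately written as straight-line enumerations
# separate from the package implementation.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# --- nearest-neighbor Tm, hand-summed from the published unified table ----
# (own copy of the constants; summation laid out term by term)
oracle_tm <- function(seq, salt_mM = 50, conc_nM = 500) {
  dh_tab <- list(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
                 CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
                 CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
                 CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds_tab <- list(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
                 CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
                 CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
                 CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  ch <- strsplit(seq, "")[[1]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(ch) - 1)) {
    nn <- paste0(ch[i], ch[i + 1])
    dh <- dh + dh_tab[[nn]]
    ds <- ds + ds_tab[[nn]]
  }
  for (end in c(ch[1], ch[length(ch)])) {
    if (end == "G" || end == "C") { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  selfcomp <- identical(seq, oracle_revcomp(seq))
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (length(ch) - 1) * log(salt_mM / 1000)
  x <- if (selfcomp) 1 else 4
  1000 * dh / (ds + 1.987 * log(conc_nM * 1e-9 / x)) - 273.15
}

# --- naive binding-site scan ----------------------------------------------
# slides the primer base by base; minus strand handled by comparing the
# primer to the reverse complement of the template window
oracle_binding_sites <- function(primer, template, max_mismatch = 3,
                                 block_size = 2) {
  pch <- strsplit(primer, "")[[1]]
  plen <- length(pch)
  tch <- strsplit(template, "")[[1]]
  n <- length(tch)
  out <- list()
  for (s in seq_len(max(0, n - plen + 1))) {
    win <- tch[s:(s + plen - 1)]
    # + strand: primer 5'->3' along the window
    mm <- sum(win != pch | !win %in% c("A", "C", "G", "T"))
    blk <- sum({
      tail_idx <- (plen - block_size + 1):plen
      win[tail_idx] != pch[tail_idx] |
        !win[tail_idx] %in% c("A", "C", "G", "T")
    })
    if (mm <= max_mismatch && blk == 0) {
      out[[length(out) + 1]] <- data.frame(strand = "+", start = s,
                                           mismatch_total = mm)
    }
    # - strand: primer must match the revcomp of the window; its 3' end
    # then lies at the left edge of the window
    winrc <- strsplit(oracle_revcomp(paste(win, collapse = "")), "")[[1]]
    ok <- win %in% c("A", "C", "G", "T")
    bad <- winrc != pch | !rev(ok)
    mm2 <- sum(bad)
    blk2 <- sum(bad[(plen - block_size + 1):plen])
    if (mm2 <= max_mismatch && blk2 == 0) {
      out[[length(out) + 1]] <- data.frame(strand = "-", start = s,
                                           mismatch_total = mm2)
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(), start = integer(),
                      mismatch_total = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$start), , drop = FALSE]
}

# --- exhaustive global alignment over unit sequences ----------------------
# enumerates every monotone alignment path and scores it from scratch
# (affine gaps: open + (k-1) * extend per gap run), so the optimum is found
# by brute force rather than by dynamic programming
oracle_align_best <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  score_path <- function(moves) {
    sc <- 0; i <- 0; j <- 0
    runs <- rle(moves)
    for (k in seq_along(runs$values)) {
      mv <- runs$values[k]; len <- runs$lengths[k]
      if (mv == "D") {
        for (t in seq_len(len)) { i <- i + 1; j <- j + 1; sc <- sc + S[i, j] }
      } else {
        sc <- sc - gap_open - (len - 1) * gap_extend
        if (mv == "U") i <- i + len else j <- j + len
      }
    }
    sc
  }
  recurse <- function(i, j, moves) {
    if (i == n && j == m) {
      best <<- max(best, score_path(moves))
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, c(moves, "D"))
    if (i < n) recurse(i + 1, j, c(moves, "U"))
    if (j < m) recurse(i, j + 1, c(moves, "L"))
  }
  recurse(0, 0, character())
  best
}

# --- brute-force dimer scan ------------------------------------------------
# checks base-by-base Watson-Crick pairing in antiparallel orientation,
# written directly in terms of complement pairs
oracle_dimer <- function(a, b) {
  ach <- strsplit(a, "")[[1]]
  bch <- rev(strsplit(b, "")[[1]])  # antiparallel partner order
  best <- 0
  for (off in seq(-length(bch) + 1, length(ach) - 1)) {
    run <- 0
    for (i in seq_along(ach)) {
      j <- i - off
      paired <- j >= 1 && j <= length(bch) && ORACLE_COMP[ach[i]] == bch[j]
      if (isTRUE(paired)) { run <- run + 1; best <- max(best, run) }
      else run <- 0
    }
  }
  best
}

# --- small builders --------------------------------------------------------
toy_alignment <- function(rows, species = NULL, ids = NULL) {
  n <- length(rows)
  as_alignment(tibble::tibble(
    id = ids %||% paste0("r", seq_len(n)),
    species = species %||% paste0("s", seq_len(n)),
    sequence = rows))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
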