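# Unified nearest-neighbor parameters (SantaLucia, 1 M NaCl):
# dH in kcal/mol, dS in cal/(mol K), 5'->3' top-strand dinucleotides.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
INIT_GC <- c(dH = 0.1, dS = -2.8)   # per duplex end closing on G.C
INIT_AT <- c(dH = 2.3, dS = 4.1)    # per duplex end closing on A.T
SYM_DS <- -1.4                      # self-complementary duplex entropy term
R_GAS <- 1.987                      # cal/(mol K)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer against its perfect complement,
#' from the unified nearest-neighbor parameter set: dinucleotide enthalpies
#' and entropies are summed 5'->3', duplex-end initiation terms are added
#' for each terminal base pair, a symmetry entropy term applies to
#' self-complementary sequences, and the entropy is salt-corrected by
#' `0.368 * (L - 1) * ln([Na+])` (L = primer length). Then
#' `Tm = 1000 * dH / (dS_salt + R * ln(C/x)) - 273.15` with `C` the total
#' strand concentration and `x = 4` (1 for self-complementary duplexes).
#'
#' @param sequence primer sequence 5'->3', unambiguous A/C/G/T, length >= 8.
#' @param salt_mM monovalent cation concentration in mM.
#' @param primer_conc_nM total strand concentration in nM.
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AGCGTCTGAACTGGACTTCA")
melting_temperature <- function(sequence, salt_mM = 50, primer_conc_nM = 500) {
  sequence <- toupper(sequence)
  chars <- seq_chars(sequence)
  if (length(chars) < 8L) abort("sequence must be at least 8 nt for Tm")
  if (any(!chars %in% UNAMBIGUOUS)) {
    abort("Tm requires unambiguous A/C/G/T bases only")
  }
  dinucs <- paste0(chars[-length(chars)], chars[-1])
  dH <- sum(NN_DH[dinucs])
  dS <- sum(NN_DS[dinucs])
  for (end in c(chars[1], chars[length(chars)])) {
    term <- if (end %in% c("G", "C")) INIT_GC else INIT_AT
    dH <- dH + term[["dH"]]
    dS <- dS + term[["dS"]]
  }
  self_comp <- identical(sequence, revcomp(sequence))
  if (self_comp) dS <- dS + SYM_DS
  dS_salt <- dS + 0.368 * (length(chars) - 1L) * log(salt_mM / 1000)
  ct <- primer_conc_nM * 1e-9
  x <- if (self_comp) 1 else 4
  1000 * dH / (dS_salt + R_GAS * log(ct / x)) - 273.15
}

#' Hairpin and self-dimer structure scores
#'
#' Integer match-run heuristics for primer secondary structure, mirroring
#' the qualitative screening used in primer-design practice rather than a
#' free-energy folding model. `hairpin_score` is the longest
#' self-complementary stem closable with a loop of at least 3 nt (perfect
#' Watson-Crick pairs only). `self_dimer_score` is the longest contiguous
#' complementary run of the sequence against itself in antiparallel
#' orientation, over all ungapped offsets.
#'
#' @param sequence primer sequence 5'->3', length >= 8.
#' @return named numeric vector `c(hairpin = , self_dimer = )`.
#' @export
#' @examples
#' structure_scores("GCGCGCTTTTGCGCGC")
structure_scores <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8L) abort("sequence must be at least 8 nt")
  c(hairpin = hairpin_stem(sequence),
    self_dimer = cross_dimer_score(sequence, sequence))
}

# longest perfect WC stem with loop >= 3 nt
hairpin_stem <- function(sequence) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  comp <- COMPLEMENT[chars]
  best <- 0L
  # innermost pair (i, j): extend stem outwards while pairs hold
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i - 1L < 3L) next
      s <- 0L
      while (i - s >= 1L && j + s <= n && comp[i - s] == chars[j + s]) {
        s <- s + 1L
      }
      best <- max(best, s)
    }
  }
  best
}

#' Cross-dimer score of two primers
#'
#' Longest contiguous complementary run between `seq_a` and `seq_b` in
#' antiparallel orientation, over all ungapped relative offsets. Equals
#' `nchar(seq_a)` when `seq_b` is the reverse complement of `seq_a`.
#'
#' @param seq_a,seq_b primer sequences 5'->3'.
#' @return integer match-run score (>= 0).
#' @export
cross_dimer_score <- function(seq_a, seq_b) {
  a <- seq_chars(toupper(seq_a))
  rb <- seq_chars(revcomp(seq_b))  # matching revcomp = complementary pairing
  na <- length(a); nb <- length(rb)
  best <- 0L
  for (off in -(nb - 1L):(na - 1L)) {
    run <- 0L
    for (i in seq_len(na)) {
      j <- i - off
      if (j >= 1L && j <= nb && a[i] == rb[j]) {
        run <- run + 1L
        if (run > best) best <- run
      } else {
        run <- 0L
      }
    }
  }
  best
}
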