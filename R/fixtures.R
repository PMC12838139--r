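#' Generate a synthetic multi-species coding-marker family
#'
#' Simulates a family of full-length protein-coding marker sequences (one
#' per species) with the statistical structure of a divergent mitochondrial
#' barcode: AT-biased composition that is strongest at first and third codon
#' positions, a target mean pairwise p-distance, substitutions concentrated
#' in a mid-gene hotspot interval, no in-frame stop codons, and a set of
#' *planted* species-diagnostic columns (one species differs from the single
#' base shared by all others) whose positions are returned as ground truth.
#'
#' An ancestral sequence is drawn codon-by-codon from per-position base
#' frequencies; each lineage then substitutes sites independently. The
#' per-site substitution-event probability is calibrated (by solving the
#' expected pairwise mismatch equation, planted columns included) so that
#' the mean pairwise p-distance is `target_p` in expectation, with a
#' `hotspot_share` fraction of events placed inside `hotspot`. An event
#' redraws the base from the positional stationary frequencies (an
#' F81-style move, so composition is preserved under divergence); events
#' and plantings that would create a stop codon are repaired. Planted columns
#' are excluded from random substitution so the planted pattern survives.
#'
#' @param n_species number of species (one sequence each).
#' @param n_codons sequence length in codons (3x in nt).
#' @param target_p desired mean pairwise p-distance, in `[0, 0.75]`.
#' @param at_fraction stationary overall A+T fraction.
#' @param hotspot `c(start, end)` 1-based nt interval receiving
#'   `hotspot_share` of substitution events.
#' @param hotspot_share fraction of substitution events inside `hotspot`.
#' @param planted_per_species number of diagnostic columns planted per
#'   species, all inside `hotspot`.
#' @param seed integer seed; the output is fully reproducible.
#' @param species_names optional character vector of species labels.
#' @return `list(records, truth)`: `records` is a record tibble (see
#'   [read_fasta()]); `truth` is a tibble with `species` and `column`
#'   giving the planted diagnostic columns.
#' @export
#' @examples
#' fam <- generate_family(n_codons = 100, hotspot = c(60, 240),
#'                        planted_per_species = 3, seed = 1)
#' fam$truth
generate_family <- function(n_species = 4L, n_codons = 515L,
                            target_p = 0.19, at_fraction = 0.70,
                            hotspot = c(600L, 1300L), hotspot_share = 0.7,
                            planted_per_species = 20L, seed = 1L,
                            species_names = NULL) {
  L <- 3L * n_codons
  if (target_p < 0 || target_p > 0.75) abort("target_p must be in [0, 0.75]")
  if (hotspot[1] < 1L || hotspot[2] > L || hotspot[1] > hotspot[2]) {
    abort("hotspot must lie inside the sequence")
  }
  if (hotspot_share < 0 || hotspot_share > 1) {
    abort("hotspot_share must be in [0, 1]")
  }
  n_planted <- n_species * planted_per_species
  hot_cols <- hotspot[1]:hotspot[2]
  if (n_planted > length(hot_cols)) {
    abort("more planted diagnostic sites than hotspot columns")
  }
  species <- species_names %||% paste0("sp", seq_len(n_species))
  stopifnot(length(species) == n_species)
  set.seed(as.integer(seed))

  freqs <- position_freqs(at_fraction)
  anc <- draw_ancestor(n_codons, freqs)

  planted_cols <- sort(sample(hot_cols, n_planted))
  planted_sp <- rep(species, each = planted_per_species)
  # shuffle the species-to-column assignment so plantings interleave
  perm <- sample.int(n_planted)
  truth <- tibble(species = planted_sp[order(perm)], column = planted_cols)

  # per-class substitution probabilities calibrated to target_p
  pos_class <- rep(0L, L)
  pos_class[hot_cols] <- 1L
  pos_class[planted_cols] <- 2L            # planted: no random substitution
  L_h <- sum(pos_class == 1L); L_o <- sum(pos_class == 0L)
  q <- calibrate_rates(target_p, L, L_h, L_o, n_planted, n_species,
                       hotspot_share, freqs)
  q_site <- numeric(L)
  q_site[pos_class == 1L] <- q[["hot"]]
  q_site[pos_class == 0L] <- q[["cold"]]
  codon_pos <- rep(1:3, length.out = L)

  seqs <- matrix(rep(anc, n_species), nrow = n_species, byrow = TRUE)
  for (s in seq_len(n_species)) {
    hit <- which(stats::runif(L) < q_site)
    for (j in hit) {
      # F81-style event: redraw from the positional stationary frequencies
      # (possibly silently), so the AT-biased composition is preserved
      # under divergence
      seqs[s, j] <- sample(colnames(freqs), 1L,
                           prob = freqs[codon_pos[j], ])
    }
    seqs[s, ] <- purge_stops(seqs[s, ], anc)
  }

  # plant the one-species-differs pattern, stop-codon safe in every lineage
  for (k in seq_len(nrow(truth))) {
    j <- truth$column[k]
    tgt <- which(species == truth$species[k])
    allowed <- allowed_bases(seqs, j)
    wts <- freqs[codon_pos[j], allowed]
    shared <- sample(allowed, 1L, prob = wts)
    rest <- setdiff(allowed, shared)
    diff_b <- sample(rest, 1L, prob = freqs[codon_pos[j], rest])
    seqs[, j] <- shared
    seqs[tgt, j] <- diff_b
  }

  records <- tibble(id = paste0(species, "_1"), species = species,
                    sequence = apply(seqs, 1L, paste0, collapse = ""),
                    frame_offset = 0L)
  list(records = records, truth = truth |> arrange(.data$species,
                                                   .data$column))
}

# per-codon-position base frequencies emulating a mitochondrial coding
# marker: AT enrichment strongest at positions 1 and 3, position 2 more
# balanced, G scarce at position 1; rows sum to 1, mean A+T = at_fraction
position_freqs <- function(at_fraction) {
  at <- at_fraction + c(0.12, -0.24, 0.12)
  if (any(at <= 0 | at >= 1)) abort("at_fraction out of feasible range")
  a_share <- c(0.60, 0.45, 0.47)   # A share of A+T per position
  g_share <- c(0.30, 0.40, 0.35)   # G share of G+C per position
  t(vapply(1:3, function(p) {
    c(A = at[p] * a_share[p], T = at[p] * (1 - a_share[p]),
      G = (1 - at[p]) * g_share[p], C = (1 - at[p]) * (1 - g_share[p]))
  }, numeric(4)))
}

# Quota (stratified) ancestral draw: per codon position the base counts are
# fixed to the stationary frequencies by largest-remainder rounding and the
# pool is shuffled, so the ancestral composition matches the target exactly
# rather than fluctuating binomially -- composition is a characteristic of
# the marker, not a per-family sampling draw. Stop codons are then repaired
# by swapping third-position bases between codons, which preserves the
# composition exactly.
draw_ancestor <- function(n_codons, freqs) {
  pool <- function(p) {
    raw <- freqs[p, ] * n_codons
    cnt <- floor(raw)
    rem <- n_codons - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    sample(rep(colnames(freqs), cnt))
  }
  cod <- rbind(pool(1), pool(2), pool(3))
  cod <- repair_stops(cod)
  as.vector(cod)
}

# swap third-position bases out of stop codons (TAA/TAG/TGA) into codons
# that tolerate them; net base counts are unchanged
repair_stops <- function(cod) {
  codon_str <- function() paste0(cod[1, ], cod[2, ], cod[3, ])
  stops <- which(codon_str() %in% STOP_CODONS)
  if (!length(stops)) return(cod)
  prefix <- paste0(cod[1, ], cod[2, ])
  # partners: third position C/T (kills TAA/TAG/TGA) and a prefix that
  # tolerates receiving A/G at position 3
  ok_partner <- cod[3, ] %in% c("C", "T") & !prefix %in% c("TA", "TG")
  partners <- sample(which(ok_partner))
  if (length(partners) < length(stops)) {
    abort("cannot repair stop codons: sequence too short for quota draw")
  }
  for (k in seq_along(stops)) {
    i <- stops[k]; j <- partners[k]
    tmp <- cod[3, i]; cod[3, i] <- cod[3, j]; cod[3, j] <- tmp
  }
  cod
}

# solve for substitution-event intensity so expected mean pairwise p ==
# target_p. Under the F81-style redraw, a site whose ancestor is drawn from
# the stationary distribution pi mismatches between two lineages with
# probability f(q) = (2q - q^2) * kappa, where q is the per-lineage event
# probability and kappa = 1 - sum(pi^2) (averaged over codon positions) is
# the chance a redraw differs from an independently pi-drawn base; planted
# columns contribute a fixed 2/n_species mismatch share.
calibrate_rates <- function(target_p, L, L_h, L_o, n_planted, n_species,
                            share, freqs) {
  kappa <- substitution_kappa(freqs)
  f <- function(q) (2 * q - q^2) * kappa
  planted_part <- n_planted * 2 / n_species
  want <- L * target_p - planted_part
  if (want <= 0) return(c(hot = 0, cold = 0))
  g <- function(M) {
    qh <- min(share * M / max(L_h, 1L), 0.99)
    qo <- min((1 - share) * M / max(L_o, 1L), 0.99)
    L_h * f(qh) + L_o * f(qo) - want
  }
  M <- stats::uniroot(g, c(1e-9, 1.2 * (L_h + L_o)))$root
  c(hot = min(share * M / max(L_h, 1L), 0.99),
    cold = min((1 - share) * M / max(L_o, 1L), 0.99))
}

# P(a stationary redraw differs from an independent stationary draw),
# averaged over codon positions: mean of 1 - sum(pi^2)
substitution_kappa <- function(freqs) {
  mean(vapply(1:3, function(p) 1 - sum(freqs[p, ]^2), numeric(1)))
}

# replace substituted bases that created in-frame stop codons; falls back
# to the ancestral base when no alternative works
purge_stops <- function(chars, anc) {
  n_codons <- length(chars) %/% 3L
  for (c in seq_len(n_codons)) {
    idx <- (3L * c - 2L):(3L * c)
    if (!paste0(chars[idx], collapse = "") %in% STOP_CODONS) next
    changed <- idx[chars[idx] != anc[idx]]
    fixed <- FALSE
    for (j in changed) {
      for (b in sample(setdiff(UNAMBIGUOUS, c(chars[j], anc[j])))) {
        cand <- chars[idx]; cand[match(j, idx)] <- b
        if (!paste0(cand, collapse = "") %in% STOP_CODONS) {
          chars[j] <- b; fixed <- TRUE; break
        }
      }
      if (fixed) break
    }
    if (!fixed) chars[idx] <- anc[idx]
  }
  chars
}

# bases usable at column j without creating a stop codon in any row
allowed_bases <- function(seqs, j) {
  pos <- (j - 1L) %% 3L + 1L
  codon_start <- j - pos + 1L
  ok <- vapply(UNAMBIGUOUS, function(b) {
    for (s in seq_len(nrow(seqs))) {
      codon <- seqs[s, codon_start:(codon_start + 2L)]
      codon[pos] <- b
      if (paste0(codon, collapse = "") %in% STOP_CODONS) return(FALSE)
    }
    TRUE
  }, logical(1))
  UNAMBIGUOUS[ok]
}
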