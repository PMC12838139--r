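---
title: "Species-diagnostic primer design: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-diagnostic primer design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagprimer)
```

## The problem and the model

Species identification by DNA barcoding normally amplifies a conserved
marker region with universal primers and sequences the product. For routine
surveillance of morphologically similar, co-occurring species — small
insects such as thrips are the archetype — sequencing is the bottleneck.
The alternative implemented here inverts the barcoding logic: instead of
conserved primer sites, primers are placed on the *most divergent* part of
the marker, and each primer's 3′-terminal base is required to fall on a
**diagnostic site**: an alignment column where the target species carries
one base and all other species share a single different base. DNA
polymerases extend poorly over a mismatch at or immediately adjacent to the
primer 3′ terminus, so a primer ending on such a site is extended on the
target template and blocked on every non-target. A primer pair built this
way yields presence/absence species calls on a gel, in single-species and
mixed-species reactions alike.

The package operates on a tibble of species-labelled coding sequences and
decomposes the workflow into alignment, divergence statistics, window
detection, candidate enumeration, pairing/ranking and in-silico validation.
This vignette records the models behind each step, the parameters that
matter, and the choices made where the design was genuinely open.

## Codon-aware alignment

Coding markers diverge by substitutions and, occasionally, by whole-codon
indels; frame-breaking gaps in a full-length functional gene are
implausible. The aligner therefore works in codon units: a pairwise global
(Needleman–Wunsch/Gotoh) alignment in which one DP cell is one codon. A
codon-vs-codon score is the summed per-nucleotide identity (+1 match / −1
mismatch), so it ranges −3…+3; a gap run of *k* codons costs
`gap_open + (k − 1) · gap_extend` with defaults 8/2 on that scale. The
defaults make a single-codon gap (cost 8) preferable to three scattered
mismatches only when the flanking context supports it, and favour one long
gap over fragmented ones. Multiple sequences are joined progressively: the
first input record seeds the profile, remaining records join by decreasing
pairwise identity to it, and a new row is aligned against the mean
per-column score of the existing profile. Leading out-of-frame bases and a
trailing partial codon are carried as short units so that ungapping any row
reproduces its input exactly.

Two caveats are deliberate. First, the pairwise engine is exhaustively
verified — its score equals the brute-force optimum over every gap
placement on small instances — but the progressive join is heuristic, as in
all progressive MSA: no claim of sum-of-pairs optimality is made or tested
for ≥3 sequences; the tested guarantees are row conservation and
codon-multiple gap runs. Second, no objective exists for "the" correct
alignment of a real marker family (reference alignments of this kind are
typically curated by hand); the codon-unit scorer is this package's
explicit, reproducible stand-in for that manual curation.

## Divergence statistics

`base_composition()` reports A/T/G/C percentages and GC content per species,
overall and per codon position, counting only unambiguous bases (ambiguity
codes leave both numerator and denominator). Codon positions are indexed on
each ungapped sequence from its `frame_offset`, never from alignment
columns, so alignment gaps cannot shift position classes. The three
positional rows recombine exactly, weighted by their denominators, to the
overall row — a closure the tests assert.

`p_distance_matrix()` computes the uncorrected proportion of differing
sites, `p = mismatches / comparable sites`, where a site is comparable for
a pair only if both rows carry an unambiguous non-gap base — pairwise
deletion, the convention of the standard phylogenetics packages. Gaps are
missing data, not a fifth state. With several sequences per species the
default collapses each species to a majority-rule consensus first (ties
become N and drop out pairwise); `collapse = "per_record"` keeps every
record. Both modes are exposed because published species-level distance
tables rarely state which was used.

## Hypervariable windows and diagnostic sites

`site_profile()` classifies each column: polymorphic when ≥2 distinct
unambiguous bases occur, diagnostic for a species under the one-species-
differs rule above. Columns containing any gap or ambiguity are never
diagnostic — a conservative rule, since a primer 3′ terminus resting on
uncertain non-target bases cannot guarantee the mismatch the assay relies
on. A corollary worth noting: in a two-species alignment a fixed difference
separates both species symmetrically, so no column is assigned to either;
the diagnostic concept needs ≥3 species.

`hypervariable_windows()` slides a `window` of 100 columns in steps of 10
and keeps windows with ≥ `min_density` = 0.15 polymorphic columns, merging
overlapping keepers and re-scoring the merged span. The defaults recover
contiguous polymorphism-rich regions several hundred columns long — the
scale at which divergent barcode markers concentrate their interspecific
variation — and at strong overall divergence (mean *p* ≈ 0.19) the merged
window can legitimately cover most of the gene, because the background
polymorphic density itself exceeds 0.15. The window step matters for
candidate placement only through `restrict_to_windows`; raising
`min_density` narrows design space toward the hotspot.

## Primer model

**Melting temperature.** The nearest-neighbor model sums dinucleotide
ΔH°/ΔS° over the primer using the unified parameter set (the ten duplex
stacks plus terminal A·T / G·C initiation terms and the self-complementary
symmetry entropy), applies the entropic monovalent-salt correction
ΔS°(salt) = ΔS° + 0.368·(L−1)·ln[Na⁺], and evaluates
Tm = 1000·ΔH° / (ΔS°(salt) + R·ln(C/4)) − 273.15, with C the total strand
concentration (x = 1 replaces 4 for self-complementary oligos). Defaults:
50 mM monovalent salt, 500 nM primer. The tests pin the implementation to
an independently hand-summed oracle of the same published table to
±0.01 °C.

**Structure heuristics.** Hairpin and dimer screening uses integer
match-run scores, not free-energy folding: the hairpin score is the longest
perfect Watson–Crick stem closable with a ≥3 nt loop; self- and cross-dimer
scores are the longest contiguous complementary run between two oligos in
antiparallel orientation over all ungapped offsets. These mirror the
qualitative screens primer-design GUIs apply; free-energy minimisation is
out of scope because assay feasibility, not ΔG accuracy, is the decision
being made.

**Enumeration and filters** (`design_config()` defaults): primer length
18–24 nt; amplicon 550–800 bp; Tm 55–65 °C with ≤3 °C pair difference; GC
35–65 %; hairpin ≤ 4, self-dimer ≤ 8, cross-dimer ≤ 8; ≥2 full-length
mismatches against every non-target row; and the diagnostic requirement —
by default `strict_terminal = TRUE`, the 3′-terminal base itself must be a
diagnostic site (the window-only alternative, ≥1 diagnostic site within the
terminal `diagnostic_3prime_window` = 5 nt, is one flag away). The amplicon
default is worth a note: assays of this family are typically described with
600–800 bp products, yet validated designs in practice run somewhat
shorter; 550 was adopted as the lower bound so that the defaults admit the
shorter validated products, and the stricter 600 remains a configuration
choice. Candidates are substrings of the target species' majority consensus;
any gap or ambiguity in the span disqualifies it outright, since a primer
synthesised against an uncertain base is an uncontrolled degeneracy.

**Ranking.** Surviving forward × reverse combinations are ordered by
`w_tm·closeness(meanTm, range midpoint) + w_diag·(diagnostic sites in both
3′ windows) + w_mm·(worst-case non-target mismatches) − w_struct·(hairpin +
self-dimer + cross-dimer)`, defaults 1/2/1/0.5. The weights encode a simple
priority: specificity signals (diagnostic anchoring, non-target mismatches)
dominate; thermodynamic centring is a soft preference; structure scores are
a penalty, not a hard wall, once under their ceilings. Commercial design
tools rank by opaque internal scores; this composite is the package's
explicit, documented replacement. Ties break by ascending amplicon start,
then length, making the ranking a total order independent of input order.

A species can legitimately yield zero pairs: with strict terminal
anchoring, candidates exist only at diagnostic columns that also pass the
Tm/GC/structure filters, and at some seeds the surviving forward and
reverse anchors simply cannot span the configured amplicon band. The
designer reports the empty result rather than silently relaxing a
constraint; users facing it should widen `amplicon_length_range` or
`tm_range`, or set `strict_terminal = FALSE`.

## In-silico PCR

`find_binding_sites()` scans both template strands for footprints with
`mismatch_total ≤ max_mismatch` (default 3) and **zero** mismatches in the
terminal `block_size` (default 2) bases of the 3′ end — the extension-block
rule that turns 3′-terminal diagnostic bases into specificity. Ambiguous
template bases always count as mismatches (a conservative reading: an
uncertain base cannot be assumed to pair). `predict_amplicons()` combines
forward sites on the plus strand with reverse sites on the minus strand
into products of ≤ `max_amplicon_scan` (3000) nt, spans including both
primer footprints (the gel-size convention). The defaults deserve honesty:
how many total mismatches a real reaction tolerates is reaction-dependent
and not derivable from first principles here; 3 was chosen to tolerate
minor uncharacterised haplotype drift while the 2-base block preserves the
diagnostic logic, and both are plain config values.

`specificity_matrix()` reproduces the validation design of mock-community
screening: each pair against each single species, an all-species mixture, a
non-target-only mixture, and a gradient series combining one target with
1–4 copies of each non-target (1:1:1:1 … 1:4:4:4) plus target-absent
negatives. The model is presence/absence only: template dose annotates the
cell but never flips an outcome, because no quantitative
amplification-efficiency, inhibition or limit-of-detection model is
attempted — those are wet-lab phenomena with no defensible in-silico
counterpart, and pretending otherwise would overstate what the screen
shows. Consequently a mixture cell is exactly the union of its members'
cells, an invariant the tests assert on every generated matrix.

## The synthetic family generator

`generate_family()` emulates the statistical structure of a divergent
four-species mitochondrial coding marker, so that every consumer module is
testable without sequence downloads. Defaults, which *are* the study
conditions of the test suite:

* 4 species, 515 codons (1545 nt), one sequence per species;
* stationary A+T fraction 0.70 overall, distributed per codon position as
  0.82 / 0.46 / 0.82 with A/T and G/C splits chosen to give an A-rich first
  position, a balanced second and a T-rich third, G rarest at position 1 —
  the compositional signature of insect mitochondrial genes;
* target mean pairwise *p*-distance 0.19, the mid-range of interspecific
  barcode divergence between congeneric insect species;
* a substitution hotspot over columns 600–1300 receiving 70 % of
  substitution events, emulating a mid-gene polymorphism-rich region;
* 20 planted diagnostic columns per species, inside the hotspot;
* no stop codons anywhere in frame.

Mechanics: the ancestor is drawn by stratified quota sampling (per-position
base counts fixed by largest-remainder rounding, pools shuffled), so the
realized composition matches the stationary target instead of fluctuating
binomially — composition is treated as a characteristic of the marker, not
a per-family sampling draw. Stop codons are repaired by swapping
third-position bases between codons, preserving counts exactly. Each
lineage then substitutes sites independently by an F81-style move: with
site-specific probability *q* the base is redrawn from the positional
stationary frequencies (possibly silently), which keeps composition
invariant under divergence. *q* is calibrated by solving the expected
mismatch equation: a pair differs at a stationary site with probability
(2q − q²)·κ, κ = 1 − Σπ² averaged over positions, and planted columns
contribute a fixed 2/n share; the per-class rates then split the solved
total intensity 70/30 between hotspot and background. Planted columns are
excluded from random substitution and set last to the one-species-differs
pattern with stationary-weighted bases, stop-safe in every lineage.

What the generator does **not** emulate: indels (alignment is exercised on
constructed indel cases instead), rate variation beyond the single hotspot,
transition/transversion bias, within-species haplotype variation, and
sequencing artefacts. Passing tests therefore demonstrate correctness of
the algorithms under a clean independent-sites model of divergence — they
do not show that any particular real marker family will yield designable
primers, which depends on where real diagnostic sites happen to fall.
Realized quantities carry sampling spread around the calibrated targets
(per-pair *p* has SD ≈ 0.01 at 1545 sites); the suite's bands reflect that.

## Numerical and degenerate-input conventions

All report coordinates are 1-based inclusive on the alignment; reverse
primers are stored 5′→3′ on their own strand. Report TSVs fix column order
and format floats to 4 decimals, so identical inputs give byte-identical
files; full precision is kept internally and percentages are conventionally
read at 2 decimals. Ties everywhere break by ascending coordinate.
Degenerate inputs fail loudly and early: empty record sets, records shorter
than one codon, unknown species labels, pairs with zero comparable sites
and malformed primer tables are errors naming the offender; an alignment
with no diagnostic sites for a target is a *warning* plus an empty result,
because "this species is not designable under these constraints" is an
answer, not a failure.

## Problem sizes used by the test and acceptance runs

The suite verifies the binding-site scanner against a naive oracle on 200
random primer/template fixtures, distance axioms on 1000 random
alignments, aligner optimality on exhaustively enumerated instances up to
5 codons, design closure (every emitted pair amplifies its target once and
no non-target) on 3 seeded families, and the divergence calibration across
50 seeds; `scripts/acceptance.R` re-runs the calibration sweep and one full
design-and-validate cycle at the caller's seed. These sizes were chosen as
the smallest at which the checked properties are statistically meaningful.

## Known limitations

* Specificity is assessed only against the supplied non-target set;
  uncharacterised haplotypes or absent taxa can defeat any fixed primer
  set, and the mismatch tolerance that real polymerases exhibit varies
  with chemistry and cycling conditions.
* The Tm model assumes perfect-match duplexes; no mismatch thermodynamics
  are applied to near-matches during in-silico PCR.
* The progressive aligner targets closely related coding sequences; it is
  not a general MSA tool and degrades with deep divergence or frameshifts.
* Presence/absence in-silico PCR cannot rank band intensities, model
  inhibitors, or predict detection limits.
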