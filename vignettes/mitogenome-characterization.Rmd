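---
title: "Methods: mitogenome characterization and distance-based phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome characterization and distance-based phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophylo)
```

This vignette explains the models and procedures behind `mitophylo`, the
choices we made where several defensible designs existed, and what the
package's tests do and do not establish about real data.

## The data model

A `mito_genome` is a nucleotide sequence (optionally absent) plus an
ordered feature table. Coordinates are 1-based inclusive — the GenBank
convention, and the convention in which published organization tables are
printed — and are never exposed in any other form. On a circular molecule
a feature may wrap the origin (`end < start`), meaning the splice
`[start..L] + [1..end]`; this is how control regions spanning the origin
are annotated in many taxa. Overlapping features are legal and preserved:
mammalian mitogenomes overlap ATP8/ATP6 and ND4L/ND4 by construction, and
class length totals are *plain sums* of declared sizes, because that is
the arithmetic annotation tables themselves use (consequently class
percentages can sum to slightly more than 100).

Sequence-free mode exists because an organization table plus printed
per-gene base percentages is sufficient for every roll-up statistic
(lengths, class totals, content, skews). The shipped *M. aurascens*
table is loaded this way; nothing in the composition module distinguishes
declared from computed percentages downstream.

Gene names are normalized to one canonical vocabulary (ND1–6, ND4L,
COX1–3, ATP6/8, Cytb, 12S/16S rRNA, tRNA-Xaa with Leu1/Leu2 and Ser1/Ser2).
The Leu and Ser paralogs are disambiguated by anticodon when the input
carries one: Leu2 reads UUR codons (anticodon UAA), Leu1 CUN; Ser1 reads
AGY (anticodon GCU), Ser2 UCN. Unrecognized names pass through unchanged
rather than erroring, keeping the parser lossless.

Per-feature composition is reported in the H-strand frame of reference
regardless of coding strand — again matching how organization tables are
printed (this is why the one L-strand protein gene, ND6, shows a positive
GC skew while every H-strand PCG is negative: the guanine excess of the
light strand is being read on the heavy strand). Sequence *extraction*,
by contrast, always returns coding sense: L-strand features are
reverse-complemented so codon analysis never sees the template strand.

## Composition and skews

Ambiguity codes and gaps are excluded from every denominator; `U` is read
as `T` on input (organization tables often print RNA-style `A(U)`
headers over DNA data). Skews are the standard strand-asymmetry
statistics

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

which are scale-invariant: counts and percentages give identical values,
which is what lets the sequence-free mode reproduce them exactly from
printed percentages. A zero denominator yields `NA`, never 0 — a missing
skew and a perfectly balanced one are different findings. Raw values are
kept at full precision; 2 decimals for percentages and 3 for skews is a
rendering choice matching conventional printed precision.

## Codon usage and RSCU

The genetic code is NCBI translation table 2 (vertebrate mitochondrial):
AGA/AGG are stops, AUA codes Met, UGA codes Trp. This explains the `AGA`
stop printed for Cytb in mammalian annotations. Mitochondrial CDSs often
end mid-codon — a trailing `T` or `TA` completed to UAA by
polyadenylation — rendered in the conventional `T--`/`TA-` notation.

Counting follows the CodonW conventions: trailing partial codons are
dropped (tallied separately), and a terminal complete stop codon is
excluded from usage. Relative synonymous codon usage is

$$\mathrm{RSCU}_c = \frac{n_c}{\frac{1}{k}\sum_{j \in \mathrm{fam}(c)} n_j},$$

with synonymous families defined per amino acid under table 2 — Leu and
Ser are single six-fold families. Family sums therefore equal $k$ whenever
a family is used at all; unused families report 0 by convention, and stop
codons have no RSCU. Codons are reported in the RNA alphabet (AUU, not
ATT), the way usage tables are conventionally printed.

## Distances

All three estimators use pairwise deletion: per pair, only columns where
both taxa carry an unambiguous A/C/G/T enter the computation. This is the
default of the mainstream distance software and composes naturally with
gap-filled concatenation (a taxon missing a gene simply contributes no
sites from that block to its pairs).

**p-distance** is the mismatch proportion over valid sites.

**Closed-form TN93** corrects for multiple hits using the two transition
proportions (purine $P_1$, pyrimidine $P_2$), the transversion proportion
$Q$, and base frequencies pooled over the pair:

$$d = -k_1 \ln w_1 - k_2 \ln w_2 - k_3 \ln w_3,$$

with $k_1 = 2\pi_A\pi_G/\pi_R$, $k_2 = 2\pi_C\pi_T/\pi_Y$,
$k_3 = 2(\pi_R\pi_Y - \pi_A\pi_G\pi_Y/\pi_R - \pi_C\pi_T\pi_R/\pi_Y)$ and
$w_1 = 1 - \pi_R P_1/(2\pi_A\pi_G) - Q/(2\pi_R)$,
$w_2 = 1 - \pi_Y P_2/(2\pi_C\pi_T) - Q/(2\pi_Y)$,
$w_3 = 1 - Q/(2\pi_R\pi_Y)$. When any $w \le 0$ the pair is saturated and
the distance is reported missing with a warning rather than truncated.
In the equal-frequency, equal-rate limit this reduces algebraically to
the Jukes–Cantor formula $-\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, which the
tests exploit as an oracle; the implementation is also cross-checked
against an independent reference implementation on simulated pairs.

**Maximum composite likelihood (MCL)** is the estimator that the
mainstream distance software labels this way: the TN93 rate ratios
$\kappa_1 = \alpha_1/\beta$ and $\kappa_2 = \alpha_2/\beta$ are *shared*
across all pairs and chosen to maximize the sum of pairwise
log-likelihoods, with frequencies pooled over the whole alignment; each
pair's distance is then its conditional MLE under the shared rates. We
fit by profiling: an inner golden-section optimization of each pair's
distance given $(\kappa_1, \kappa_2)$, and an outer Nelder–Mead over
$(\log\kappa_1, \log\kappa_2)$ (default 500 iterations, relative
tolerance 1e-10; non-convergence is an error, not a silent fallback).
Pairwise pattern counts are precomputed once, so each likelihood
evaluation is a 16-term sum. For two taxa the composite likelihood *is*
the single pair's likelihood, so the MCL distance coincides with the
pairwise TN93 ML distance — a fixed point the tests pin.

Distances are computed on nucleotide supermatrices, not codon or
amino-acid recodings, because the distances being reproduced are
nucleotide distances. Concatenation appends genes column-wise, records a
partition map, and gap-fills taxa missing a gene; supermatrix analyses of
mitochondrial PCGs conventionally exclude ND6 (the one L-strand protein
gene, with anomalous composition), which is the default exclusion in
`run_distances()`.

## Trees and bootstrap

Neighbor joining follows Saitou–Nei with the standard Q-criterion. Two
determinism choices are made explicit: ties on Q are broken in favor of
the lowest index pair (row-major, preserving input label order), and
negative branch lengths — a known artifact of NJ on non-additive input —
are clamped to zero. On additive matrices NJ is exact, and the tests
verify path-length reproduction against a brute-force oracle on random
additive trees up to 8 taxa, plus topological agreement with an
independent NJ implementation.

Bootstrap support resamples alignment columns with replacement, ignoring
partitions (the standard site bootstrap; a partitioned bootstrap is a
non-goal), rebuilds the NJ tree per replicate, and reports the percentage
of replicates containing each original bipartition. The supports are
reproducible under a fixed seed, and the basal label of the arbitrary
trichotomy of an unrooted tree is left blank rather than reported as a
vacuous 100%.

## The simulator and what it does (not) emulate

The simulator exists so every pipeline stage can be tested against known
ground truth without downloading anything.

* `simulate_tree()` draws topologies *uniformly* over the $(2n-5)!!$
  labeled unrooted binary topologies by sequential random edge addition
  — each new leaf attaches to an edge chosen uniformly — which the tests
  verify with a $\chi^2$ test over all 105 six-taxon topologies at
  10,000 draws. Branch lengths are uniform on a configured range,
  defaulting to 0.02–0.2 substitutions/site: the congeneric-divergence
  regime of the distance matrices the package targets.
* `evolve_sequences()` draws the root from the equilibrium frequencies
  and applies the exact TN93 transition matrix $e^{Qt}$ edge by edge.
  TN93 was chosen as the single simulation model deliberately: it is the
  generating counterpart of the distance model, which makes parameter
  recovery a meaningful end-to-end test. Defaults
  ($\pi = (0.34, 0.22, 0.13, 0.31)$, $\kappa_1 = 8$, $\kappa_2 = 16$)
  mimic AT-rich, transition-biased mammalian mtDNA with the heavier
  pyrimidine transition class.
* `synth_genome()` lays out 13 PCGs, 22 tRNAs, 2 rRNAs and a control
  region on a circular molecule with a configurable L-strand fraction
  (default 0.25, near the 9/38 of real mammalian layouts) and incomplete
  stop fraction (default 0.4, near the 5/13 of the real table). Declared
  start and stop codons are genuinely present in the sequence, so
  annotation-consistency tests are non-circular.

Not emulated: indels (alignment columns are masked to gaps post hoc at a
configured rate instead — this exercises pairwise deletion without
simulating an indel process), rate heterogeneity across sites, codon
structure in evolved sequences, and base-compositional heterogeneity
across lineages. Passing recovery tests therefore show the estimators are
correct *under their own model*, not that the model is adequate for any
particular empirical alignment — the usual caveat for model-based
distances.

Every generator consumes a child seed derived from the root seed per
stage, so adding a stage never perturbs earlier draws, and all generators
are fully deterministic given the configuration.

Problem sizes used by the test suite — 20 kb alignments over 6 taxa and
10 seeds for composite-likelihood recovery (pooled RMSE against true path
lengths below 0.01), 100 random additive trees for NJ exactness, 1,000
random usage tables for RSCU family-sum conservation, 10,000 draws for
topology uniformity — were chosen as the smallest scales at which the
corresponding statistical tolerances are meaningful.

## Morphometrics

The range check uses inclusive bounds (a value exactly at a bound is
within range), and single-individual references — point values, not
ranges — are compared with a 5% relative tolerance by default, a
configurable acknowledgment that a point value is an informal range. The
shipped reference table reproduces the published comparison values
verbatim, keeping single-individual entries flagged via their `n` column
rather than inventing ranges for them. Principal-component analysis of
the morphometric data is deliberately out of scope; the range logic is
the asserted surface.

## Known limitations

* The GenBank reader is a minimal flat-file parser (LOCUS/FEATURES/ORIGIN,
  `complement`, origin-wrapping `join`) aimed at mitogenome records; it
  is not a general GenBank implementation and skips unknown feature keys
  with a warning.
* Reproducing published distance *matrices* from accession sets requires
  the sequences and an alignment step; alignment choice introduces
  uncertainty that no distance implementation can remove. The package
  ships the engine and its simulation-based validation, not the
  alignments.
* MCL fitting assumes the alignment is informative enough for the shared
  rate ratios to be identifiable; for a single near-identical pair the
  ratios are weakly constrained (the distance itself remains stable).
* NJ is a point estimator: clamped zero-length branches and Q-ties are
  resolved deterministically rather than enumerated.
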