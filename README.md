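# mitophylo

Tidy tools for characterizing annotated mitochondrial genomes and testing
species distinctness with distance-based phylogenetics.

Small mammals — bats in particular — are full of cryptic species whose
morphology is ambiguous but whose mitochondrial genomes are not. The
standard evidence chain runs: assemble and annotate a mitogenome; summarize
its organization (gene inventory, base composition, strand skews, codon
usage); concatenate protein-coding genes across congeners into a
supermatrix; compute pairwise genetic distances under a substitution model;
and ask whether the focal taxon sits closer to its putative synonym than to
other congeners. `mitophylo` implements that chain as composable, tested R
functions, together with a simulation module that generates every input
with known ground truth, and a morphometric helper for the companion
external-measurement comparison.

## What it computes

* **Genome organization.** GenBank flat files or tab-separated feature
  tables become a `mito_genome`: 1-based inclusive coordinates, H/L
  strands, circular wrap-around features, and the canonical 37-gene
  vertebrate layout (13 PCGs, 22 tRNAs, 2 rRNAs + control region).
  L-strand genes are reverse-complemented on extraction so codon logic
  always reads the coding sense.
* **Composition and skews.** Per-feature and whole-genome base
  fractions, with the strand-asymmetry statistics
  AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C).
* **Codon usage and RSCU** under the vertebrate mitochondrial code
  (AGA/AGG stop, AUA = Met, UGA = Trp), honoring incomplete stop codons
  (`TA-`, `T--`) completed by mRNA polyadenylation. RSCU of a codon is its
  count divided by the mean count of its synonymous family, so values sum
  to the family size k.
* **Distances.** p-distance, the closed-form Tamura–Nei (1993) distance,
  and maximum composite likelihood (MCL) TN93 distances in which the two
  transition/transversion rate ratios are shared across all pairs and
  estimated by maximizing the summed pairwise log-likelihood — all under
  pairwise deletion.
* **Trees.** Saitou–Nei neighbor joining (exact on additive matrices,
  deterministic tie-breaking, negative branches clamped to zero) with
  nonparametric site-bootstrap support, returned as `ape::phylo`.
* **Simulation.** Uniform random unrooted topologies, TN93 sequence
  evolution via the exact transition-probability matrix, and synthetic
  annotated circular mitogenomes whose declared start/stop codons are
  genuinely present in the sequence.
* **Morphometrics.** Range checks of specimen measurements against
  published species reference ranges with inclusive bounds.

## Worked example

The package ships the published organization table of the *Myotis
aurascens* mitogenome (accession OK053029) as a fixture, loadable without
the sequence itself:

```r
library(mitophylo)
g <- maurascens_genome()
g
#> <mito_genome> OK053029 Myotis aurascens mitogenome
#>   circular, 16771 bp, 38 features (sequence-free)
#>   control_region: 1, PCG: 13, rRNA: 2, tRNA: 22

class_totals(g)
#> # A tibble: 4 × 4
#>   class          n_features total_bp pct_genome
#> 1 PCG                    13    11405      68.0
#> 2 control_region          1     1313       7.83
#> 3 rRNA                    2     2534      15.1
#> 4 tRNA                   22     1514       9.03
```

The 13 protein-coding genes cover 11,405 bp — 68.0% of the 16,771-bp
molecule — and the 22 tRNAs 1,514 bp. Composition and skews per feature
and genome-wide:

```r
comp <- genome_composition(g)
dplyr::filter(comp, name %in% c("COX1", "ND6", "Total")) |>
  dplyr::select(name, size, at_content, at_skew, gc_skew)
#>   name   size at_content at_skew gc_skew
#> 1 COX1   1545       62.5 -0.134   -0.100
#> 2 ND6     525       67.6 -0.285    0.588
#> 3 Total 16771       64.9  0.0461  -0.262
```

The genome is AT-rich (64.9%) with a weak positive AT skew (0.046) and a
strong negative GC skew (−0.262); among the PCGs only ND6 — the one
L-strand protein gene — has a positive GC skew. `autoplot(comp)` draws the
per-gene skew profile.

A full distance-and-tree run on simulated data with known truth:

```r
cfg <- sim_config(seed = 42, n_taxa = 6, seq_length = 8000)
tr  <- simulate_tree(cfg)
aln <- evolve_sequences(tr, cfg)
res <- run_distances(list(supermatrix = aln), exclude = character(),
                     bootstrap = 100, seed = 1)
glance(res$mcl)
#>   estimator n_taxa   min  mean   max n_missing
#> 1 mcl            6 0.158 0.461 0.831         0
```

`res$combined` is the journal-style square table (model distances above
the diagonal, p-distances below), `res$tree` the NJ tree with bootstrap
percentages on its internal edges — here both internal splits of the
generating topology are recovered with 100% support. The morphometric
companion check:

```r
glance(range_check(morpho_specimen(), morpho_reference(),
                   species = "M. aurascens", source = "Kim"))
#>   species      n_indices n_within n_below n_above n_no_reference fraction_within
#> 1 M. aurascens        19        5       3       0             11           0.625
```

The three below-range indices are tibia, tail and tragus length — the
specimen is otherwise inside the species' signature ranges.

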