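# teepi

Inference of epigenetic effects of polymorphic transposable element (TE)
insertions from multi-strain ChIP and RNA data.

A TE that is present in some genomes of a panel and absent in others is a
natural experiment: if the insertion recruits or depletes a histone mark,
the *homologous flanking sequence* should differ in ChIP fold-enrichment
between carrier and non-carrier genomes, close to the insertion and only
in carriers. `teepi` implements that comparison end to end for H3K9me3
(repressive) and H3K27ac (active):

* **Breakpoint projection** — locate each TE's insertion junction in the
  genomes that lack it, from the placements of its ±500 bp flanks (unique
  placements, gap/overlap within ±50 bp).
* **Window profiles** — binned fold-enrichment (10 bp bins, replicates
  averaged) in 20 × 1 kb windows per side, anchored at the TE edges in
  carriers and the junction in non-carriers.
* **Effect calls** — per strain pair, two-sided Wilcoxon rank-sum tests
  per window give the percentage change
  `P = 100 (median₊ − median₋)/median₋` in the innermost ±1 kb and the
  spread `S` = longest consecutively significant run of windows, minimized
  over sides; a consensus across pairs (at most one deviating pair) yields
  the per-TE call for each body part × mark, including bivalent/mix
  combinations of the two marks.
* **Expression linkage** — TMM-normalized counts; genes within `S` kb of a
  called TE get `z = (mean₊ − mean₋)/√(SE₊² + SE₋²)`, significant at
  `|z| ≥ 1.96`.
* **Null models** — permutation tests against positionally matched random
  TE sets and against TE-free control regions (no TE within 1 kb), with
  add-one empirical p-values; family-level χ² proportion tests.
* **Synthetic cohorts** — a deterministic generator (strains, genomes,
  planted boxcar enrichment/depletion kernels, negative-binomial counts
  with TE-linked shifts) records its ground truth so the whole chain is
  testable without any external data.

## Worked example

Fifty polymorphic TEs across five strains, one body part and one mark,
with planted effects; the pipeline projects breakpoints, calls effects,
and links genes:

```r
library(teepi)
spec <- cohort_spec(n_te = 50, seed = 42, body_parts = "gut",
                    marks = "H3K9me3")
res <- run_pipeline(spec, "teepi_demo")
res$summary
#>       class    mark body_part percentage spread  n
#>   depletion H3K9me3       gut  -40.22258      3 10
#>  enrichment H3K9me3       gut   50.66008      3 16
```

The summary recovers the generator's planted magnitudes (+50% enrichment,
−40% depletion, 3 kb spread). Per-link expression z-scores carry the
expected signs — more H3K9me3 near a gene, lower expression:

```r
head(res$links[, c("te_id", "gene_id", "class", "positional_category",
                   "z", "direction")], 5)
#>  te_id gene_id      class positional_category           z direction
#>  te004   g0004 enrichment              intron -18.2398174      down
#>  te007   g0043 enrichment            upstream   1.7990389      none
#>  te010   g0008  depletion            upstream   4.7842480        up
#>  te011   g0047 enrichment          downstream   0.3543083      none
#>  te012   g0010 enrichment          downstream  -2.8191627      down

mean(res$breakpoints$status == "unique")
#> [1] 1
```

Every insertion junction was projected uniquely at the true position. All
result tables (`effect_calls.tsv`, `pair_calls.tsv`, `te_gene_links.tsv`,
`family_tests.tsv`, `summary.tsv`, `quadrant_counts.tsv`) plus a manifest
are written to the output directory; reruns with the same spec are
byte-identical.

A thin CLI wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/teepi.R", package="teepi"))')" \
    run --config cohort.yaml --seed 4 --out-dir results/
```

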