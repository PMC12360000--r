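---
title: "Detecting epigenetic effects of polymorphic TE insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epigenetic effects of polymorphic TE insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

A transposable element (TE) insertion present in some genomes of a
population and absent in others offers a natural experiment: if the
insertion nucleates or depletes a chromatin mark, the flanking sequence —
which is homologous between carrier and non-carrier genomes — should differ
in ChIP fold-enrichment only in the carriers, and only near the insertion
point. `teepi` implements this comparison for the repressive mark H3K9me3
and the active mark H3K27ac across a small panel of strains profiled in
several body parts, and links the chromatin changes to expression changes
of nearby genes.

The chain has five stages:

1. **Breakpoint projection.** For each polymorphic TE, the ±500 bp flanks
   are taken from a carrier genome and located in each non-carrier genome.
   A junction is accepted only when the upstream, downstream, and
   concatenated flank each place uniquely and the signed gap/overlap
   between the two flanks is within ±50 bp. This gives the anchor point in
   genomes that lack the TE.
2. **Window profiles.** ChIP fold-enrichment, averaged in 10 bp bins and
   then across replicates, is collected in 20 non-overlapping 1 kb windows
   on each side of the anchor: the TE's outer edges in carriers, the
   projected junction in non-carriers. Anchoring at the edges excludes the
   TE body itself, so window *i* on a given side covers homologous flank
   sequence in both genomes.
3. **Effect calling.** For every carrier × non-carrier strain pair,
   window *i* of the carrier is compared to window *i* of the non-carrier
   with a two-sided Wilcoxon rank-sum test on the ~100 bin values per
   window. Two statistics summarize a pair: the **percentage change**
   `P = 100 (median+ − median−)/median−` over the pooled bins of the two
   innermost (±1 kb) windows, and the **spread** `S`, the longest run of
   consecutively significant windows with a common direction starting at
   window 1, minimized over the two sides (the conservative choice when the
   sides disagree). A pair is *enrichment* (*depletion*) when window 1 is
   significantly higher (lower) on both sides; *none* when either side's
   window 1 is not significant; missing when tests are unavailable or the
   sides contradict each other. A TE-level call per body part × mark then
   requires all pairs but one to agree (the single allowed deviation may be
   a different class or missing data); anything less concordant is
   excluded. `P` and `S` are averaged over the concordant pairs.
4. **Expression linkage.** Counts are TMM-normalized; genes overlapping a
   called TE or within `S` kb of its edges are linked to it, and each link
   receives `z = (mean+ − mean−)/sqrt(SE+² + SE−²)` comparing the gene's
   normalized abundance between carrier and non-carrier samples of the
   same body part. `|z| ≥ 1.96` is called significant.
5. **Null models and family tests.** A positional permutation test asks
   whether the expression effects of TEs with chromatin effects exceed
   those of random TE sets matched by position relative to genes
   (intron/UTR/CDS/upstream/downstream); TE-free control regions (no TE
   within 1 kb, category- and length-matched) put strain-level epigenetic
   variation on the same footing; per-family χ² goodness-of-fit tests ask
   which TE families are over-represented among effect-carrying copies.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `flank_bp` | 500 | bp | flank length for breakpoint projection |
| `breakpoint_tolerance_bp` | 50 | bp | max gap/overlap between projected flanks |
| `window_bp` × `n_windows_per_side` | 1000 × 20 | bp | profile geometry (±20 kb) |
| `bin_bp` | 10 | bp | signal resolution; must divide `window_bp` |
| `alpha` | 0.05 | — | per-window significance (no multiplicity correction, matching the source analysis) |
| `min_bins_per_window` | 50 | bins | below this the window test is missing |
| `z_threshold` | 1.96 | — | expression-link significance |
| `n_permutations` | 1000 | draws | null sampling depth; p ∈ [1/1001, 1] |
| `loess_span` | 0.10 | fraction | metaprofile smoothing |
| `min_copies_family`, `min_effect_copies_family` | 20, 8 | copies | family-test eligibility |

Geometry and thresholds default to the study design the package targets;
all are configurable through `teepi_config()`.

## What the synthetic cohort emulates — and what it does not

`cohort_spec()`/`generate_cohort()` build a deterministic cohort from a
seed: 5 strains, 3 body parts, 2 marks, 3 replicates by default. TEs are
drawn from a small library of synthetic families, every insertion is
polymorphic, and carrier/non-carrier genomes share the ancestral sequence
so that flank homology is exact. Signal is lognormal around a
fold-enrichment of 1.0 (`signal_sdlog = 0.2` by default); a planted effect
multiplies the bins within `spread_kb` of the TE by `1 + percentage/100`
with a hard-edged boxcar kernel. Defaults plant +50% enrichment and −40%
depletion over 3 kb — magnitudes inside the ranges reported for natural
insertions. Expression is negative-binomial (dispersion 0.1) with
per-sample depth factors; genes linked to an affected TE shift by ±1 log2
unit in carriers, signed by the mark's biology (more H3K9me3 → down, more
H3K27ac → up).

Deliberate simplifications: the boxcar kernel gives the spread estimator
an unambiguous true value, where real marks decay gradually; baseline
signal is spatially homogeneous, with none of the chromatin-domain
structure, mappability gaps, or strain-level variation of real tracks;
genomes are isolated single-chromosome sequences with TEs spaced ≥ 40 kb
apart, so profile windows never overlap a second insertion; expression
effects are planted directly rather than mediated by chromatin. Passing
the planted-truth checks therefore demonstrates that the inference chain
is correct and calibrated — not that real cohorts will show effects this
cleanly. Quantities that depend on the real data's noise structure (the
published per-body-part counts and averages) are out of reach of the
generator by design.

## Numerical choices

* **Rank-sum units.** The Wilcoxon samples are the replicate-averaged
  10 bp bin values within a window (~100 per genome). Bins give the test
  within-window replication; the alternative of testing replicate means
  would leave n = 3. The implementation uses the exact distribution for
  tie-free samples under 50 per group and the tie-corrected,
  continuity-corrected normal approximation otherwise — the same decision
  rule as `stats::wilcox.test`, which the unit tests cross-check, with an
  independent enumeration oracle at small n.
* **Direction.** Two-sided tests with post-hoc direction from the rank
  shift, so enrichment and depletion are detected symmetrically.
* **Percentage.** Bins of the two innermost windows are pooled before the
  medians (a per-side variant is available). A zero non-carrier median
  leaves `P` undefined and the pair missing.
* **Missing data.** Missing signal stays missing (never zero); a window
  with fewer than 50 usable bins on either side yields no test; a missing
  window-1 test or contradictory window-1 directions make the pair
  missing, which the consensus rule counts as a deviation.
* **Consensus ties.** With two pairs split 1–1 between an effect class and
  `none`, the effect class wins (its deviation is the allowed one); a tie
  between enrichment and depletion is contradictory and excludes the TE.
  `P` and `S` aggregate across concordant pairs by the mean.
* **Junction position.** When the projected flanks leave a gap or overlap,
  the called breakpoint is the midpoint, rounded toward the upstream side;
  any point inside the tolerance interval would be defensible.
* **Breakpoint uniqueness.** "Unique mapping" is operationalized as
  exactly one primary placement with mapping quality ≥ 30 covering ≥ 80%
  of the flank. The built-in exact-substring mapper synthesizes a spanning
  placement for the concatenated flank from unique up/down placements, so
  junction indels are adjudicated by the ±50 bp rule rather than failing
  as unmapped.
* **Permutation p-values.** Add-one empirical p,
  `(1 + #{null ≥ obs})/(N + 1)`, sampling without replacement within a
  draw; each null draw reproduces the focal set's positional-category
  histogram exactly. The permutation statistic is configurable (proportion
  of significantly downregulated links by default; mean-z as a continuous
  alternative used for calibration checks, where the discreteness of a
  proportion would confound uniformity diagnostics).
* **Replicate aggregation** is the mean (median available), applied
  per bin; averaging commutes with window slicing, which is tested.
* **LOESS** metaprofile smoothing is degree-1 with tricube weights and
  span 0.10 of the offsets; a constant profile is reproduced exactly.

## Validation problem sizes

The test suite validates the chain on cohorts of 200 TEs (5 strains, one
body part × one mark, 3 replicates, `signal_sdlog = 0.2`): planted +50%
enrichment over 3 kb is recovered with ≥ 90% sensitivity, ≤ 5% false
calls, percentage error ≤ 10 points and spread within ±1 kb — in practice
the margins are much wider — while an effect-free cohort yields ≤ 1%
calls. Breakpoint projection is exercised on 100-TE cohorts (100% unique
junctions at the true position; a planted 60 bp junction indel is
rejected). Permutation calibration uses 200 repetitions at N = 1000.
These sizes were chosen so the whole suite runs on a laptop in about a
minute while leaving the statistical margins interpretable.

## Known limitations

* The consensus rule's "all pairs but one" criterion becomes strict as
  the number of strain pairs grows; with many strains a proportion-based
  rule would scale better.
* TEs significant on only one side of the insertion are called `none` by
  the min-rule; genuinely asymmetric spreading is therefore conservative.
* The positional classifier assigns one category per TE-gene pair from
  the gene model; overlapping isoforms are not resolved.
* Family tests are χ² against the cohort-wide proportion, not a mixed
  model; families with correlated insertions (shared local chromatin)
  will look more significant than they should.
* Real-data input is limited to the formats the package reads (BED6+,
  bedGraph, GFF3, PAF, TSV); BigWig must be converted upstream.
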