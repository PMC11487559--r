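---
title: "Scoring T cell functional states with TStateScore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring T cell functional states with TStateScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TStateScore)
```

## The problem

T cell compartments of the same nominal subtype can sit in very different
functional states — resting, proliferating, cytotoxic, exhausted, senescent.
Deconvolution tools estimate *how many* T cells of each subtype a bulk
RNA-seq sample contains; they do not say *what state* those cells are in.
TStateScore quantifies eight functional states — Quiescence, Regulating,
Proliferation, Helper, Cytotoxicity, Progenitor exhaustion, Terminal
exhaustion, Senescence — in each individual sample, from a TPM expression
matrix, a marker gene set per state, a housekeeping gene list, and a
single-cell derived reference spectrum.

## The model

Scoring one state in one sample proceeds in five steps.

**1. Log transform.** All TPM values are mapped to `log2(TPM + 1)`.

**2. Housekeeping normalization.** With `HKbar_j` the mean log2 expression of
the housekeeping genes present in sample *j*, sample *j*'s column is
multiplied by `mean_j(HKbar_j) / HKbar_j`. Afterwards every sample has the
same mean housekeeping expression (the pre-correction global mean), which
makes the reference-weight comparison below meaningful across samples with
different global expression levels. The correction is idempotent, and its
per-sample factors are kept in the result metadata for audit. We apply it on
the log2 scale, after the transform, so that "mean housekeeping expression"
refers to the same scale the ranks and weights use. Housekeeping genes
absent from the matrix are ignored with a warning; fewer than `minHK`
(default 50) present genes is an error, because a correction estimated from
a handful of genes is noise.

**3. Stratified background.** To put marker ranks on a fixed denominator,
genes are ordered by pooled expression (mean corrected value across
samples), split from high to low into 50 contiguous bins, and 100 genes are
drawn uniformly without replacement from each bin — 5000 background genes in
total, drawn once per run from a user-supplied seed and shared by all eight
states and all samples. Pooling the ordering statistic makes the background
identical for every sample, which a shared rank matrix requires. Stratifying
keeps the background's expression distribution representative of the whole
matrix, so the rank null is not dominated by silent genes. At score time the
current state's markers are removed from the background (a gene must not be
both signal and null) and the panel size adjusted accordingly.

**4. Rank score.** Within each sample the combined background-plus-marker
panel is ranked (ascending, average ties). With `n` markers, `m` background
genes and `R_i` the marker ranks, the Mann–Whitney statistic is

> U = Σ R_i − n(n+1)/2

and the default **unit** normalization is `U / (n·m)`: the probability that
a randomly chosen marker outranks a randomly chosen background gene, ties
counted half. It is bounded by construction — `U = 0` when all markers rank
below all background genes, `U = n·m` when they rank above — so scores live
in [0, 1], the range the method promises. A second normalization,
`mode = "printed"`, divides by `N = n + m` instead; it reproduces the
method's defining formula literally but is not bounded by 1 (for the
default panel, `U` can reach `n·m ≈ n·5000` while `N ≈ 5000`, i.e. the
printed quotient can reach ≈ `n`). Because the score range and every
downstream use assume [0, 1], the unit normalization is the default and the
printed divisor is kept behind a flag for formula-level reproduction. The
two modes are strictly monotone transforms of each other (`unit =
printed · N / (n·m)` with fixed `n`, `m`), so orderings, AUCs and dominance
calls within a state do not depend on the choice.

**5. Reference weighting.** A high rank score should reflect broadly
elevated markers, not one extreme outlier. Each marker's corrected
expression `sp_i` is compared with its level `ref_i` in the reference
spectrum — per-state average expression profiles of sorted single cells —
and contributes a weight of 1 if `sp_i ≥ ref_i`, else `sp_i / ref_i`. The
final score is the rank score times the mean weight, so it can never exceed
the rank score and a sample must approach the reference spectrum marker by
marker to keep its score. The spectrum is supplied on the TPM scale and is
placed on the log2(TPM+1) scale before the comparison, since `sp_i` comes
from the log-scale corrected matrix; comparing a log quantity to a linear
one would be dimensionally inconsistent. No housekeeping correction is
applied to the reference (it is a single fixed profile, not a cohort
member). A marker with `ref_i = 0` gets weight 1: an absent reference level
cannot penalize, and `sp = ref = 0` already falls in the `sp ≥ ref` branch.

All five steps run per state and per sample via `scoreTCellStates()`, which
returns a `TCellScores` object (states × samples) carrying the seed,
normalization mode, effective marker counts and a warnings log.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nBins`, `perBin` | 50, 100 | background strata and genes per stratum (5000 total ranks); shrink automatically, with a warning, when the matrix is small |
| `seed` | 1 | fixes the background draw; always recorded in the result |
| `mode` | `"unit"` | rank-score normalization (see step 4) |
| `minHK` | 50 | least housekeeping genes that must be present |
| `strict` | `FALSE` | whether a state with < 2 present markers errors instead of being skipped |

Marker matching is exact string equality after whitespace trimming. No
gene-alias resolution is attempted — alias maps are annotation-version
dependent, so harmonizing identifiers is deliberately the user's
responsibility. Duplicate gene rows in expression input are summed on load:
such duplicates usually arise from transcript-level quantification collapsed
to gene level, where abundances are additive.

## Edge cases and numerical choices

* Ties in expression get average ranks (the Mann–Whitney convention); ties
  are common after log transformation of zero-inflated data, and the
  brute-force pairwise interpretation (ties count half) holds exactly.
* If the matrix cannot host `nBins × perBin` background genes next to the
  largest marker set, `perBin` shrinks to `floor((G − maxSet)/nBins)`; an
  effective per-bin draw below 5 is refused.
* Markers absent from the matrix are dropped from both the rank score and
  the weight mean; the effective count is recorded. Below 2 present markers
  a state is skipped (or errors under `strict`), because a rank score over
  one gene is not an enrichment statistic.
* One background draw per run, shared by all states and samples, keeps the
  eight scores of one sample comparable; the per-state panel removes that
  state's markers from the background. Whether the upstream method draws
  once per dataset or per state is not documented; drawing once and
  exposing the seed makes the choice visible and reproducible, and the
  stability test below shows sample orderings are insensitive to it.
* Argmax ties in dominance calls break by the canonical state order
  (`canonicalStates()`) and are flagged.

## Pseudo-bulk construction and the reference builder

`makePseudobulk()` emulates purified bulk samples from labelled single
cells: a subtype with *c* cells yields `max(1, floor(c/5))` pseudo-bulk
samples, each the per-gene arithmetic mean (linear scale, no
re-normalization — pre-normalize cells if desired) of `ceiling(0.6·c)` cells
drawn without replacement. The 60% draw is read as sampling without
replacement; drawing with replacement would be an unusual reading of
"selecting 60% of the cells". Ceiling on the draw size guarantees at least
one cell; floor with a minimum of 1 on the replicate count keeps tiny
subtypes represented. `buildReference()` averages the cells mapped to each
state; any upstream refinement of labels (e.g. splitting exhausted cells
into progenitor and terminal stages along a pseudotime trajectory) is
supplied through its `stateMap` argument rather than re-derived here, and
dropout imputation of the single-cell input is likewise out of scope.

## What the synthetic generator does and does not emulate

`simulateCohort()` produces a self-consistent bundle: gene baseline means
drawn on the log2 scale from Normal(1, 1) (a log-normal TPM profile — the
skewed dynamic range the 50-bin stratification assumes), one planted
dominant state per sample with that state's markers shifted up by a log2
effect size, housekeeping genes with inter-sample SD 0.01 (so correction
factors sit near 1 unless a library-size distortion is planted via
`sampleScaleSD`), and a reference spectrum equal to the generator's own
state-mean profiles. Gene-level noise SD defaults to 0.5 log2 units,
a typical between-replicate spread for bulk RNA-seq.

The generator emulates bulk cohorts with clean, disjoint marker blocks. It
does **not** model scRNA-seq dropout or overdispersed counts, correlated
marker modules, partially overlapping marker sets between states, or
annotation noise. Tests passing on these fixtures therefore demonstrate the
algorithm's arithmetic, determinism, calibration and discrimination under
its own assumptions — not performance on any real cohort, which depends on
marker-set quality and identifier harmonization.

Default problem sizes used by the test suite are deliberately modest
(cohorts of ~1,200–2,600 genes with 10–25 background bins for most
properties; a 12,000-gene cohort with the full 50 × 100 background for the
seed-stability check; 100 cohorts of 8,000–15,000 genes in the acceptance
script): they are the smallest sizes at which every property is
scale-representative.

## Evaluation utilities

`rocAUC()` computes AUC by the rank formula — the probability a positive
sample outscores a negative one, ties half — which is the same statistic the
scores themselves are built on. `dominantStateProportions()` reproduces
dominant-state composition profiling per group. `compareGroups()` wraps a
two-sided Wilcoxon rank-sum test per state (exact when the combined n ≤ 20,
normal approximation with continuity correction above); raw p-values are
reported by default, with a Benjamini–Hochberg column behind `adjust =
TRUE`, since the classic use reports per-state significance without
correction across the eight states.

## A worked example

```{r example}
sim <- simulateCohort(nGenes = 2000, nSamples = 8, markersPerState = 6,
                      hkCount = 150, effectSize = 3, seed = 7)
res <- scoreTCellStates(sim$expression, sim$markers, sim$reference,
                        sim$housekeeping, seed = 7, nBins = 10, perBin = 50)
round(stateScores(res)[, 1:4], 3)
dominantStateProportions(res, sim$truth)$proportions
```

## Known limitations

* Scores are single-sample but not single-cell: applying the pipeline to
  raw scRNA-seq columns is untested territory because dropout distorts the
  rank null.
* The eight states are scored independently; no joint model enforces, e.g.,
  that Quiescence and Proliferation trade off.
* Everything downstream of the inputs assumes the marker sets, housekeeping
  list and reference spectrum use the same gene identifier namespace as the
  expression matrix.
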