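---
title: "tiledep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tiledep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiledep)
```

## The problem

When an essential ribonuclease such as *B. subtilis* RNase Y is partially
depleted, transcripts it normally cleaves become more stable and accumulate,
while a smaller set of transcripts drops through indirect (regulatory or
physiological) effects. Strand-specific tiling microarrays measure this
genome-wide: probes every 22 nt on both strands, duplicate cultures of an
IPTG-inducible depletion strain grown with (induced, reference) and without
(depleted) inducer. `tiledep` implements the downstream statistical pipeline
for this design — aggregation, normalization, testing, threshold selection,
cross-study comparison, category enrichment, the expression-level projection
of direct versus indirect effects, and half-life estimation from rifampicin
chases — together with a synthetic-data generator so every stage can be
exercised against known ground truth.

## Pipeline model

### Aggregation

Probe-level log2 intensities are aggregated per annotated feature as the
median over same-strand probes whose position falls in `[start, end)`
(0-based, half-open everywhere internally; GFF3 input is converted, BED is
native). An even probe count gives the mean of the two middle values.
Features spanning no probe are masked (`NA`), never zero: absence of
evidence is not a zero intensity. Probes match features only on the same
strand — the arrays are strand-specific and antisense transcription is real
signal, not noise.

### Least-variant-set normalization

Between-array technical variation is removed against an anchor set of genes
whose *rank* is most stable across arrays: expression values are ranked
within each array, the per-gene variance of that rank across arrays is the
stability statistic, and the `lvs_fraction` (default 0.4, conservative
middle of published least-variant-set practice) of genes with the smallest
rank variance forms the anchor. Each array is then affine-corrected so the
least-squares regression of its anchor-gene values on the anchor baseline
(per-gene mean over arrays) has slope 1 and intercept 0.

Two implementation choices deserve notice:

* **Boundary trimming (`rank_trim`, default 0.05).** A gene at the very
  top or bottom of the expression range keeps its extreme rank no matter
  how strongly it responds to the depletion — rank variance is blind there.
  Without a guard, strongly regulated extreme genes enter the anchor set
  and their (systematically up-biased) effects leak into the per-array
  intercepts, shifting every fold-change downward — exactly the
  up/down-imbalance distortion this normalization exists to avoid. Genes
  whose mean rank lies within 5% of either boundary are therefore
  ineligible.
* **Fixed-point iteration.** A single affine pass changes the anchor
  baseline, so the single-pass operation is not idempotent on noisy data.
  The fit is iterated to its fixed point (tolerance 1e-12, a handful of
  passes in practice; one exact pass suffices on noiseless affine
  distortions), making normalization a projection: applying it twice equals
  applying it once to within 1e-9.

Note the global frame is unidentifiable: any common affine transform of all
arrays is invisible to a between-array method. "Distortion removed" means
the arrays agree with one another; fold-changes are preserved exactly when
the distortions average to the identity.

At small gene counts the rank statistic is coarse: an effect gene sitting
in a locally sparse stretch of the expression distribution may barely move
in rank and slip into the anchor set, shifting that run's fold-changes by
up to ~0.1 log2 units. This is a granularity limit of rank variance around
n = 100 and fades at genomic scale (thousands of genes); the recovery-bias
property is therefore stated about the mean over replicate simulations.

### Testing and the local FDR

Per gene, a pooled-variance two-sample t-test compares depleted against
induced log2 values (`df = n1 + n2 - 2`). Welch's correction is
deliberately not used: its df estimate is degenerate at n = 2 per group,
the duplicate-culture design this pipeline targets. A variance floor
(default 1e-8) keeps exact ties finite: identical groups give t = 0, p = 1,
and p-values are floored away from exactly 0.

P-values are converted to local false discovery rates. The null proportion
is estimated by censoring at λ = 0.5:
η₀ = min(1, #{p > λ} / ((1 − λ) m)). The marginal density f(p) is the
Grenander estimator — the slopes of the least concave majorant of the
empirical CDF — which is monotone non-increasing by construction, so
lfdr(p) = min(1, η₀ / f(p)) is monotone non-decreasing in p. A gene is
called differentially expressed iff lfdr ≤ 0.1 (inclusive): the
least-significant call still has at most a 0.1 probability of being a
false positive. The mean lfdr over the called set is the reported average
FDR. Below m = 100 p-values the density estimate is not usable and the
estimator returns all-ones with a warning.

The Grenander density has a known spike near p = 0 at finite m (the first
majorant segment can be steep by chance), so a pure-null dataset
occasionally yields a handful of tiny lfdrs; the type-I property is
therefore controlled in expectation, not per run.

### Amplitude threshold selection

Calls are further filtered by effect amplitude, max(FC, 1/FC). The
threshold is chosen from the curve of up% versus down% of the coding pool
over a cut-off grid (default 1.0–4.0 by 0.05, bracketing the 1.5x/1.6x/2x
choices of the three published studies). In the (down%, up%) plane the
curve of this design shows a slope break: above the knee up-effects
dominate, below it down-effects (held to be indirect) accumulate. The
detector fits a continuous two-segment least-squares model with the knot
grid-searched over interior curve points (≥ 3 points per segment) and
reports a break only when the two-segment fit improves the straight-line
RSS by ≥ 5% — a reproducible operationalization of what was originally a
visual judgment, and declared as such.

One numerical subtlety: above the knee the curve barely moves along the
down% axis, so many cut-offs map to nearly the same knot coordinate and the
RSS surface has a plateau. Knots within 30% of the minimum RSS are treated
as equivalent and the smallest cut-off among them — the onset of the
plateau, i.e. the knee — is reported. On noiseless two-segment curves the
detection is exact.

Final sets use inclusive boundaries: up iff called and FC ≥ 1.6, down iff
called and FC ≤ 1/1.6.

### Concordance, enrichment, projection, half-lives

* **Concordance**: gene identity is the case-folded locus tag; synonym
  resolution is the input's responsibility. Venn regions are computed per
  direction (up and down compared separately) and always partition the
  union (asserted at every call). The uniform-cut-off comparison re-derives
  each study's sets at a shared amplitude (default 1.5x), keeping a study's
  significance filter only where its table carries one.
* **Enrichment**: per-category up fractions are compared with the
  whole-genome reference fraction by an exact two-sided hypergeometric test
  (doubled smaller tail, capped at 1), Benjamini–Hochberg across categories,
  flags at q ≤ 0.05. The original tables flag categories without naming a
  test; this choice is a declared substitute and both the test and the
  correction are exposed in configuration.
* **Projection**: per regulation class, Gaussian kernel densities of the
  reference (induced-condition mean) log2 expression with kernel sd 0.5,
  each scaled by its class fraction so the scaled curves sum to the total
  density; fractions are evaluated only where the total density exceeds 1%
  of its maximum (tail guard). At the expression level x\* where the
  up-fraction peaks, under the working assumptions that indirect effects
  cause equal up- and down-regulation and all down-effects are indirect,
  `indirect share = 100·down(x*)/up(x*)` and
  `direct repertoire = up(x*) − down(x*)`.
* **Half-lives**: ordinary least squares of ln(intensity) on time after
  transcription arrest; t½ = ln 2 / (−slope); unweighted because no error
  model is given for band intensities; the pre-arrest t = 0 point is
  included by default with a flag to drop it. Slopes shallower than 1e-4
  per minute return a `not_measurable` sentinel. One-sided bounds (a
  reference half-life known only as "< 2 min") propagate as bound objects:
  the stabilization ratio against an upper bound is a lower bound, never a
  plain number.

## The synthetic world

The generator emulates the study design, not any particular dataset (no
raw arrays are packaged, and the publication names no accession in the
available text):

* 22-nt probe pitch on both strands; duplicate cultures per condition.
* Gene baselines Normal(10, 2) log2 units — placing the bulk of genes where
  the up-fraction of the real data peaks (near 10.5).
* Planted direct up-effects on 22.5% of features and indirect down-effects
  on 7.5% (matching 958 up / 310 down of 4244 coding genes); absolute log2
  effects Normal(1.2, 0.6) up and Normal(0.8, 0.4) down.
* Per-probe affinity offsets (sd 0.15, shared across arrays, cancelling in
  comparisons) and per-probe, per-array replicate noise (sd 0.1). The paper
  gives no noise magnitudes; these defaults are free parameters chosen at
  plausible microarray scale, not estimates of the real arrays.
* A hard saturation ceiling (14.5 log2 units, clipping ~1–2% of genes) —
  the simplest model of transcripts already near the dynamic-range limit,
  for which a further increase is undetectable. A hard clip, not soft
  compression, because the published observation is a detection ceiling.
* Decay series follow I(t) = i0·2^(−t/t½) with mean-one log-normal noise of
  stated CV, and a `"stable"` sentinel for non-decaying controls.

One master seed drives everything; each generator stage derives its own
child stream, so adding a stage never shifts the randomness of another, and
all outputs are bit-reproducible per seed.

What a green test does *not* establish: the generator has no
cross-hybridization, no dye or spatial artifacts, no probe-sequence (GC)
affinity structure, no operon correlation between neighboring genes, and
its noise is Gaussian by construction. Passing tests validate the
statistical machinery on data satisfying the design assumptions, not
performance on raw Nimblegen intensities.

For break-point validation the amplitude mixture plants a knee at 1.6:
1600 up-called genes with 60% of log2 amplitudes above log2(1.6) and 1280
down-called with 24% above (uniform within each side, amplitudes ≤ 4x) —
proportions derived from the published counts (2884 calls; 958 up and 310
down at ≥ 1.6x) and the observation that down-effects concentrate below the
threshold.

## Numerical choices and degenerate inputs

* Even-count medians: mean of the two middle values (standard).
* LVS ties: broken by gene id, making selection deterministic.
* t-test ties: variance floor + p = 1 for exactly equal groups; never p = 0.
* Break-point: none reported when points are collinear (relative RSS
  improvement < 5%) or fewer than 6 points are available (error).
* Density grid: 512 points spanning the data range ± 3 bandwidths; the
  truncated kernel mass is far below the 1e-3 quadrature tolerance.
* Readers accept comma decimal separators (as printed in the source
  tables); writers always emit periods. Missing values are `"NA"` in every
  TSV.
* All percentages print to one decimal. Note 169/1598 = 10.58%, which
  rounds to 10.6 — the commonly quoted 10.5% truncates the same ratio.

## Known limitations

* The exact least-variant-set variant and lfdr tool settings of the
  original analysis are in cited companion work; parameters here are
  declared defaults, not reconstructions, and the original 958/310/0.047
  numbers are not reproducible without the raw arrays (property-based
  substitutes are tested instead).
* Rank-variance LVS selection is coarse below a few hundred genes (see
  above).
* Only single-knot segmentation; no formal change-point inference.
* Whole-transcriptome profile reconstruction from raw hybridization data is
  out of scope: aggregation starts from probe intensities and a given
  annotation.
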