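---
title: "cnvseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cnvseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cnvseg re-implements a classical two-channel array-CGH copy-number
workflow as a tested, reusable pipeline: preprocessing of Cy3/Cy5
intensities into per-probe log2 ratios, least-squares change-point
segmentation, threshold-based five-way calling, cohort recurrence
analysis over minimal common regions, feature annotation and set
enrichment, and 2^-dCt qPCR validation analysis. This vignette explains
the model behind each stage, the tunable parameters, and the design
decisions taken where the workflow is conventionally under-specified.

## The measurement model

A tiling array interrogates the genome at (approximately) evenly spaced
probes — 2509 bp by default, the genome-wide density of the NimbleGen
720K-class whole-genome designs this package emulates. Tumor DNA is
labeled in one dye channel and pooled reference DNA in the other, and
the signal of interest at probe $i$ is the log ratio

$$ r_i = \log_2 \frac{T_i}{R_i}, $$

which is 0 for copy-neutral (diploid) probes, positive in gained and
negative in lost regions. Copy-number state enters only through the mean
shift of $r_i$; the package never converts to integer copies, because
the downstream calling rules are defined directly on mean log2 ratios.

Two systematic artifacts are modeled and removed:

* **Spatial non-uniformity.** Signal varies smoothly with the physical
  (x, y) position of a feature on the slide. `spatial_correct()` fits a
  locally weighted polynomial (LOESS) surface $f(x, y)$ to the log2
  ratios over the array grid and subtracts it, then restores the
  pre-correction global mean so the correction is exactly
  mean-preserving. Defaults are span 0.3 and local degree 2; the method
  is standard but its parameters are conventionally unreported, so they
  are exposed and documented rather than hidden.
* **Dye and distributional bias.** `qspline_normalize()` maps the
  quantiles of the test-channel log intensities onto those of the
  reference channel through a monotone cubic (Hyman-filtered) spline
  fitted at `n_anchors = 14` anchors placed at quantiles
  $k/(n_\mathrm{anchors}+1)$. A constant dye bias is absorbed exactly in
  the large-sample limit, and rank order is preserved by monotonicity.
  Outside the outermost anchors the mapping continues linearly with the
  boundary slope. This matters: anchoring the extremes (quantile 0 and
  1) instead would force the test channel's genuinely amplified tail
  onto the reference channel's noise-only extremes and compress real
  copy-number signal, which we observed as segment means biased toward
  zero.

### Order of operations, and centering

Spatial correction is applied first (on raw log2 ratios), folded back
into the test channel, and q-spline normalization second — with
`order = "qspline-first"` available as a switch, since the natural
intensity-domain definition of quantile normalization can also be read
as preceding ratio-level corrections. The invariant suite passes under
both orders.

After normalization the log2 ratios are median-centered
(`center = TRUE`). Quantile mapping between a CNV-carrying test channel
and a CNV-free reference both shifts and slightly attenuates the
baseline; because more than half of the genome is copy-neutral in the
regimes this pipeline targets, the median probe is diploid and centering
re-anchors log2 = 0 where the fixed calling thresholds assume it.
Re-centering segmented profiles is standard practice in aCGH analysis.

## Segmentation

`best_partition_sse()` computes, for a chromosome's ordered ratio series
$x_1,\dots,x_n$, the partition into $k$ contiguous segments minimizing

$$ \mathrm{SSE}(k) = \sum_{s=1}^{k} \sum_{i \in s} (x_i - \bar x_s)^2 $$

by an exact $O(kn^2)$ dynamic program on prefix sums (compiled code;
long-double accumulation). Ties are broken toward the lexicographically
smallest breakpoint vector, which makes results platform-deterministic.
An exhaustive-enumeration oracle over all partitions verifies exactness
for short series in the test suite.

The number of segments is chosen by `choose_k()` as
$k^* = \arg\min_k \mathrm{SSE}(k) + \lambda k$ with the BIC-like default
$\lambda = 2\hat\sigma^2\log n$. The noise scale $\hat\sigma$ is
estimated robustly from first differences,
$\hat\sigma = \mathrm{MAD}(\Delta x)/(\sqrt2 \cdot 0.6745)$, which is
insensitive to the segment structure itself. The penalty form and noise
estimator are this package's own choices — the published description of
the segMNT-style least-squares DP names no model-selection rule — and
both are configurable. On pure noise ($n = 500$, $\sigma = 0.15$) the
default penalty selects a single segment in at least 95% of seeded
replicates.

Before the DP, `segment_sample()` applies running-median outlier
smoothing (window half-width 5 probes; probes deviating more than
4$\hat\sigma$ from their local median are shrunk to median
$\pm 2\hat\sigma$), the same guard that mainstream CBS-based pipelines
apply before change-point search. Without it, quantile normalization
occasionally leaves isolated extreme probes inside high-level
amplifications that the DP fences off as one-probe segments. Segment
means and SSE are always reported on the unsmoothed values. The DP
itself carries no minimum-segment-length constraint; length filtering is
purely post hoc, in the calling stage.

## Calling

Segments are retained when they span at least 5 consecutive probes and
$|\bar r| \ge 0.25$; retained segments are classified by mean log2
ratio, all bounds inclusive:

| mean log2 ratio | class |
|---|---|
| $\ge 1.0$ | amplification |
| $[0.25, 1.0)$ | gain |
| $(-0.25, 0.25)$ | unchanged |
| $(-1.0, -0.25]$ | loss |
| $\le -1.0$ | deletion |

Boundary unit tests pin the inclusivity of all four thresholds.
`call_sample()` finally merges same-class calls separated by at most
`min_probes - 1` probes: a gap that short could never have been a
retained segment of its own, so the two fragments are one biological
event that the change-point search happened to split.

## Cohort recurrence

`minimal_common_regions()` pools all samples' calls per chromosome,
partitions the covered footprint at the union of call breakpoints into
atomic intervals (via interval disjoining), counts **distinct samples**
per class on each atom, and merges adjacent atoms with identical count
vectors. Class nesting is applied when counting: an amplification call
also satisfies the gain criterion and a deletion call the loss
criterion, so one region can legitimately appear in both a gain and an
amplification summary with different frequencies.

Recurrent regions are those altered (gain or loss) in at least 50% of
samples, and the focal tables list amplification/deletion regions at
at least 20%. Both comparisons are inclusive, because published summary
tables of this design list rows at exactly the stated percentage.
Frequencies are computed over minimal common regions, not over any
sample's literal call intervals; with per-sample breakpoint jitter the
core of a shared region retains the full carrier count while its flanks
decay, which is the behavior the recovery tests assert.

## Annotation and enrichment

Gene and miRNA features are read from BED (0-based half-open on disk)
or GFF (1-based) via rtracklayer and held internally as 1-based
inclusive intervals, the convention used by the printed tables this
format mirrors; conversion happens only at file boundaries, and `"chr12"`
vs `"12"` naming is normalized away. A feature maps to a region iff
their closed intervals share at least one base pair, strand ignored; no
minimum-overlap fraction is imposed. `write_circos_tracks()` emits one
plain-text Circos data file per class with the conventional color
legend: gain = orange, loss = purple, amplification = red,
deletion = green.

Set enrichment is the exact hypergeometric upper tail
$P(X \ge k)$ computed in log space (`lchoose` + log-sum-exp), so small
p-values keep full relative precision; the test suite verifies 1e-10
relative agreement against direct rational summation over all parameter
tuples with universe size up to 60, and against `phyper`. An optional
EASE-style conservative variant (tail at $k-1$) is available behind a
flag, since the web tools this stage replaces use a jackknifed statistic
whose exact form is not published with the workflow. The default
universe is all features in the supplied annotation file, configurable
because the original tools' background is similarly unstated. Raw
p < 0.05 drives the reporting rule, with Benjamini–Hochberg adjusted
values always included alongside. Annotation clustering groups terms by
single-linkage over pairwise Cohen's kappa of membership vectors
(threshold 0.5); each cluster is represented by its lowest-p member
(p < 0.05 required, ties broken lexicographically) and scored by the
negative mean log10 p of its members.

## qPCR relative quantification

Triplicate Cts are averaged (missing replicates tolerated and flagged),
$\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{reference}$, expression is
$2^{-\Delta Ct}$, and the per-gene fold change is the ratio of group
mean expressions. Group comparison is a two-sided independent-samples
t-test on the expression scale — matching the validation design this
module mirrors — with Welch's correction by default (the equal-variance
variant is a flag, since the original analysis does not state which was
used). A dCt-scale test is available for users who prefer testing on the
additive scale.

## The synthetic-data generator

`simulate_cohort()` is the package's stand-in for FFPE tumor arrays: no
public raw data accompanies the workflow this package operationalizes,
so every stage is validated against simulated truth. The generator
emulates:

* an evenly spaced tiling layout with probes scattered over the array
  grid by a seeded permutation (so spatial artifacts are independent of
  genomic position — exactly the assumption LOESS correction makes);
* implanted truth regions with default shifts +0.4 (gain), +1.3
  (amplification), −0.4/−1.3 (loss/deletion), chosen to clear the
  0.25/1.0 calling thresholds with defined margins;
* per-probe ratio noise (default sd 0.15, chosen for testability — the
  noise level of real FFPE arrays is not published for this workflow),
  a shared per-probe affinity term giving both channels a realistic
  intensity spread that cancels in the ratio, linear spatial gradients,
  and a constant dye bias; the ratio noise is split symmetrically
  across the two channels so both stay positive by construction;
* cohort structure: each of 20 samples (the emulated study size)
  carries each recurrent region independently with its penetrance
  (defaults: one gain at penetrance 0.6, one amplification at 0.35),
  plus a Poisson number of private non-overlapping CNVs;
* qPCR Ct tables whose group dCt means are set to
  $-\log_2(\mathrm{expression})$, making the generator the exact
  inverse of the analysis pipeline at zero noise.

It deliberately does **not** model FFPE degradation, GC waves, probe
sequence effects, PCR duplication, or saturation. Passing tests
therefore demonstrate correctness of the algorithms under a clean
additive-noise model, not robustness to every artifact of archival
tissue; autosomes only by default, since a sex-matched pooled reference
makes sex chromosomes behave like autosomes in the ratio model anyway.

## Numerical choices and degenerate inputs

* DP cost terms accumulate in long doubles; the within-segment cost is
  clamped at 0 to absorb cancellation error.
* `estimate_noise_sd()` returns `NA` below 3 probes; `choose_k` then
  treats the penalty as 0.
* Outlier smoothing is skipped when $\hat\sigma = 0$ (noise-free data
  has no outliers) or when the series is shorter than the window.
* Degenerate quantile anchors (massively tied intensities) trigger a
  piecewise-linear fallback mapping with a warning.
* Probes with missing log2 ratios are dropped with a warning before
  segmentation; chromosomes with no probes are skipped with a warning.
* `kappa_similarity` is defined as 1 when both membership vectors are
  identical with degenerate margins.
* Ties everywhere (DP breakpoints, smallest k, representative terms)
  break deterministically (lexicographic / smallest-first).

## Problem sizes in the test suite

The recovery studies run on two 1000-probe chromosomes (2509-bp
spacing) with 20-sample cohorts; the segmentation oracle enumerates all
partitions of 200 series of length up to 15; hypergeometric exactness
is swept over all universes up to N = 60; q-spline behavior is checked
at n = 10,000 probes. These sizes exercise every code path at full
statistical fidelity while keeping the default suite quick to run.

## Known limitations

* Recurrence frequencies from real cohorts depend on per-sample
  breakpoint jitter; only the stable core of a shared region attains
  the full carrier frequency.
* The q-spline mapping assumes the two channels should share a
  distribution; genomes with a very large altered fraction (well beyond
  half) would defeat both the mapping and the median-centering step.
* Boundary localization at gain-level contrast (shift 0.4 vs noise
  0.15) is accurate to ±2 probes for most but not all boundaries; this
  is the exact maximum-likelihood limit of the least-squares model, not
  an implementation artifact.
* Enrichment p-values are exact hypergeometric values, not
  reproductions of any specific web tool's jackknifed variant.
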