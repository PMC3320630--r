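---
title: "Methods: discovering plasma-detectable placental RNA markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering plasma-detectable placental RNA markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmapanel)
```

## The problem and the model

Spontaneous preterm birth is hard to study in predelivery samples because
markers measurable before delivery, in material comparable to
gestational-age-matched controls, are scarce. The placenta releases
cell-free RNA into the maternal circulation, so a placental transcript that
is (a) aberrantly expressed in the complication and (b) expressed highly
enough to be detectable in plasma is a candidate blood-borne marker. This
package implements that two-criterion screen and the downstream statistics,
with a synthetic-data generator standing in for the microarray and qPCR
instruments.

Signals are modelled log-normally: the log2 intensity of probeset $i$ in
sample $j$ is

$$x_{ij} = b_i + \delta_i\,\mathbb{1}[j \in \text{case}] + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with per-probeset baseline $b_i \sim N(\mu_b, \sigma_b^2)$ and
$\delta_i = \pm\log_2(\text{FC}_i)$ for the planted differentially
expressed probesets (0 otherwise). Spike-in control probesets have
$\delta = 0$ by construction; the reference probeset's baseline is pinned
at $\log_2(408)$ so its control-group median sits at 408 linear intensity
units. The matrix is emitted on the linear scale, as an instrument would.

## Stage-by-stage choices

**Quantile normalization.** Each column is ranked, values are replaced by
the across-column means of the order statistics, and ranks are restored;
ties receive the mean of the candidate quantile values (linear
interpolation at the midpoint rank). Signals then move to
$\log_2(x + 1)$; the +1 offset guards zeros and never touches the
panel-selection stage, which thresholds the *linear* matrix. Probe-level
preprocessing (background convolution, median-polish summarisation) is out
of scope because the pipeline's inputs are already probeset summaries; the
provenance note on the normalized matrix records exactly what was applied.

**Differential expression.** The Mann–Whitney test takes the exact
enumeration path when the smaller group has at most 8 observations
(configurable) and the pooled values are tie-free; the exact null of the
$U$ statistic is built once per group-size pair by dynamic programming and
cached. Otherwise the normal approximation with tie and continuity
corrections applies. Note that quantile-normalized columns share one value
multiset, so across-sample ties occur whenever two samples give a probeset
the same rank — a sizeable fraction of rows legitimately takes the
corrected-approximation path. Fold-change is the ratio of group medians on
the linear scale, $2^{\tilde{x}_\text{case} - \tilde{x}_\text{control}}$
— robust, and consistent with the rank-based test; the testing universe
excludes spike-in and reference probesets. With 5 arrays per group the
smallest attainable exact two-sided p is $2/252 \approx 0.0079$, which can
never clear BH adjustment across thousands of probesets; the package's
default synthetic study therefore uses 8 per group, where the floor is
$2/12870$.

**Thresholds.** Both screening thresholds are strict inequalities:
fold-change must exceed the largest spike-in fold-change magnitude
($T_{fc}$), and a probeset's case-group median linear signal must exceed
the reference probeset's control-group median ($T_{expr}$). A probeset
sitting exactly at either threshold is excluded. The case-group *median*
(not per-sample signals) defines "highly expressed"; this is the
convention the recount oracle in the tests pins down.

**Panel collapse.** Intersection happens at the probeset level — a
probeset must itself be both aberrant and highly expressed to carry its
gene into the panel — and genes collapse afterwards, with the arithmetic
mean of member fold-change magnitudes (the plain reading of "average
fold-change"). Transcripts without an approved gene symbol are keyed by
accession. Genes whose member probesets disagree in direction are excluded
with a warning rather than averaged across signs.

**GO over-representation.** List size $n$ and background size $N$ are
category-specific: a gene counts toward a category's totals only if it
carries at least one term of that category, which is why BP, MF and CC
totals differ. The default test is the EASE variant (upper-tail
hypergeometric with $k-1$ in place of $k$), the conservative choice
associated with the DAVID toolchain; the classic hypergeometric tail is
available by flag because the toolchain's exact internal variant is not
recoverable — fold-of-enrichment values are exact and checkable, p-values
should be read as order-of-magnitude. Annotation is used flat, with no
ancestor-term propagation, which keeps every count exactly reproducible.
FDR control is BH within category.

**qPCR.** The calibration model is $C_q = m\,\log_{10}(\text{copies}) + b$
with efficiency $E = 10^{-1/m} - 1$; replicates aggregate by mean $C_q$
before inversion (standard practice). The LOD is the lowest tested
concentration with $\ge$ 95% replicate detection, and the detection call
`copies >= LOD` is inclusive — a sample exactly at the calibrated LOD
level is positive. Replicate scatter above 3× the curve's $C_q$ sd at LOD
(configurable) flags a result indeterminate rather than silently
averaging. Volume defaults follow the workflow the pipeline emulates: 1.6
mL plasma processed, 50 µL elution, 10 µL into reverse transcription.

**Cohort statistics.** The two-sided Fisher p sums hypergeometric point
probabilities $\le$ that of the observed table (relative tolerance 1e-7);
the doubling-the-one-tail convention was rejected because it double-counts
when no opposite-tail table is as extreme. The Kruskal–Wallis statistic is
tie-corrected; the SNK post hoc runs on mean ranks with studentized-range
critical values at infinite degrees of freedom, obtained from
`qtukey(1 - alpha, span, Inf)` rather than a transcribed table, and uses
step-down acceptance (a non-significant span blocks everything nested
inside it).

## What the generator emulates — and what it does not

The canonical synthetic study (the `sim_config()` defaults) has 2000
regular probesets, 8 case and 8 control arrays, 20 spike-ins, one
reference probeset at 408 units, 50 probesets planted 6-fold up, noise sd
0.25 on the log2 scale, multi-probeset genes (30 genes × 2, 10 × 3), ~5%
symbol-less transcripts, and a three-category GO annotation with one
planted enriched BP term (10 genes, 8 overlapping the planted
up-regulated genes). At that noise level the spike-in fold-changes
concentrate well below 2.9, so the derived threshold behaves like the
technical-variation bound it is meant to be.

One generator choice deserves emphasis. Planted probesets draw their
baselines from the middle of the intensity range
(`planted_baseline_log2_mean = 7`, sd 1) rather than the global baseline
distribution. Quantile normalization assumes near-identical per-array
signal distributions; in a genome-scale experiment where well under 1% of
probesets change this holds automatically, but a scaled-down simulation
that plants 2.5% of probesets one-directionally into the sparse upper
tail would violate it and manufacture rank-displacement artifacts no real
study of this design exhibits. Keeping the planted case-group signals
inside the distribution bulk preserves the regime the method was designed
for. The exact-panel-recovery test narrows further (1% planted fraction,
10 arrays per group, low noise) for the same reason: exact set equality
between recovered and planted panels is only a meaningful expectation
where the normalization assumption and the BH resolution both hold.

Not emulated: probe-level (25-mer) intensities, array spatial artifacts,
batch or labeling-day effects, GC/affinity biases, cross-hybridisation,
annotation errors, or correlated biological co-regulation beyond the
planted GO term. Passing recovery tests therefore demonstrate that the
*statistics* behave as specified under the assumed noise model — not that
the pipeline is robust to every failure mode of real arrays.

Other simulation conditions: qPCR calibrators are serial 10-fold
dilutions with Gaussian $C_q$ noise and a logistic dropout curve in
$\log_{10}$ copies near the bottom of the range (the simplest monotone
dropout; midpoint and scale are exposed in the arguments). The plasma
cohort defaults to 10 cases vs 27 controls with 60% vs 3.7% detection.
The three-group concentration generator plants an 8-fold case elevation
over a shared control/cesarean null with log2 sd 1.2 — roughly an
order-of-magnitude spread within group, typical of normalized qPCR
concentration data. The spike-in count (20) and the calibrator ladder are
assumptions, stated here because no design document fixes them.

## Numerical conventions and degenerate inputs

* BH adjustment requires p-values in (0, 1]; zeros are rejected loudly
  rather than clamped.
* A 2×2 table with a zero margin returns Fisher p = 1; a zero control
  detection rate makes the rate ratio `Inf` with a warning.
* `estimate_lod()` errors, reporting the best achieved fraction, when no
  level reaches 95% detection; adding detections at a level can only lower
  the LOD.
* An all-identical Kruskal–Wallis input gives H = 0, p = 1.
* Round-trips through the TSV/CSV writers preserve numeric values to
  1e-9 (15 significant digits are written).
* Problem sizes in the test suite — 50-seed null-study loops, 100-seed
  spike-in and SNK Monte-Carlo loops, brute-force enumeration up to pooled
  n = 12 and margins of 40 — were chosen so the whole suite completes in
  well under a minute while keeping Monte-Carlo standard errors far from
  the asserted bounds.

## Known limitations

* The exact Mann–Whitney path requires tie-free data; heavily tied data
  (including quantile-normalized values, see above) fall back to the
  corrected normal approximation, which is anti-conservative at extreme
  tails for very small samples.
* The EASE p-values match the DAVID-style definition, not any specific
  release of that service; only fold-of-enrichment values are exact
  reproductions.
* The SNK procedure uses infinite-df studentized-range quantiles, the
  large-sample convention of legacy statistics packages; for very small
  groups this is mildly liberal.
* `run_pipeline()` with file input expects the package's own TSV/CSV
  formats; no vendor binary formats are parsed.
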