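---
title: "Quantifying myotube maturation: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myotube maturation: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

Cultured human myotubes mature over days in differentiation medium:
nuclei disperse and align, sarcomeric proteins (α-actinin, then STIM1 and
RyR1) organize into ~2.5–2.7 μm striations, acetylcholine-receptor
clusters grow past a few μm², and electric-field stimulation evokes
robust cytosolic Ca²⁺ transients. myoquant packages the quantification
of those readouts — morphometry on label masks, transient
parametrization, cluster and striation measurement, qPCR normalization,
and the comparison statistics — together with synthetic generators that
make every stage testable against known ground truth. This vignette
records the models behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do and do
not establish about real data.

## Nuclei morphometry

The input is a calibrated integer label mask (`labeled_mask()`): 0 is
background, label *k* is nucleus *k*, and `pixel_size` (μm/px) carries
the spatial calibration. Areas are rasterized areas — pixel count ×
pixel_size² — because that is what any mask-based measurement sees;
analytic shape areas exist only inside the generator's truth tables.

**Area filter.** Nuclei are retained when their individual area lies in
the closed interval [40, 200] μm². We read "between" as inclusive at
both bounds; the boundary cases are exercised explicitly in the tests.

**Clustering.** Two nuclei are neighbours when the minimal Euclidean
distance between their boundary pixel centres is *strictly* below the
gap threshold (default 3 μm). Boundaries use the 8-connectivity
convention (a labelled pixel any of whose eight neighbours carries a
different value). Clusters are the connected components of the
neighbour graph — single linkage — so a chain of pairwise-close nuclei
forms one cluster that may span far more than 3 μm end to end. That
transitive reading is the only one that can produce the large (up to
~20-nucleus) aggregates seen in immature flat cultures. Nuclei in
singleton clusters are *isolated*; shape statistics are reported for
them only, since touching nuclei distort each other's apparent shape.

**Shape.** Eccentricity and orientation come from the ellipse matched to
the pixel set's central second moments, with the 1/12 per-pixel variance
correction (the convention of the mainstream region-properties
implementations): e = √(1 − λ₋/λ₊) and the major-axis angle against the
+x axis, counterclockwise positive as displayed, wrapped to [−90, 90).
A single pixel is exactly isotropic under this correction and is
reported as eccentricity 0 with a degeneracy flag, as is any object with
an isotropic second-moment tensor (for which the axis direction is
meaningless). On rasterized test shapes the estimates converge quickly:
2:1 ellipses with a 40 px major axis are within 0.02 of the analytic
√3/2 ≈ 0.866, disks of radius ≥ 10 px stay below 0.05, and orientation
is rotation-equivariant to better than 1°.

**Aggregation.** One microscope field is the unit of analysis: the field
summary reports the median cluster size and the median eccentricity of
isolated nuclei, and downstream tests compare those per-field medians.
Whether the median cluster size should include singleton "clusters" is
genuinely ambiguous in practice; we include them by default and expose
`include_singletons = FALSE`, which changes the statistic materially in
sparse fields (documented, selectable, and tested both ways).

**Fusion index.** "Nuclei within myotubes" needs a membership test; we
use centroid-in-mask because it is robust to partial overlap at myotube
edges and depends on no extra parameter. Any-overlap membership would
count edge-grazing nuclei and inflate the index on thin myotubes.

## Calcium transients under burst stimulation

The default stimulation protocol (`stim_protocol()`) delivers 1 s bursts
of 10 Hz pulses (2 ms each, metadata only) every 10 s for 180 s — 18
bursts — and recordings are sampled at 3.3 Hz. Analysis is
stimulus-locked: burst onsets are taken from the protocol plus a
user-supplied stimulation start time, never detected blindly, because
the experiment is protocol-driven and onset detection would add an
unnecessary failure mode.

Traces are normalized to F/F0 with F0 the mean over the 5 s preceding
the first onset (window configurable; it must precede stimulation and
contain ≥ 3 samples). Per-burst amplitude is max(F/F0) − 1 over
[onset, onset + burst + 2 s]: the 2 s extension captures the
decay-delayed sampled maximum at 3.3 Hz, and amplitudes are clipped at
zero. We define amplitude as F/F0 − 1 rather than the raw F/F0 peak —
the two differ by exactly 1 — because a 0.5 responder threshold is only
meaningful for a baseline-referenced quantity. A cell is a *responder*
when its first amplitude strictly exceeds 0.5 ΔF/F0; the exact-threshold
tie goes to non-responder.

"Decay time" has no unique definition at 3.3 Hz sampling; the default is
the time from the first-transient peak to the first crossing of
baseline + amplitude/e with linear interpolation between samples (equal
to the time constant τ for a monoexponential), and a log-linear
monoexponential fit is available as `method = "fit"`. Traces that never
reach the 1/e level before the next burst are censored, not guessed.
Remaining Ca²⁺ is 100 × (last amplitude)/(first amplitude), the standard
run-down measure.

## AChR clusters and sarcomere striations

AChR clusters come in as a label mask (thresholding raw α-bungarotoxin
images is upstream of this package; `label_from_intensity()` offers a
deliberately generic global-Otsu + connected-components utility, which
is not a calibrated segmentation procedure). The size rule is strict:
clusters with area > 5 μm² are retained. Cluster-to-myotube assignment
uses centroid-in-mask, the same rationale as the fusion index.

Sarcomere spacing is estimated from uniformly sampled line profiles of
striation fluorescence. The estimator takes the dominant positive-lag
peak (lag ≥ 2 samples) of the per-lag Pearson autocorrelation of the
mean-subtracted profile, refines it by parabolic interpolation — the
period is only a handful of samples at realistic pixel sizes — and then
regresses the refined lags of the available harmonic peaks (m·period,
m = 1, 2, …) on m. The regression step matters: finite windows shift
every harmonic peak by a nearly constant number of samples, and that
shift cancels in the slope. With it, noiseless Gaussian-peak trains of
5–12 periods anywhere in the physiological 1.5–4 μm range are recovered
within 2%; without it the single-peak estimate can err by ~3% at short
periods. The mean distance between successive detected intensity peaks
is reported alongside as an independent cross-check (the two agree
within 5% on clean trains), and at least three detectable peaks are
required. Flat or aperiodic profiles — no autocorrelation peak above a
noise floor of max(0.15, 3/√n) — are signalled as undefined rather than
returning a number.

## qPCR normalization

Relative quantities follow Q = E^(Ct_cal − Ct) with amplification
efficiency E = 2 (the classical ΔΔCt assumption; per-gene efficiencies
are rarely available and are not modelled). The per-gene calibrator is
the minimum Ct across samples by default — so the most-expressing sample
has Q = 1 — with mean-Ct selectable; the choice cancels out of fold
changes between conditions. The normalization factor per sample is the
geometric mean of the housekeeping genes' quantities (at least two are
required, e.g. B2M and EEF1A1), which absorbs any per-sample global Ct
offset such as pipetting differences — an invariance the tests assert
directly. Fold changes are per-condition means of Q/NF divided by the
reference-condition mean, so the reference (adult tissue) is exactly 1.
The geNorm stability measure M is provided as a diagnostic
(`genorm_stability()`), but it never selects genes: the housekeeping
pair is fixed by the experimental design. Missing Ct values drop the
gene–sample pair; nothing is imputed.

## Statistics

Group comparisons of per-field medians use the Wilcoxon rank-sum test
with midranks for ties, the tie-corrected variance, no continuity
correction, and the two-sided normal tail p = 2(1 − Φ(|z|)). The
no-correction choice is deliberate: it makes the reported (z, p) pairs
mutually consistent as plain normal tails, which is how such pairs are
conventionally printed. The trade-off is approximation quality at very
small samples: enumerating every attainable rank-sum value shows the
normal-tail p can differ from the exhaustive-permutation exact p by up
to 0.089 for two groups of five (0.047 even restricted to exact
p ≤ 0.25, shrinking monotonically with group size; a continuity
correction would cap the worst case at 0.017). Our validation suite
records this exhaustively; the practical reading is that borderline
calls (p near 0.05) from groups of ≤ 8 fields deserve the exact test,
which the test suite's permutation oracle implements. Ordering of
conclusions is unaffected in all enumerated cases.

Other comparisons use the classical equal-variance Student t test
(Welch selectable), descriptives are mean ± SEM (SEM undefined at n = 1
and signalled, never silently 0), and stars follow the strict mapping
\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001, \*\*\*\* p < 0.00001 —
boundary values take the weaker label.

## The synthetic generators: what they emulate, and what they don't

Every generator is a pure function of its parameters including the seed,
and emits ground truth sufficient to score the corresponding analysis
without re-derivation.

- `generate_nuclei_field()` rasterizes non-overlapping ellipses in
  spatial clusters: consecutive members sit within an intra-cluster
  border gap (default 1.5 μm, below the 3 μm clustering threshold) and
  different clusters are separated by at least 4 μm (above it), so the
  generated partition is recoverable exactly — which the tests verify
  against a brute-force all-pairs oracle. Cluster-size distributions,
  eccentricity spread and orientation concentration (uniform vs
  x-axis-aligned, via an axial wrapped-normal law) are free parameters;
  `nuclei_condition_params()` provides presets for an immature "flat"
  phenotype (large aggregates, rounder, unoriented nuclei) and a
  "nanopattern" phenotype (small aggregates, elongated, aligned).
  Placement is rejection sampling with a per-nucleus retry cap and
  whole-cluster restarts; impossible configurations fail loudly.
- `generate_trace()` renders one transient per burst with an
  instantaneous rise at the first sample at/after onset — 3.3 Hz
  sampling cannot resolve the true rise — and a monoexponential decay;
  amplitudes run down log-linearly so last/first equals
  `rundown_fraction` exactly. Because transients superpose, tails of
  earlier bursts contaminate later peaks by a factor
  e^(−10 s/τ); with the defaults (τ = 2 s) that is < 0.7%, which bounds
  the accuracy of the remaining-Ca²⁺ round-trip. `responder = FALSE`
  caps the amplitude at 0.3, safely below threshold.
- `generate_achr_field()` scatters elliptical blobs with lognormal (or
  explicit) areas and records exact rasterized areas.
- `generate_striation_profile()` builds Gaussian peak trains with exact
  spacing; `generate_ct_table()` builds Ct matrices from true fold
  changes with two unit-fold housekeeping genes, optional per-sample
  offsets, and inverts exactly under `fold_change()` when noiseless.

What passing these tests shows: the measurement code recovers known
parameters under controlled degradation (rasterization, sampling, run-
down, Gaussian noise). What it does not show: robustness to real-world
segmentation errors (merged/split nuclei), uneven illumination, focus
drift, photobleaching trends in F0, non-exponential Ca²⁺ recovery,
motion, or PCR inhibition — none of which the generators model. The
generators are fixtures for verification, not microscope simulators
(no PSF, no shot noise, no 3D).

## Numerical and degenerate-input conventions

- Coordinates are 0-based pixel indices, x along columns, y along rows;
  centroids are reported in μm in image coordinates; orientation flips y
  so counterclockwise-as-displayed is positive.
- Quantities that are mathematically undefined for an input (fusion
  index with zero nuclei, remaining Ca²⁺ with a non-positive first
  amplitude, SEM of one value, medians over empty populations, periods
  of flat profiles) raise or warn with condition classes
  `myoquant_undefined` / `myoquant_undefined_warning`; cohort-level
  wrappers convert them to `NA` so mixed populations summarize cleanly.
- Even-length medians are the mean of the two central order statistics.
- Strict inequalities everywhere the rule is phrased as strict: cluster
  edges (< 3 μm), AChR retention (> 5 μm²), responder calls (> 0.5),
  star thresholds.
- Validation problem sizes were chosen to keep the full suite fast
  while still exercising the asymptotics: 50 random fields of 20–60
  nuclei for the clustering oracle, 100 traces for the transient
  round-trip, 8-period striation profiles, exhaustive permutation for
  group sizes 5–8.

## Known limitations

- Border-to-border distances are measured between boundary pixel
  centres; sub-pixel edge geometry is unrecoverable from a mask, so
  distances carry O(1 px) quantization.
- The responder threshold is a hard 0.5 ΔF/F0; cells hovering at the
  threshold under noise will flip between calls, and the tests only
  guarantee correct classification at ≥ 3 noise-SD margins.
- Amplification efficiency is fixed per run, not per gene.
- The normal-approximation p is anti-conservative at n ≤ 8 (see the
  statistics section); use the permutation oracle for borderline calls.
- No multiple-testing correction is applied; the statistical layer
  reports per-comparison p values by design.
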