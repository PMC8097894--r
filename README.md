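# myoquant

Quantification of in vitro skeletal-muscle (myotube) maturation readouts:
nuclei-arrangement morphometry on segmentation masks, calcium-transient
parametrization under burst electric-field stimulation,
acetylcholine-receptor (AChR) cluster and sarcomere-striation
quantification, geNorm-normalized qPCR fold changes, and the statistics
used to compare culture conditions. Every analysis stage is paired with a
synthetic-data generator that emits machine-readable ground truth, so the
whole pipeline is verifiable without raw microscopy data.

It is aimed at muscle cell biologists and imaging-facility analysts who
have label masks (e.g. Cellpose nuclei segmentations), per-cell
fluorescence recordings, and Ct tables, and want reproducible, tested
quantification instead of ad hoc spreadsheet analysis.

## What it computes

**Nuclei morphometry** on a calibrated label mask (0 = background,
k = nucleus k, pixel size in μm/px):

- nuclei are retained if their individual area lies in [40, 200] μm²
  (bounds inclusive, configurable);
- nuclei are grouped into clusters by single linkage: an edge joins two
  nuclei whose minimal border-to-border distance (boundary pixel centres,
  8-connectivity boundary) is < 3 μm; a cluster of size 1 is an
  *isolated* nucleus;
- for each nucleus the ellipse matched to the pixel set's central second
  moments gives the eccentricity e = √(1 − λ₋/λ₊) (0 for a circle, → 1
  for a line) and the major-axis orientation in degrees ∈ [−90, 90);
- field-level summaries: median cluster size, median eccentricity of the
  isolated nuclei, orientation histogram, fusion index (fraction of
  nuclei whose centroid lies inside a myotube mask), marker-positive
  fraction (MEF2C, MyoD, Pax7, ...).

**Calcium transients** from F/F0-normalized traces under a burst protocol
(default: 1 s of 10 Hz pulses every 10 s for 3 min, sampled at 3.3 Hz):
per-burst amplitude max(F/F0) − 1, responder classification (amplitude
> 0.5), decay time of the first transient (time to the 1/e level, or a
monoexponential fit), and the percentage of remaining Ca²⁺
(100 × last/first amplitude).

**Image quantification**: AChR clusters retained if area > 5 μm² (strict),
counted per field and per myotube; sarcomere z-line spacing estimated from
α-actinin line profiles as the dominant positive-lag autocorrelation peak
with sub-sample (parabolic + harmonic-regression) refinement.

**qPCR**: relative quantities Q = E^(Ct_cal − Ct) (efficiency E = 2 by
default), geNorm normalization factor = geometric mean of two
housekeeping-gene quantities (e.g. B2M and EEF1A1), fold changes relative
to a reference condition (adult muscle ≡ 1).

**Statistics**: per-field medians as the unit of analysis, Wilcoxon
rank-sum with midranks, tie-corrected variance and no continuity
correction (two-sided p = 2(1 − Φ(|z|))), classical Student t tests,
mean ± SEM, and strict significance stars (\* p<0.05, \*\* p<0.01,
\*\*\* p<0.001, \*\*\*\* p<0.00001).

## Worked example

```r
library(myoquant)

# a synthetic 640x640 px field (0.325 um/px) with clustered nuclei
f   <- generate_nuclei_field(60, seed = 42,
                             cluster_size_prob = c(0.5, 0.2, 0.15, 0.1, 0.05))
rec <- filter_nuclei_by_area(f$mask, records = nucleus_records(f$mask))
asg <- cluster_nuclei(f$mask, rec, max_gap = 3)
summarize_field(rec, asg)
#> <field_summary> 60 nuclei retained | median cluster size 2 | median eccentricity (isolated) 0.587

# a noisy burst-stimulation recording and its transient metrics
tr <- generate_trace(first_amplitude = 1.2, decay_tau = 2,
                     rundown_fraction = 0.8, noise_sd = 8, seed = 7)
nt <- normalize_trace(tr$trace, NULL, stim_start = tr$truth$stim_start)
transient_metrics(nt, tr$protocol)
#> <transient_metrics> first amplitude 1.186 dF/F0 (responder) | decay 2.01 s | remaining 81.2% | 18 bursts

# comparing per-field medians between two conditions
wilcoxon_ranksum(c(4.5, 5, 6.5, 7, 3.5), c(2, 2.5, 3, 2, 4))
#> <wilcoxon_ranksum> z = 2.41, p = 0.01597 * (n = 5/5)
```

The field summary says: after the 40–200 μm² filter all 60 nuclei remain;
half the clusters are singletons or pairs (median cluster size 2); the
isolated nuclei are moderately elongated (median eccentricity 0.59). The
trace metrics recover the generator's parameters through the noise: first
amplitude ≈ 1.2 ΔF/F0 (a responder, > 0.5), decay ≈ 2 s, remaining
Ca²⁺ ≈ 80%.

A thin command line covering all stages is installed as
`inst/scripts/myoquant` (see `?cli_main`), e.g.
`myoquant simulate --kind nuclei --seed 1 --out-prefix sim`.

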