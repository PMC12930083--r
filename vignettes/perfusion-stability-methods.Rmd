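---
title: "Methods: phantom design, perfusion quantification and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom design, perfusion quantification and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(perfstab)
```

`perfstab` studies how stable automated CT-perfusion (CTP) metrics are
from one acquisition to the next. Because repeated clinical CTP data are
scarce and not redistributable, every claim the package makes is grounded
in a synthetic dynamic phantom with known hemodynamic ground truth. This
vignette documents the forward model, the quantification pipeline and its
tunables, the numerical choices that were genuinely open, and what the
phantom does and does not establish about real data.

## 1. Forward model

Each tissue voxel follows the indicator-dilution model

$$C(t) \;=\; B \;+\; \kappa\,\mathrm{CBF}\,\bigl(\mathrm{AIF} \circledast R\bigr)(t - \delta) \;+\; \varepsilon(t),$$

where $B$ is the pre-contrast baseline in HU, $\delta$ the bolus delay,
$\varepsilon$ i.i.d. Gaussian CT noise, and
$\kappa = 1/6000\;\mathrm{s}^{-1}$ per (mL/100g/min) converts flow to a
per-second fractional rate at unit tissue density. The residue function is
mono-exponential, $R(t) = e^{-t/\mathrm{MTT}}$, optionally dispersed by a
normalized exponential kernel of time constant $\tau$. The
mono-exponential family is the minimal standard choice with closed-form
Tmax behaviour; the vendor software whose pipeline this package mirrors
does not state its tissue model, so the exponential residue is an explicit
stand-in, and the dispersion option is off by default (with dispersion on,
the residue peak — and hence true Tmax — moves past the delay by an offset
the package computes numerically).

The arterial input is a gamma-variate
$a(t) \propto (t-t_0)^{\alpha} e^{-(t-t_0)/\beta}$, normalized so its peak
equals the `amplitude` parameter. Defaults: peak 350 HU (typical of 80 kVp
acquisitions, where arterial peaks of 300–500 HU are common), onset
$t_0 = 8$ s, $\alpha = 3$, $\beta = 1.5$ s. Simulation uses a 0.05 s
fine-grid convolution, so the forward curves are continuous-time objects,
deliberately *not* generated from the discretization the deconvolution
inverts.

### Phantom anatomy and lesions

The head is a two-hemisphere ellipsoid (semi-axes 81 × 87 × 42 mm on the
default 64 × 64 × 24 grid at 3 × 3 × 4 mm): a grey-matter shell
(CBF 60 mL/100g/min, MTT 4 s, 35 HU) around a white-matter core
(25 mL/100g/min, 5 s, 28 HU) — phantom constants, not clinical claims.
Small arterial (undelayed input curve) and venous (delayed 3.5 s,
amplitude × 1.3) voxel clusters provide realistic targets for automatic
AIF selection. Default acquisition: dt 2 s, duration 50 s, within the
clinically typical envelope (sampling 1.5–3.5 s, duration 38–55 s), CTP
noise 2 HU, NCCT noise 1.5 HU.

A lesion is a penumbra ellipsoid with an optional concentric core.
Perfusion inside a lesion is uniform relative to the grey-matter
reference: penumbra CBF fraction 0.65 with 8 s delay, core fraction 0.15
with 10 s delay, MTT prolonged reciprocally and capped at 12 s. The
default lesion sits cortically at (−52, 0, 0) mm so that the mirrored
(contralateral) core lies in grey-matter-dominated tissue, which is what
contralateral normalization assumes. Ground-truth masks are obtained by
applying the standard thresholds to the *true* maps: hypoperfusion at
Tmax > 6 s, core at rCBF < 30 % of the normal-tissue median. With the
defaults the truth is a 37.9 mL hypoperfused territory containing a
17.6 mL core. When an exact volume is requested
(`penumbra_target_ml`), the region is the set of voxels closest to the
centre in the ellipsoid metric with the count matched to the target
within one voxel.

### Scan-pair scenarios

`make_scan_pair()` generates repeated acquisitions of the same patient:
`stable` (same truth, fresh noise), the disruptive events `new_occlusion`
(a disjoint additional territory whose voxelized volume matches the
requested growth within one voxel) and `thrombus_migration` (lesion moved
15 mm posteriorly), and the technical failure modes `bolus_truncation`
(bolus delayed 20 s, scan shortened to 38 s, leaving the input function
at roughly 30 % of peak at the last frame — a literal cut right after the
peak would leave too few frames to deconvolve), `coverage_shift`
(acquisition window moved 4 slices along z) and `high_noise` (noise SD
× 2.5). Acquisition timestamps are `HHMMSS.ffffff` strings 0.6–9 h apart;
a negative raw difference is interpreted as a midnight wrap.

## 2. Quantification pipeline

Per scan: brain mask → preprocessing → AIF selection → deconvolution →
maps → normalization → segmentation → ASPECTS → intensity metrics.

**Brain mask.** Voxels within 10–60 HU, reduced to the largest
6-connected component with cavities filled. Deterministic.

**Preprocessing.** Optional rigid (integer-translation, phase-correlation)
frame-to-first motion correction — off by default, the phantom does not
move. Bolus arrival is the first frame whose whole-brain mean enhancement
exceeds 3 × the SD of the first three frames' means (with a small floor so
noise-free data still trigger); the baseline volume is the mean of the
pre-arrival frames, falling back to the first three frames with a warning.

**Two denoising paths.** A single smoothing scale cannot serve both map
families: the Tmax > 6 s boundary must not be displaced by partial-volume
mixing, while the rCBF < 30 % core test needs very low voxel noise. The
timing path therefore smooths lightly (Gaussian FWHM 4 mm) before
deconvolution, and the flow path (CBF/CBV) smooths strongly (9 mm). The
AIF is always selected from *unsmoothed* data: partial-volume dilution of
the arterial peak would rescale every CBF in the scan.

**AIF selection.** Candidates are the top 2 % of brain voxels by peak
enhancement that also clear an amplitude floor — the larger of 20 HU and
40 % of the strongest peak; the relative part keeps noise spikes on
tissue curves out of the pool whenever genuine vessels are present (a
single diluted tissue curve in the averaged AIF would rescale every CBF
in the scan). Candidates are
clustered into two groups on standardized (time-to-peak, peak amplitude)
with deterministic initialization (the earliest- and latest-peaking
candidates); the earlier-peaking group is the arterial pool. Isolated
candidates (no fellow candidate in the 26-neighbourhood) are dropped.
Candidates are ranked by the quality score
$\mathrm{peak}/(\mathrm{FWHM}\cdot\mathrm{TTP})$ — early, tall, narrow —
with ties broken by the lowest linear voxel index, and the mean of the
top 5 curves is returned. The quality formula and the top-k averaging are
package choices; only "predefined quality criteria" are specified
upstream.

**Deconvolution.** The convolution matrix is built from the AIF samples,
by default in the delay-insensitive block-circulant form (zero-padded to
twice the frame count). The regularized solution uses SVD filter factors
$f_i = s_i^2/(s_i^2 + (\lambda_{\mathrm{rel}} s_1)^2)$. Two documented
departures from the naive construction, both calibrated once on
forward-model recovery experiments and then frozen:

* *Quadrature.* Taps $(a_j + a_{j-1})/2$ — the AIF modelled as piecewise
  linear between samples — instead of the raw samples. For continuum
  curves this halves the CBF discretization bias and removes a systematic
  one-sample late bias in Tmax. The classical raw-sample (`"rect"`) and
  Simpson-corrected constructions remain available.
* *Regularization split.* $\lambda_{\mathrm{rel}} = 0.12$ on the timing
  path and $0.065$ on the (more strongly denoised) flow path. A single
  0.15 for both — the common literature default — over-regularizes here:
  it biases CBF down by > 30 % and pushes Tmax a further sample late.

The pipeline description upstream calls the method "L1-Tikhonov …
equivalent to a regularized SVD formulation"; an L1 penalty has no SVD
filter form, so the package implements the L2-Tikhonov SVD filtering that
the "regularized SVD" clause describes, and notes the discrepancy here.

**Maps.** CBF is the maximum of the residue estimate over the physical
samples (first maximum on ties defines Tmax); CBV is the trapezoid area
ratio of enhancement to AIF with negatives clipped; MTT = CBV/CBF above a
small flow floor, `NA` elsewhere. Negative residue *samples* are not
clipped — only the map values are. Two estimator refinements, both
exposed as switches:

* a masked 3 × 3 × 3 median filter on CBF and CBV (not Tmax: a
  neighbourhood median systematically erodes the convex Tmax lesion
  boundary, while Tmax speckle is already removed by the cluster filter);
* a model-based CBF bias correction dividing the max-of-residue estimate
  by $(\mathrm{MTT}/\Delta t)(1 - e^{-\Delta t/\mathrm{MTT}})$ — the
  exact factor by which sampling underestimates the peak of a
  mono-exponential residue — with MTT re-estimated iteratively from
  CBV/CBF. Without it, short-MTT normal tissue is underestimated much
  more than long-MTT lesions, inflating lesion rCBF ratios by up to half
  their value. The correction runs after the median filter because its
  MTT feedback amplifies unfiltered voxel noise.

**Normalization.** rCBF and rCBV are percentages of the median over
normally perfused tissue (brain with Tmax < 4 s). The reference set is
eroded two 6-neighbourhood iterations away from the brain surface so that
partial-volume-dampened edge voxels do not drag the reference median
down.

**Segmentation.** Hypoperfusion: brain with Tmax strictly > 6 s. Core:
hypoperfused tissue with rCBF strictly < 30 % (the restriction of core to
the hypoperfused region is standard mismatch practice and can be turned
off). Clusters below 1 mL are removed. Strict inequalities match the
printed threshold conventions; a voxel at exactly 6 s or exactly 30 % is
not lesional.

**ASPECTS.** The phantom supplies a geometric 10-region-per-hemisphere
atlas (ganglionic slab: medial strip split into four bands standing in
for caudate, lentiform, internal capsule and insula, lateral strip into
M1–M3; supraganglionic slab into M4–M6), mirror-symmetric by
construction. Real-data non-rigid template registration is out of scope;
an affine mode (per-axis moment matching of brain masks) stands in for
it and recovers pure translations to within half a voxel. A region is
flagged when the contralateral-minus-ipsilateral difference of the region
summary statistic strictly exceeds 2.25 HU. The summary statistic is the
median (robust; a trimmed mean is available) — the comparison statistic
behind the threshold is not specified upstream. The affected side is the
one with more flags; ties, including zero flags, mean "none" and a score
of 10; the score is 10 minus the affected side's flags.

**Intensity metrics.** Median Tmax inside the hypoperfusion mask
(native seconds); median CBF and median NCCT HU inside the core as
percentages of the median over the mirrored (contralateral homologous)
core region. Metrics over empty masks are `NA`, never zero, and
per-metric sample sizes are reported downstream.

## 3. Agreement analysis

Signed differences are scan 2 minus scan 1 throughout. Bland–Altman bias
is the mean difference, the limits of agreement bias ± 1.96 × sample SD
(n−1). Pearson correlation and paired t-tests are computed in closed form
(t transforms and `pt`), which keeps them independently checkable against
the reference implementations; agreement to 1e−9 is enforced in the test
suite. The interval association is operationalized as the Pearson
correlation of the signed differences with the inter-scan interval
(Spearman available by configuration); for a simple linear fit the slope
test gives the same p-value, so the choice is presentational. Two-sided
p < 0.05 is the significance convention. Degenerate inputs are handled
explicitly: identical scans give t = 0, p = 1; a constant non-zero
difference gives p = 0; zero-variance correlates give `NA` rather than an
error. Pairs whose scenario is a disruptive cerebrovascular event are
excluded from the agreement statistics but listed in the report.

## 4. What the tests establish, and at what sizes

The test suite runs entirely on simulated data at the default phantom
conditions. The main problem sizes, chosen to make the suite complete in
minutes on one CPU while keeping every check at full grid resolution:

* parameter recovery on a 5 × 5 × 3 grid of (CBF 20–80, MTT 3–10 s,
  delay 0–3 s) tiled as homogeneous blocks into three phantom runs;
  medians over the grid must reach one time sample in Tmax and 15 % in
  CBF;
* lesion-volume recovery for 10/30/60 mL territories (±10 %, Dice ≥ 0.90);
* a 200-pair stable cohort for the stability claim: zero inside the 95 %
  limits of agreement for all six metrics, and type-I behaviour of the
  paired t-test and the interval association measured as the rejection
  fraction over 40 disjoint 5-pair subcohorts × metrics (a single cohort
  yields only one p-value per metric, so a rejection *rate* is only
  estimable over many small cohorts; zero-variance tests, e.g. ASPECTS
  differences that are identically zero, are excluded from the
  denominator);
* 50 new-occlusion pairs with +20 mL ground-truth growth for
  disruptive-event sensitivity (detection = difference above half the
  induced growth);
* 100 noise seeds for the ASPECTS false-flag rate at zero true
  hypodensity.

## 5. Known limitations

* The exponential residue is a stand-in for an unknown vendor tissue
  model; absolute CBF is reported in deconvolution units and only
  relative quantities are interpreted.
* The segmented core is conservative: the strong flow-path smoothing
  contaminates the core rim with penumbral flow, so the default phantom's
  17.6 mL core is recovered at roughly 2–5 mL. Core metrics are therefore
  read as stability measures, not volumetric truth; cores whose truth
  volume is below roughly 12 mL may not be detected at all, and their
  intensity metrics are then `NA`.
* ASPECTS on the default phantom is constant at 10 — the default core
  does not majority-cover any atlas region — so its scan-to-scan
  difference carries no variance there; constructed hypodensities are
  used to exercise the scoring itself.
* The phantom has no skull, motion, beam hardening or contrast
  recirculation, its noise is white Gaussian in HU, and its anatomy is
  piecewise constant. Passing tests demonstrate correctness of the
  algorithms and stability under the modelled noise, not performance on
  clinical data.
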