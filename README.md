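# perfstab

Scan-to-scan stability of CT perfusion (CTP) metrics, studied on a digital
dynamic phantom.

## The problem

CT perfusion is the workhorse for estimating the infarct core and the
hypoperfused (penumbral) tissue in acute ischemic stroke, yet repeated CTP
in the same patient is rare, so little is known about how reproducible the
derived metrics are from one scan to the next. When repeated scans do
exist — clinical deterioration, technical failures, drip-and-ship
transfers — the key question is whether automated perfusion metrics drift
systematically over a few hours (which a linear infarct-growth-rate model
would predict) or merely fluctuate around a stable hemodynamic state.

`perfstab` makes that question testable without patient data. It provides:

* a **synthetic dynamic-CTP phantom** with known hemodynamic ground truth —
  a two-hemisphere ellipsoidal brain (grey-matter shell, white-matter
  centre), arterial and venous voxel clusters, and configurable ischemic
  lesions (penumbra + core ellipsoids with bolus delay, reduced flow, and
  optional dispersion). Paired scans of the same "patient" share the
  ground truth but have independent noise, and can be perturbed by
  disruptive events (new occlusion, thrombus migration) or technical
  failure modes (bolus truncation, z-coverage shift, elevated noise);
* a **perfusion quantification engine**: bolus-arrival detection, fully
  automatic arterial-input-function (AIF) selection by clustering of
  time–attenuation-curve features, delay-insensitive block-circulant
  regularized-SVD (Tikhonov) deconvolution, and CBF / CBV / MTT / Tmax
  maps normalized to normally perfused tissue (Tmax < 4 s);
* **lesion volumetry** by the standard thresholds — hypoperfusion at
  Tmax > 6 s, infarct core at rCBF < 30 % — in mL;
* **automated ASPECTS** on non-contrast CT via atlas region labels and
  inter-hemispheric Hounsfield-unit differences (region flagged when
  ΔHU > 2.25);
* **agreement statistics** across repeated pairs: Bland–Altman bias and
  95 % limits of agreement, Pearson correlation, paired t-tests, and the
  association of paired differences with the inter-scan interval.

## The model in brief

Tissue attenuation follows the indicator-dilution model

    C(t) = B + kappa * CBF * (AIF ⊛ R)(t - delay),    R(t) = exp(-t / MTT),

with `kappa = 1/6000` converting CBF in mL/100g/min to a per-second
fractional flow. Deconvolution inverts the discretized convolution
`c = A k` by SVD with Tikhonov filter factors
`f_i = s_i^2 / (s_i^2 + (lambda_rel * s_1)^2)`; CBF is the maximum of the
residue estimate `k(t)`, Tmax its time, CBV the enhancement-to-AIF area
ratio and MTT = CBV/CBF. rCBF is CBF as a percentage of the normal-tissue
median.

## Worked example

```r
library(perfstab)

spec <- phantom_spec(seed = 1)              # default 64x64x24 grid, dt 2 s
pair <- make_scan_pair(spec, "stable", interval_h = 3, seed = 42)
report <- run_pair_analysis(pair, perfstab_config())
print(report)
```

```
<pair_report> scenario 'stable', interval 3.00 h
      core_ml hypoperfusion_ml aspects median_tmax_hypo_s rel_cbf_core_pct
scan1    4.93            38.16      10                 10            25.52
scan2    2.48            37.37      10                 10            27.17
diff    -2.45            -0.79       0                  0             1.64
      rel_hu_core_pct
scan1           84.94
scan2           85.74
diff             0.80
```

Both scans see the same 37.9 mL ground-truth hypoperfused territory; the
recovered volumes agree to about 1 mL, the median Tmax inside the lesion
is 10 s on both scans, and the intensity metrics (CBF and NCCT HU in the
core, relative to the mirrored contralateral region) move by a few
percentage points — noise, not biology. `run_cohort()` aggregates many
pairs into a Bland–Altman table and excludes disruptive-event pairs the
way a reader would.

A thin command-line interface wraps the same functions:

```sh
inst/cli/perfstab simulate --scenario stable --seed 7 --out pair7/
inst/cli/perfstab compare-pair --in pair7/ --out pair7-report/
```

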