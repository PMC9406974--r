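---
title: "Perfusion post-processing methods: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion post-processing methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfstroke)
```

## The problem

In acute ischemic stroke, perfusion imaging separates irreversibly
injured tissue (the *ischemic core*) from hypoperfused but salvageable
tissue (the *penumbra*). The DEFUSE3 neuroimaging criteria select
patients for mechanical thrombectomy when the core volume (ICV) is
below 70 mL, the penumbra/core mismatch ratio exceeds 1.8, and the
mismatch volume exceeds 15 mL. perfstroke implements the full automated
chain from a raw 4D perfusion series (CT perfusion or DSC-MRI) to that
triage decision, plus the agreement statistics used to compare two such
processing pipelines on a paired cohort.

## Tracer-kinetic model

For an intravascular tracer, the tissue concentration curve is the
convolution of the arterial input function (AIF) with the flow-scaled
residue function:

$$c_t(t) = F \cdot \big(c_a \ast r\big)(t), \qquad r(s) = e^{-s/\mathrm{MTT}},$$

where $F$ carries the cerebral blood flow together with unit
conversions. The four parameter maps are

* $\mathrm{rCBV} = 100\,\frac{k_{AV}}{\rho}\,
  \frac{1-H_{SV}}{1-H_{LV}}\,
  \frac{\int c_t\,dt}{\int c_a\,dt}$ (mL/100 g),
* $\mathrm{rCBF} = 100 \cdot 60\,\frac{k_{AV}}{\rho}\,
  \frac{1-H_{SV}}{1-H_{LV}}\,\max_t \hat r(t)$ (mL/100 g/min),
* $\mathrm{MTT} = 60\,\mathrm{CBV}/\mathrm{CBF}$ (s),
* $T_{max} = \arg\max_t \hat r(t)$ (s),

with $\hat r$ the deconvolved flow-scaled residue, $\rho$ the brain
density (default 1.04 g/mL), $k_{AV}$ a calibration factor (default 1)
and $H_{SV}, H_{LV}$ the small/large-vessel hematocrit fractions
(defaults 0.25 and 0.45). One deliberate choice is visible here: the
hematocrit ratio $(1-H_{SV})/(1-H_{LV})$ appears in **both** rCBV and
rCBF. It converts the measured large-vessel (arterial) concentration
scale to the small-vessel scale, and since that rescaling acts on
$c_a$ it propagates identically into both quantities; printing it only
in CBV (as some sources do) makes CBV and CBF mutually inconsistent,
breaks the MTT identity against ground truth, and makes a
forward-model/inversion round trip impossible. With
$H_{SV} = H_{LV}$ the rCBF equation reduces to the familiar
uncorrected form. All four constants are configuration-exposed.

## Deconvolution

`deconvolve()` builds the discrete convolution matrix
$A_{ij} = \Delta t\, c_a(t_{i-j+1})$ (lower-triangular Toeplitz) and
solves $A\hat r = c_t$ per voxel by truncated SVD, discarding singular
values below 10% of the largest (configurable). In the default
*block-circulant* mode both $A$ and $c_t$ are zero-padded to length
$2N$, which makes the solution insensitive to bolus delay: the residue
of delayed tissue wraps around instead of being clipped.

Two well-known failure modes shaped the design:

* the **circulant** solution smears the residue discontinuity at
  $s = 0$ and underestimates its peak (we measure roughly −13% median
  over a CBF 10–80, MTT 3–12 s grid at the 10% threshold);
* the **standard** solution recovers the peak well at zero delay
  (about −3%) but degrades badly with tissue delay (about −15% at 3 s).

perfstroke therefore solves both systems in circulant mode and
composes the maps from their strengths: $T_{max}$ (a delay measure) is
the argmax of the delay-insensitive circulant residue, while the flow
peak is read from the standard-Toeplitz residue. On noiseless phantoms
this keeps the median absolute CBF error under 5% across the grid,
with the worst case (~6%) at MTT 3 s where the residue is sharpest.
Non-uniform frame times are linearly resampled to the minimum spacing
before matrix construction. MTT is defined as $60\,\mathrm{CBV}/\mathrm{CBF}$
(0 where CBF is 0), so the identity
$\mathrm{MTT}\cdot\mathrm{CBF} = 60\,\mathrm{CBV}$ holds to machine
precision on every map by construction.

The flow estimate degrades for broad arterial boluses: the singular
values of $A$ decay with the AIF's spectral width, so a sluggish
injection (first-pass FWHM well above ~6 s at $\Delta t = 1.5$ s)
pushes more of the residue's high-frequency content under the
truncation threshold and the peak is increasingly underestimated. This
is a property of truncated-SVD deconvolution itself, not of this
implementation; it is why the phantom's default AIF is a brisk
first-pass bolus (gamma-variate, FWHM ≈ 4.5 s).

## Preprocessing

* **Brain mask**: threshold on the temporal mean (CTP: 20–80 HU
  soft-tissue window; DSC-MRI: above 20% of the maximum), largest
  6-connected component, interior hole filling. Deterministic.
* **Motion correction**: translation-only rigid alignment to frame 1
  via FFT cross-correlation with parabolic subvoxel refinement,
  applied by trilinear interpolation. Desk-scale phantoms contain no
  rotation; full rigid registration is an extension point.
* **Smoothing**: per-frame separable Gaussian,
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ converted to voxels per
  axis. The default is **2 mm FWHM for CTP** and 0 for MR. We
  originally used 4 mm, but on the noiseless 64×64×16 phantom
  (3×3×6 mm voxels) a 4 mm kernel erodes the segmented core by ~14%:
  the rCBF < 30% operating point sits far below the 50% blend point of
  a core/normal boundary voxel, so blurring reclassifies a boundary
  shell outward of the true core. At 2–3 mm the recovery is exact.
  Heavier smoothing remains available in the configuration for noisy
  acquisitions, with this bias as the documented cost.
* **Concentration**: the baseline window is auto-detected from the
  mean brain signal (minimum 3 frames, growing until a frame departs
  from the running baseline mean by more than 3 baseline SDs). CTP
  uses baseline subtraction; DSC-MRI uses
  $c = -\ln(s/s_0)/TE$. Negative or non-finite concentrations are
  clipped to zero and counted (`n_clipped`), which stabilizes the
  deconvolution at the cost of a small positive bias in very noisy
  voxels.

## AIF detection

Every brain voxel is scored by equally weighted z-scores of peak
height, earliness (low first moment) and narrowness (low FWHM) — the
three classic arterial-curve properties. The top five voxels (ties
broken by lexicographic coordinate, so the result is deterministic)
are averaged. An optional gamma-variate refit
($A(t-t_0)^\alpha e^{-(t-t_0)/\beta}$, fitted up to 1.5× the
time-to-peak) suppresses recirculation; it is off by default because
the phantom has none.

## Segmentation and triage

Thresholds are the standard clinical operating points, all strict
inequalities, all configurable: core at rCBF < 30% of the reference
(CTP) or ADC < 620×10⁻⁶ mm²/s (MRI); penumbra at $T_{max}$ > 6 s,
excluding the core. Three choices the thresholds alone do not fix:

* the rCBF **reference** is the median rCBF of normally-perfused brain
  ($T_{max} \le 4$ s, falling back to the whole-brain median): it is
  self-contained (no contralateral-hemisphere registration) and
  phantom-verifiable;
* CTP core is additionally **gated to hypoperfused tissue**
  ($T_{max} > 6$ s, disable with `gate_by_tmax = FALSE`), preventing
  spurious core in normally-perfused low-flow tissue such as white
  matter;
* connected components below **1 mL** (26-connectivity) are discarded,
  making the handling of speckle explicit and auditable.

The mismatch profile is `mismatch_volume = PV − ICV` and
`mismatch_ratio = PV/ICV`, with the ratio defined as +∞ for an empty
core with non-empty penumbra (so a zero-core patient with adequate
mismatch volume is DEFUSE3-eligible) and 0 when both are empty.
DEFUSE3 eligibility is ICV < 70 **and** ratio > 1.8 **and** mismatch
volume > 15 mL, strict, with every violated criterion reported.

## Agreement statistics

`icc_two_way()` is ICC(2,1) — two-way random effects, absolute
agreement, single measures — from the ANOVA decomposition, with the
F-distribution confidence interval of McGraw & Wong. Absolute
agreement is the defensible variant for method comparison (a constant
bias between packages *should* lower the coefficient).
`bland_altman()` uses limits of agreement $\bar d \pm 1.96\,s_d$ and
the standard $t_{0.975,n-1}\, s_d \sqrt{3/n}$ limit CIs.
`wilcoxon_paired()` drops zero differences, uses an exact
dynamic-programming null (sign enumeration over midranks) up to 25
non-zero differences and a tie- and continuity-corrected normal
approximation beyond. Triage concordance splits cases at a package-A
core volume of 70 mL (boundary assigned to the ≥ side) and codes
decisions 0/1 into ICC(2,1); when that ICC is degenerate (zero
variance) it is reported as 1 if the decision vectors are identical
and NA otherwise. Mean differences follow the reference-minus-variable
convention (package A minus package B).

## The phantom: what it emulates and what it does not

`make_phantom()` builds a head-sized ellipsoidal "brain" in which every
voxel carries a forward-modelled tissue curve: gamma-variate AIF
convolved with a flow-scaled mono-exponential washout, with a planted
ellipsoidal core (CBF 10 vs 60 mL/100 g/min, ADC 450 vs
800×10⁻⁶ mm²/s) nested in a hypoperfused region (8 s bolus delay,
hence $T_{max} \approx 8$ s > 6 s), a 5-voxel arterial plug carrying
the pure AIF, and additive Gaussian noise. Two discretization choices
make the ground truth exact rather than approximate:

* the residue is sampled as $r[k] = (1 - \Delta t/\mathrm{MTT})^k$,
  the rectangle-rule solution of $dr/ds = -r/\mathrm{MTT}$; its
  discrete peak is exactly the flow scale and its discrete area
  exactly $F\cdot\mathrm{MTT}$, so the central-volume identity holds
  without discretization bias (continuum sampling of $e^{-s/MTT}$
  would overestimate the rectangle-rule area by up to
  $\Delta t/2\mathrm{MTT}$, ~25% at MTT 3 s);
* the forward convolution uses the same rectangle rule as the
  deconvolution matrix, so noiseless inversion errors reflect the SVD
  truncation only.

Default sizes (a ~31 mL core in ~92 mL of hypoperfusion) describe a
clearly thrombectomy-eligible patient. Noise is additive Gaussian on
the signal for both modalities — a deliberate simplification (Rician
MR noise is near-Gaussian at phantom SNR). What the phantom does *not*
emulate: anatomy, partial-volume effects at acquisition, contrast
recirculation, scanner artifacts, or rotational motion. A green
phantom test therefore establishes correctness of the numerical chain
and its conventions, not clinical performance on patient data. At the
default CTP noise (1 HU against ~5 HU peak tissue enhancement)
voxelwise $T_{max}$ is genuinely unstable — as it is in practice,
which is why vendors regularize aggressively; volumetric validation
uses the noiseless phantom, and the noisy default is kept as an honest
stress case.

## Numerical conventions

* Axis order (x, y, z, t); spacing in mm; time in s; frame 0 at t = 0.
* $T_{max}$ is an exact multiple of $\Delta t$ (argmax over the
  acquisition window of the circulant residue).
* Strict inequalities exactly as stated for every threshold, so
  boundary voxels and boundary patients fall on the stated side
  (a voxel at exactly 620×10⁻⁶ mm²/s is *not* core; a patient at
  exactly ICV 70 mL is *not* eligible).
* All pipeline randomness flows from the single configuration seed;
  reruns are byte-identical (the pipeline itself is deterministic —
  only phantom noise consumes the seed).
* NIfTI-1 I/O is implemented in the package (little-endian write,
  both-endian read, `.nii`/`.nii.gz`), exchanging volumes with
  standard neuroimaging tools; acquisition metadata the NIfTI header
  cannot carry reliably (frame times, modality, echo time) travels in
  a JSON sidecar.

## Known limitations

* Translation-only motion model; no slice-timing or rotation handling.
* No bolus-truncation extrapolation: late, long-MTT tissue loses some
  $\int c_t$ if the acquisition window clips the washout (kept under
  ~2% in the phantom's 60 s window).
* The flow estimate inherits truncated-SVD bias for broad AIFs (see
  above).
* Noisy voxelwise $T_{max}$ segmentation is unregularized beyond the
  cluster filter.
* The agreement module reproduces the statistical machinery, not any
  vendor's patient-level results; no patient data ship with the
  package.
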