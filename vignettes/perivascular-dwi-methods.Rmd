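---
title: "Methods: simulating and estimating perivascular pseudo-diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating perivascular pseudo-diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsdwi)
```

## The signal model and its assumptions

The measurement this package emulates is a fast-spin-echo acquisition with
an ultra-long effective echo time (TE~eff~ = 142 ms) and a low-b
motion-probing gradient pair. Two assumptions define the forward model:

* **Mono-exponential T2 contrast at a single effective TE.** The signal of
  a compartment with relaxation time T2 is scaled by exp(−TE/T2)
  (`t2_attenuation()`), with an optional saturation-recovery factor
  1 − exp(−TR/T1) that is off by default because TR = 5 s makes it
  negligible and no compartment T1 values are established for this
  protocol. The phase-encode-dependent TE modulation of the echo train is
  *not* simulated; treating TE~eff~ as constant is the same simplification
  the acquisition design itself relies on. At TE = 142 ms the surviving
  fractions are ≈ 28% for fluid (T2 111 ms), ≈ 2% for grey matter (38 ms)
  and ≈ 1% for blood (30 ms) — the mechanism that isolates fluid-filled
  compartments.
* **Tensor pseudo-diffusion decay.** Each voxel decays as
  S = S₀·exp(−b·gᵀD\*g). D\* is a *pseudo*-diffusion tensor: at
  b ≈ 100 s/mm² incoherent fluid motion, not Brownian diffusion, dominates
  the decay, so its entries (10⁻³–10⁻² mm²/s) sit well above free-water
  diffusivity. We make no attempt to separate flow from diffusion
  (a multi-b IVIM analysis); one b0 plus one shell is the stated design.

### b-values: closed form vs scanner values

`stejskal_tanner_b()` implements the rectangular-pulse closed form
γ²G²δ²(Δ − δ/3), with γ = 2.675×10⁸ rad s⁻¹ T⁻¹ and all unit conversions
centralised in one place. For the protocol settings (δ = 5 ms, Δ = 26 ms,
G = 4.2 G/cm) this gives 76.8 s/mm², whereas scanner-calculated b-matrices
that include imaging-gradient contributions report 107 s/mm². Those
waveforms are not public, so the closed form cannot reproduce 107 and we
do not try: `acq_params()` carries a `b_nominal` field (default 107) that
overrides the closed form everywhere downstream, and `fit_tensor()`
accepts externally calculated full 3×3 b-matrices for the same reason.

## The digital phantom: what it emulates, and what it does not

`phantom_spec()` + `build_geometry()` produce a schematic single-slice
(128×128, 25×25 mm FOV) ventral rat-brain image containing six labels:
background, parenchyma, blood, subarachnoid CSF, perivascular tracts and
third ventricle. The geometry is parametric, not anatomical: a circular
Circle-of-Willis arterial ring, two middle-cerebral-artery branches
modelled as quadratic Bézier curves diverging left/right (tangents by
finite differences), perivascular tracts flanking each branch on both
sides without entering the lumen, a midline caudal–rostral subarachnoid
band, and an elliptical ventricle.

Ground-truth tensors are axially symmetric (λ⊥₁ = λ⊥₂), solved in closed
form from a target FA and MD (`tensor_from_fa_md()`): only FA and MD per
ROI are established in vivo, so a two-parameter family is the most honest
choice. Defaults use the in-vivo ROI means as ground truth — PVS FA 0.44,
MD 0.0042 mm²/s; subarachnoid FA 0.60, MD 0.0065 mm²/s — with the PVS
principal axis along the local vessel tangent and the subarachnoid axis
caudal–rostral. The ventricle is isotropic at 0.003 mm²/s (ventricular
CSF shows little directional ordering in this slice), parenchyma isotropic
at 7×10⁻⁴ mm²/s (tissue ADC scale; it is almost fully T2-suppressed
anyway), blood isotropic at 0.05 mm²/s (fast incoherent flow; ~1% signal).

Scenarios rescale the truth: `pulsation` multiplies the PVS leading
eigenvalue by 4.0 relative to `diastole` (a ~300% increase),
`dobutamine` by 1.65 relative to `baseline` (a 65% increase), and
`postmortem` scales all fluid tensors by 0.1 — this last factor is a free
parameter, since only a qualitative post-mortem reduction is established.

Noise is Rician (magnitude MRI): out = √((S+n₁)² + n₂²),
n ~ N(0, σ). σ is set in signal units, or from a target b0 SNR in
CSF-like fluid via `sigma_for_b0_snr()`; SNR 50 is the reference
condition for the recovery experiments. Partial volume is deliberately
absent (nearest-label assignment): the acquisition's purpose is to
suppress partial volume, so the clean case is the reference. The phantom
therefore does **not** emulate: realistic anatomy, respiratory motion,
flow artefacts, coil profiles, eddy currents, or k-space effects. A green
recovery test establishes that the estimation chain is unbiased under the
stated noise model on this geometry — not that it is robust to everything
an in-vivo acquisition can produce.

## Estimation chain: numerical choices

* **Log-linear least squares.** With one b0 and one shell there are two
  amplitudes per direction, so the log-linearised system
  ln(S₀/Sᵢ) = Σ BᵢⱼₖDⱼₖ is solved by ordinary least squares (QR); the
  whole-volume fit (`fit_dti()`) shares one pseudo-inverse across voxels.
  Weighted and nonlinear variants are out of scope by design.
* **Rank checking.** A direction design whose 6-column expansion has rank
  < 6 (coplanar or duplicated directions) is rejected with an explicit
  error rather than silently regularised.
* **Non-PSD fits.** Low-b, low-SNR fits can produce negative eigenvalues.
  These voxels are flagged `FALSE` in `valid_mask`; eigenvalues are
  clipped to 10⁻¹² only for FA/MD evaluation, never in the stored tensor.
* **Eigenvector conventions.** Eigenvalues descending; the first two
  eigenvectors are signed so their first non-zero component is ≥ 0 and
  the third is their cross product. (Applying the sign rule to all three
  can conflict with right-handedness; the triad convention wins for the
  third axis.) This makes maps byte-reproducible.
* **Masking.** The default intensity mask keeps voxels above the 90th
  percentile of the b0 image — with ~6% of voxels being fluid and an
  order-of-magnitude contrast over parenchyma, any cutoff in the gap
  works; Otsu's method is provided as an alternative (cutoff taken at the
  upper edge of the argmax histogram bin). The exact in-vivo threshold
  level was never stated, so it is a parameter.
* **Edge-preserving smoothing.** A masked median filter (radius 1
  default): the median is edge-preserving on piecewise-constant maps, and
  restricting both the targets and the neighbourhoods to the mask keeps
  fluid and suppressed-tissue values from mixing. No specific filter was
  ever named, so the simplest member of the class was chosen.
* **Six directions.** The exact in-vivo direction table is unpublished;
  the default is the classic dual-gradient six-direction set
  (normalised ±1/1/0 permutations), which is full-rank and symmetric.

## Cardiac gating

The weighting is centred on the first refocusing pulse at half the first
echo time (72 ms), so a trigger delay t gives a centre at t + 36 ms and a
window of width Δ = 26 ms: delays of 0/80 ms give windows of 23–49 and
103–129 ms after the r-wave. With a pulse-wave arrival of
1000·0.10/2.69 ≈ 37 ms and an r-r interval of ~150 ms, the first window
overlaps the arterial pulse (`pulsation`) and the second does not
(`diastole`). The systolic-interval width defaults to 40 ms — an invented
but conventional rodent value; only the two printed delays were ever
classified, and both classifications are reproduced with margin.
Classification is boundary-inclusive and invariant to shifting window and
arrival by whole cardiac cycles. The first echo time is a direct input,
never derived from the echo spacing, because the k-space-centre echo
relation is not stated for this sequence.

## Statistics

ROI means are arithmetic means over valid masked voxels. Paired
comparisons use the classical paired t with n − 1 df; p-values are
two-sided by default even for directional hypotheses (conservative;
one-sided via `alternative = "greater"`), and no multiple-testing
correction is applied, matching the original uncorrected reporting. SEM
is computed across subjects only.

## What the tests establish

The suite verifies: exact closed-form values (attenuation percentages,
gating windows, worked signal values); exact noiseless tensor recovery
and agreement with an independent numpy least-squares fitter to 10⁻⁶ on
200 random tensors; rotation equivariance of signal and of the whole
fitting chain; and Monte-Carlo parameter recovery at b0 SNR 50 over 100
seeds (ROI FA bias < 0.05, MD bias < 10%, median principal-direction
error < 10°), plus replication of the directional (parallel >
perpendicular, paired p < 0.01 over 10 subjects) and scenario (~300%
pulsation, ~65% dobutamine, recovered within a ±20% band fixed before
measurement) contrasts. No empirical claim appears in this vignette that
those tests and `scripts/acceptance.R` do not themselves compute.

## Known limitations

Single slice, schematic geometry, no partial volume by default, no motion
or flow artefacts, mono-exponential TE contrast, one-shell acquisition
(no biexponential IVIM separation), and a NIfTI codec intentionally
limited to the package's own needs (diagonal orientation, common
datatypes). In-vivo point values (heart rates, animal FA/MD) are inputs
and recovery targets for the phantom, not quantities this package can
reproduce from data.
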