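# pvsdwi

Simulation and analysis of ultra-long-TE, low-b diffusion-weighted MRI of
perivascular and subarachnoid fluid movement.

## The problem

The perivascular space (PVS) — the fluid-filled channel surrounding brain
arteries — is a key conduit for CSF inflow in the glymphatic pathway, but
measuring fluid movement inside it normally requires invasive tracers.
A non-invasive alternative uses two MRI tricks together:

1. **T2 compartment contrast.** At an effective echo time of 142 ms, signal
   from grey matter (T2 ≈ 38 ms) and blood (T2 ≈ 30 ms) has decayed to ~2%
   and ~1% of its initial value, while CSF-like fluid (T2 ≈ 111 ms) retains
   ~28%. Fluid-filled compartments are therefore essentially the only thing
   left in the image.
2. **Low-b pseudo-diffusion weighting.** With motion-probing gradients at
   b ≈ 100 s/mm², the residual fluid signal decays as

   S = S₀ · exp(−b · gᵀ D\* g)

   where D\* is the *pseudo-diffusion tensor*: at such low b the decay is
   dominated by incoherent fluid motion (the IVIM regime), not molecular
   diffusion. Fitting D\* from ≥ 6 gradient directions gives eigenvalues
   λ₁ ≥ λ₂ ≥ λ₃, mean diffusivity MD = (λ₁+λ₂+λ₃)/3, fractional anisotropy

   FA = √(3/2) · √( Σ(λᵢ − MD)² / Σλᵢ² ),

   and a principal direction that, in the PVS, runs along the vessel.

Cardiac gating adds a temporal dimension: triggering acquisition at the
r-wave (diffusion weighting applied 23–49 ms after it) samples arterial
pulsation; delaying by 80 ms (window 103–129 ms) samples diastole.

`pvsdwi` packages this whole chain for simulation studies and method
development: a closed-form forward signal model, a seeded digital phantom
of a ventral rat-brain slice with ground-truth tensors, the estimation
chain (per-direction D\*, log-linear tensor fit, FA/MD/eigenvector maps,
intensity masking, edge-preserving smoothing, ellipsoid glyph export),
the gating timing calculator, ROI statistics with paired tests, minimal
NIfTI-1 + FSL bval/bvec I/O, and a CLI.

## Worked example

```r
library(pvsdwi)

# Gating: immediate trigger lands the weighting window on the pulse wave
print(gating_plan(0))
#> Cardiac gating plan
#>   r-wave delay             0.0 ms
#>   weighting centre        36.0 ms
#>   weighting window        23.0 - 49.0 ms
#>   pulse arrival           37.2 ms
#>   r-r interval           150.0 ms
#>   phase               pulsation

# Simulate a noisy phantom (b0 SNR 50 in CSF) and fit the tensor maps
spec <- phantom_spec(noise_sigma = sigma_for_b0_snr(phantom_spec(),
                                                    acq_params(), 50),
                     seed = 42)
sim <- simulate_phantom(spec, acq_params())
fit <- fit_dti(sim$dwi)

pvs <- sim$truth$label_map == sim$truth$labels[["pvs"]]
sa  <- sim$truth$label_map == sim$truth$labels[["subarachnoid"]]
cat(sprintf("PVS:          FA %.3f, MD %.5f mm^2/s\n",
            roi_mean(fit$fa_map, pvs), roi_mean(fit$md_map, pvs)))
cat(sprintf("subarachnoid: FA %.3f, MD %.5f mm^2/s\n",
            roi_mean(fit$fa_map, sa), roi_mean(fit$md_map, sa)))
#> PVS:          FA 0.454, MD 0.00419 mm^2/s
#> subarachnoid: FA 0.605, MD 0.00650 mm^2/s
```

The ground truth behind those numbers is FA 0.44 / MD 0.0042 mm²/s in the
PVS and FA 0.60 / MD 0.0065 mm²/s in the subarachnoid band — the fit
recovers them to within the noise at this SNR.

The same pipeline is available from the shell (`inst/cli/pvsdwi`):

```sh
pvsdwi simulate --out /tmp/sim --seed 7 --snr 50
pvsdwi fit      --in /tmp/sim --out /tmp/fit
pvsdwi gate     --delay 80 --json /tmp/plan.json
```

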