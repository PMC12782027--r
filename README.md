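# lipidxr

Analysis of specular X-ray reflectivity (XR) from lipid monolayers at the
air/water interface, built around a before/after enzyme-oxidation
experiment: a Langmuir monolayer of an arachidonoyl substrate lipid (SAPC)
is measured, the lipoxygenase 15-LOX-2 oxidizes the unsaturated tail in
situ, and the monolayer is measured again. The structural readout is the
laterally averaged electron-density profile ρ(z) normal to the interface —
oxidation pulls the peroxidized tail segment up toward the headgroups,
shortening the apparent tail layer by ~3 Å (~30 %) and densifying the
headgroup region.

The package is for scattering scientists who want a scriptable, testable
version of that analysis chain: forward modelling, model-dependent (slab)
fitting, model-independent (B-spline) inversion, and the derived
oxidation metrics, exercised on synthetic data generated from the
published parameter table.

## What it computes

**Forward model.** A film is described as slabs: air | tails | headgroups |
water, each layer with thickness d, electron density relative to water
ρ/ρ_w, and an error-function interfacial roughness σ. The profile is
micro-sliced and specular reflectivity R(q_z) is computed with the exact
Parratt recursion

    r_j = (F_j + r_{j+1} e^{2 i k_{j+1} d_{j+1}}) / (1 + F_j r_{j+1} e^{2 i k_{j+1} d_{j+1}}),
    k_j = sqrt((q_z/2)^2 − 4π (SLD_j − SLD_air)),  R = |r_0|^2,

with q_z = (4π/λ) sin θ and curves normalized to the Fresnel reflectivity
R_F of the ideal sharp air/water interface.

**Slab fitting.** `fit_slab_model()` minimizes the reduced
χ² = Σ[(R/R_F)_model − (R/R_F)_data]²/σ² / (N − p) by bounded
Levenberg–Marquardt from multiple perturbed starts, supports fixed
parameters, breaks ties between statistically indistinguishable minima in
favour of realistic (closest-to-start) parameters, and reports 1σ errors
from the finite-difference concavity (Hessian) of the χ² surface.

**Spline inversion.** `fit_spline_profile()` fits ρ(z) as a cubic B-spline
pinned to bulk water on one side and air on the other, from hundreds of
random starts; all models within χ² ≤ 1.2 χ²_min form a family whose
pointwise envelopes are the uncertainty ribbons, and the reported best
model is the smoothest profile within 1 % of the minimum χ².

**Structural metrics.** `compare_models()` turns a before/after pair of
fits into tail shortening (Å and %), headgroup density change and subphase
roughness change with propagated errors; `rho_from_electron_count()` and
`layer_distinction()` provide the electron-counting and layer-contrast
checks.

**Synthetic data.** `reference_model()` holds the five published monolayer
parameter sets (SAPC, SAPC+15-LOX-2, PAzePC, DSPC, DSPC+15-LOX-2);
`simulate_curve()` / `paired_experiment()` generate reflectivity with
multiplicative 2 % Gaussian counting noise over 0.016 < q_z < 0.7 Å⁻¹.

## Worked example

```r
library(lipidxr)

## before/after oxidation experiment on synthetic data
pair <- paired_experiment("SAPC", "SAPC+15-LOX-2", seeds = c(101, 102))
before <- normalize_to_fresnel(pair$before)
after  <- normalize_to_fresnel(pair$after)

fit_before <- fit_slab_model(before, reference_model("SAPC"), seed = 1)
fit_after  <- fit_slab_model(after,  reference_model("SAPC+15-LOX-2"), seed = 2)
summary(fit_before)
compare_models(fit_before, fit_after)
```

```
Slab-model fit: 120 points, 6 free parameters, reduced chi2 = 0.8909
                   estimate std_error
tails.thickness    11.74099   0.06912
tails.rho_rel       0.95987   0.00097
heads.thickness     6.83531   0.42898
heads.rho_rel       1.31785   0.02176
heads.roughness     2.60906   0.06777
subphase.roughness  4.61694   0.18672
fixed: tails.roughness, scale, background
<xr_structural_comparison> SAPC -> SAPC+15-LOX-2
  tail shortening:  3.13 +/- 0.073A  (26.6 +/- 0.48% )
  headgroup rho/rho_water change: 0.219 +/- 0.056
  subphase roughness change:      2.98 +/- 0.39 A
```

The fitted tail layer of the pure SAPC monolayer comes back at 11.74 Å
(generating value 11.8 Å) and the paired pipeline recovers the
oxidation-induced tail shortening of ~3 Å (26.6 % of the initial length),
the increase in headgroup density, and the roughening of the
film/subphase interface.

A command-line interface wrapping the same functions is installed as
`exec/lipidxr` (`simulate`, `fit-slab`, `fit-spline`, `compare`,
`replicate-paper`).

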