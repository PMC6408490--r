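---
title: "Kinetic analysis of chloride-promoted acid-catalyzed fructose dehydration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of chloride-promoted acid-catalyzed fructose dehydration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorkin)
```

## The problem

Dehydration of fructose to 5-hydroxymethylfurfural (HMF) over strong
Brønsted acids is strongly solvent-dependent: in polar aprotic
solvent/water mixtures such as γ-valerolactone (GVL) with 10% water, rate
constants rise by over an order of magnitude relative to pure water, and
adding catalytic (millimolar) amounts of chloride salts raises them
further — up to an order of magnitude between HCl and H2SO4 at equal acid
loading. `chlorkin` packages the kinetic analysis behind such studies:
estimating specific-acid rate constants from batch concentration–time
profiles, modelling the chloride enhancement as saturable binding of the
chloride ion to the rate-determining transition state, and the Arrhenius,
isotope-effect and free-energy bookkeeping around it.

## Rate law and rate-constant estimation

Acid catalysis of a reactant R admits both specific-acid and general-acid
channels, `r = k_H+ [R][H+] + k_HB [R][HB]`. Measured solvent kinetic
isotope effects for this chemistry are *inverse* (k_D/k_H of 1.7–2.7),
the signature of fast pre-equilibrium protonation; the general-acid term
is therefore neglected and every profile is fit to the specific-acid
pseudo-first-order law

$$R(t) = R_0 \, e^{-k\,[\mathrm{H}^+]\,t},$$

with `[H+]` constant over a batch run (strong acids are essentially fully
dissociated in these media). `fit_rate_constant()` estimates `k`
(M⁻¹ ks⁻¹) and `R_0` by Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nls.lm`), reporting 95% intervals from the linearized
(Jacobian-based) covariance with Student-t quantiles on n − p degrees of
freedom; profile-likelihood intervals are available with
`ci = "profile"`. Salt-only experiments (no acid) fit the same law with
the salt concentration as the reference catalyst concentration.

Two estimation choices deserve comment:

* **R₀ is fitted, not fixed.** The nominal loading initializes the fit;
  estimating it absorbs dilution and calibration error in the first
  sample.
* **Residuals are relatively weighted by default.** Chromatographic
  concentration measurements carry *relative* (multiplicative) error, and
  the synthetic generator reproduces exactly that structure. Minimizing
  plain squared concentration residuals under relative error
  underestimates the parameter variance where concentrations are large,
  and the resulting Wald intervals under-cover (the package's Monte-Carlo
  coverage test fails the 0.90–0.99 band with absolute weighting).
  `weighting = "relative"` divides residuals by the model value, making
  the error model variance-consistent; measured coverage then sits within
  the nominal band. `weighting = "absolute"` restores the plain-SSE
  objective for comparison. Both give identical estimates on noiseless
  data.

Degenerate inputs — flat or rising reactant series, total predicted decay
below 10⁻⁶ — set `converged = FALSE` rather than reporting a spurious
rate.

`compute_yield()` evaluates conversion (1 − R/R₀), yield (P/R₀, 1:1
stoichiometry) and selectivity at a requested conversion, interpolating
linearly in time between bracketing samples; `fold_change()` forms rate
ratios, rounding half-up in `nearest_int` mode so that a ratio of 9.5
reads as "10-fold", and `kie_ratio()` forms k_D/k_H with first-order
error propagation, classifying ratios above 1 as inverse.

## The chloride saturation-enhancement model

The promotional effect of chloride is modelled as reversible association
of Cl⁻ with the rate-determining transition state R‡,

$$\mathrm{Cl^-} + R^\ddagger \overset{K_{\mathrm{Cl}}}{\rightleftharpoons} R\mathrm{Cl}^\ddagger,$$

so the fraction of transition states carrying a chloride is the
Langmuir-form saturation fraction
`f = K_Cl[Cl⁻] / (1 + K_Cl[Cl⁻])` (`saturation_fraction()`). With the
chloride-free channel proceeding at `r_o` and the chloride channel faster
by the factor `r_enhance = r_Cl / r_o`, the observed rate constant is

$$k_{\mathrm{obs}} = r_o\left[1 + r_{\mathrm{enhance}}
  \frac{K_{\mathrm{Cl}}[\mathrm{Cl^-}]}{1 + K_{\mathrm{Cl}}[\mathrm{Cl^-}]}\right],$$

increasing and concave-down in chloride, rising from `r_o` to the plateau
`r_o (1 + r_enhance)`. `fit_chloride()` fits this law to
rate-constant-versus-chloride tables:

* **Parameterization.** All three parameters are positive by
  construction; fitting proceeds in log-parameter space, which enforces
  positivity without active box constraints and makes the relative-scale
  covariance natural. Intervals are mapped back to the natural scale by
  the delta method.
* **Initialization.** `r_o` from the smallest-chloride point, `r_enhance`
  from the plateau/baseline ratio minus one, `K_Cl` from the reciprocal
  of the half-rise chloride level.
* **Weighting.** Residuals are divided by the model value
  (`weighting = "relative"`), so solvent systems whose rate constants
  span orders of magnitude (0.1 to 100 M⁻¹ ks⁻¹ across 5–90% GVL)
  contribute comparably to the pooled objective.
* **Shared enhancement.** With several solvents the enhancement factor is
  shared across solvents by default while `r_o` and `K_Cl` stay
  solvent-specific. Whether the enhancement really is solvent-independent
  is a model restriction, not a law; the fit therefore always computes
  both the shared and the free-enhancement fits and reports an F test for
  the restriction. One solvent reduces exactly to the single-solvent fit.
* **Identifiability.** A table with no curvature (rates flat in
  chloride) leaves `K_Cl` unidentified; the fit flags this
  (`identifiable = FALSE`, infinite upper CI on `K_Cl`) instead of
  raising an error, and drives `r_enhance` to zero.

`k_vs_kcl_relation()` regresses the chloride-free rate constant on the
fitted `K_Cl` across solvent systems (ordinary least squares): both grow
with the GVL fraction, and their linear relation (slope ≈ 0.84,
intercept ≈ −0.87 in M⁻¹ ks⁻¹ against M⁻¹ for the bundled benchmark
systems) summarizes that co-variation.

## Arrhenius, Eyring and free-energy bookkeeping

`fit_arrhenius()` regresses ln k on 1/T (the conventional
linearization; a direct nonlinear fit is available) with
Ea = −slope·R, R = 8.314462618×10⁻³ kJ mol⁻¹ K⁻¹ throughout.
`assemble_profile()` performs the apparent-barrier bookkeeping for the
two-step dehydration mechanism: the apparent activation free energy is
the exact sum of the reaction free energy to form the oxocarbenium ion
(protonation of the C2 hydroxyl plus water elimination) and the
activation free energy for deprotonation of that ion. `barrier_delta()`
differences two assembled barriers, and `eyring_rate_ratio()` converts a
barrier difference into the implied rate ratio
`exp(−ΔΔG/(R T))` — used only for qualitative trend comparison against
measured rate constants, never as a fitted quantity. Benchmark component
tables ship with the package (`reference_free_energy_table()`, with
provenance notes on rows whose components carry corrections), alongside
benchmark rate-constant tables for acids (`reference_acid_table()`) and
acid/salt systems (`reference_salt_table()`).

## What the synthetic generator emulates

`simulate_profile()` produces batch profiles from the minimal reaction
network consistent with the three monitored species:

* fructose → HMF with branching fraction `selectivity` (default 0.8, the
  HMF-selectivity scale observed in chloride-containing GVL), the
  remainder routed to unobserved condensation byproducts (humins);
* HMF → levulinic acid with rate constant `k_deg`;
* all steps pseudo-first-order in the catalyst concentration;
* closed-form solutions of the consecutive scheme, so noiseless profiles
  satisfy the analytic solutions to machine precision and conserve mass
  (R + HMF + levulinic acid + humins = R₀ at every time);
* multiplicative log-normal noise with unit mean and CV `noise_cv`
  (default 0.05, an HPLC-like relative error) applied per observation,
  reproducible from the seed.

Defaults reproduce a typical experiment: 50 mM fructose, 5 mM acid,
sampling from t = 0 (the nominal loading) across several half-lives.
Internal units are M and ks; the CSV reader converts declared `mM` and
`min` columns.

`generate_chloride_table()` applies the saturation-enhancement law as the
generative model. The default `chloride_design()` encodes five GVL/water
systems (5, 25, 50, 75, 90% GVL) with shared enhancement 5 and
per-solvent parameters chosen on the benchmark linear relation
`k_o = 0.84 K_Cl − 0.87` with K_Cl = (1.2, 2.5, 5, 12, 25) M⁻¹ — anchoring
the 5% GVL baseline near the water-like 0.14 M⁻¹ ks⁻¹ and the 90% GVL
baseline at 20 M⁻¹ ks⁻¹ — over a chloride grid from 0 to 2.5 M.

What the generator does **not** emulate: reactor heat-up transients
(profiles are isothermal), stirring and mass-transfer effects, solvent
hydration equilibria, activity-coefficient corrections at high salt, and
anion-specific chemistry beyond labels. Passing recovery tests on this
generator therefore validates the estimators under the assumed error
model, not the chemistry of any particular reactor.

## Problem sizes and numerical choices

The package's simulation studies use sizes chosen to characterize the
estimators well while staying light: 500-replicate Monte-Carlo coverage
for the rate-constant interval (20 points per profile, 5% noise),
200-replicate recovery for single-solvent `K_Cl`, 20 seeded replicates of
the five-solvent global design (40 observations each), and 11 replicates
in the acceptance script (median reported). Levenberg–Marquardt runs with
tight tolerances (ftol, ptol ≈ 1e-15) so noiseless inversions are exact
to ≤ 1e-6 relative error; interval coverage for the defaults falls inside
the 0.90–0.99 band asserted by the test suite.

## Known limitations

* The transition-state binding picture is a phenomenological saturation
  model; `K_Cl` should not be over-interpreted microscopically (ion
  pairing and solvation-shell structure are outside its scope).
* Anions other than chloride are carried as labels only; no
  anion-specific model terms are fitted.
* Profiles are fit per condition, independently; no joint multi-profile
  or multi-temperature regression is attempted.
* The KIE machinery computes and classifies ratios; it does not model the
  isotope effect mechanistically.
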