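---
title: "The steric NOM-CD model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The steric NOM-CD model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snomcd)
```

## The problem and the model

Glyphosate (PMG) binds goethite through its phosphonate group, and
adsorbed humic acid (HA) competes with it by three mechanisms: direct
occupation of singly coordinated surface sites, electrostatic
repulsion by the negative charge HA places in the compact layer, and —
the contribution this package centres on — steric coverage of sites by
the voluminous HA supramolecules. Small oxyanions can slip underneath
adsorbed HA; a stretched-out glyphosate molecule occupying the full
Stern-layer depth cannot. The S-NOM-CD model captures all three
mechanisms inside one surface complexation framework.

### Surface complexation core

The equilibrium chemistry is a classical tableau: components (aqueous
masters, surface sites, surface components), species defined by
stoichiometry and an intrinsic log K, and mass-action equations
coupled to mass/site balances. Goethite carries singly (FeOH⁻⁰·⁵,
3.45 sites nm⁻²) and triply (Fe₃O⁻⁰·⁵) coordinated oxygens whose
proton and NaNO₃ ion-pair reactions produce the primary charging;
the proton constant of both site types equals the point of zero
charge (9.3) so bare-surface neutrality at that pH is built into the
database rather than emergent from tuning.

Charge distribution follows the CD-MUSIC convention. Each surface
species carries a triplet (Δz0, Δz1, Δz2): the charge its formation
reaction adds to the surface plane, the inner Stern plane and the
outer Stern plane. Reference charges of surface components are
counted in plane 0, so the triplet must sum to the total charge of
the aqueous reactants — `validate_database()` enforces exactly this
bookkeeping, which also reconciles the two notations in circulation
(total plane charges as superscripts versus added charges as Δz).

### NOM-CD and the steric extension

Adsorbed NOM is not partitioned thermodynamically; its interfacial
density is an input. The component HNOM⁻¹ (two carboxylates, one
protonated) forms three species on FeOH sites — inner-sphere FeNOM
(log K = 0) and FeNOMH (log K_H, NOM-specific), outer-sphere
FeOH₂–NOM (log K = 0.6) — whose balance shifts with pH through the
electrostatic factors: the outer-sphere species gains weight as the
surface potential falls, which is why the outer-sphere fraction f_OS
rises with pH. The carboxyl distribution ratio over the first Stern
layer is reported as R = 0.5 (1 − f_OS): a fully inner-sphere NOM
layer has half its carboxylates in plane 1 (R = 0.5), a fully
outer-sphere layer none (R = 0). FeNOMH is counted with the
inner-sphere pool; this convention reproduces the four anchor pairs
(f_OS, R) = (2.5 %, 0.49), (35 %, 0.32), (75 %, 0.10), (90 %, 0.05)
to within 0.03, which is the tightest consistency the rounded anchors
support.

The steric component S⁰ is zero-charged and occupies FeOH sites. For
every proton/electrolyte FeOH species a mirror species with one S⁰
and identical log K and Δz exists (`augment_with_steric_sites()`), so
the blocked sub-pool titrates exactly like the free pool and primary
charging is unchanged in the absence of glyphosate — the package
asserts σ₀ equality to 10⁻¹⁰ C m⁻². Glyphosate and HNOM have no
mirrors: blocked sites are invisible to them. The S⁰ density is
conditional on solution chemistry,

$$\theta_S = \frac{K\,(H)^a I^b}{1 + K\,(H)^a I^b},\qquad
  [\equiv\!S^0] = \theta_S\,[\equiv\!S^0_{max}],$$

with K = 80, a = 0.32, b = −0.33 (empirical coefficients of the
conditional maximum Stern-layer occupation by NOM; proton activity is
the dimensionless 10^−pH, which reproduces the worked values
θ_S ≈ 50 % at pH 7 and ≈ 85 % at pH 4.5 in 0.1 M). θ_S is defined as
the allowed fraction of the physical Stern-layer capacity
(Γ_MST⁰ = 1 mg NOM m⁻²); that definition documents the meaning of
θ_S but the computation only ever uses the two equations above.
S⁰_max is the single adjustable parameter.

## Electrostatic sub-model and solver

The interface is an extended Stern stack: capacitor C1 between planes
0 and 1, C2 between planes 1 and 2, and a Gouy–Chapman diffuse layer
(symmetric 1:1 electrolyte, 25 °C) at the head of plane 2. The solver
works on log₁₀ free activities of the non-fixed components plus the
log₁₀ Boltzmann factors of the three planes, with residuals

* one mass/site balance per component (relative to its total),
* σ₀ − C1(ψ₀ − ψ₁), σ₀ + σ₁ − C2(ψ₁ − ψ₂), and
  σ₀ + σ₁ + σ₂ + σ_d(ψ₂),

solved by damped Newton iteration with an analytic Jacobian: full
steps capped at 3 log units, residual-norm backtracking with up to 30
halvings, convergence at 10⁻¹⁰ (relative for balances, C m⁻² for the
charge relations; converged systems typically reach 10⁻¹² or better, so
the conservation assertions at 10⁻¹⁰ have margin). The initial guess
is ψ = 0 and free activities at 10 % of totals; a previous solution
can be supplied as a warm start, which the fitting routine uses
point-wise (warm starts change only the iteration path, not the
converged answer). There is no randomness anywhere in the solver:
identical inputs give bit-identical output.

Activity corrections use the Davies model (A = 0.509, 0.3 linear
term), the standard companion of CD-MUSIC databases at I ≤ 0.1 M;
surface species carry no activity coefficient. Ionic strength is
nominal (the electrolyte level) by default, matching how batch
experiments are reported; a self-consistent computed mode iterates
the Davies correction to a fixed point. pH is imposed as a fixed
proton activity and the proton balance dropped, because batch pH is
measured per point. Temperature is fixed at 25 °C throughout.

Degenerate inputs are handled explicitly: components with zero totals
are pruned together with their species (so a glyphosate-free system
never carries glyphosate unknowns); a zero solid concentration
removes the surface and the electrostatic unknowns entirely; surface
component demand at or above the available site total raises an
infeasibility error naming the site balance; non-convergence either
errors with the residual norm or, on request, returns the unconverged
state flagged.

## Parameters and defaults

| Parameter | Unit | Default | Origin |
|---|---|---|---|
| FeNOM_T | µmol m⁻² | 1.77 | from Q_RCOO = 2.5 mol kg⁻¹ via slope 0.89 |
| Γ_ref | mg HA m⁻² | 1.6 | maximum loading of the batch design |
| K, a, b (θ_S) | — | 80, 0.32, −0.33 | empirical Stern-occupation relation |
| S⁰_max | µmol m⁻² | 2.56 | fitted; the model's one free parameter |
| FeOH site density | nm⁻² | 3.45 | goethite crystallography |
| Fe₃O site density | nm⁻² | 2.70 | literature goethite model |
| C1, C2 | F m⁻² | 0.85, 0.75 | literature values for this goethite |
| PZC / log K_H sites | — | 9.3 | acid–base titration of the goethite |
| log K Na⁺ / NO₃⁻ pairs | — | −0.6 offset | symmetric electrolyte binding |
| log K_H (FeNOMH) | — | 6.0 | NOM-specific literature default |
| PMG aqueous log K | — | 10.14, 15.60, 17.83 | cumulative protonation ladder of glyphosate |
| PMG surface log K, Δz | — | 22.5 / 25.5, (0.3, −1.3, 0) / (0.3, −0.3, 0) | representative, see below |
| A (specific surface) | m² g⁻¹ | 94 | BET of the goethite |
| solid | g L⁻¹ | 10 | batch concentration |

Everything outside the printed core lives in `default_config()` and
can be overridden or supplied as JSON; the printed core (site density 3.45 nm⁻², PZC 9.3, the NOM triplet
log K 0 / log K_H / 0.6 and its Δz values) is fixed in
`default_database()`.

The glyphosate surface complexes deserve a frank note. Their
published constants for this goethite are not reproduced here; the
package ships representative values for a monodentate phosphonate
complex with and without a protonated carboxylate. Their magnitudes
were set so the model reproduces the documented gross behaviour of
the system — glyphosate adsorption above 70 % across the batch
design, about 100 of the 144 design points above the 6·10⁻⁷ M
detection limit, and measurable dissolved concentrations spanning
roughly 10⁻⁶–10⁻⁴ M. Absolute predictions for real goethite
therefore depend on substituting measured constants via the config;
all structural conclusions (nesting, charging neutrality of S⁰,
monotonicities, parameter recovery) are insensitive to this choice.

## The synthetic data generator

`design_spec()`/`generate_design()` emulate the structure of the
batch study: HA loadings 0.5–1.6 mg m⁻², target pH 4–8 with a
within-isotherm scatter of at most 0.3 units (uniform, seeded),
NaNO₃ at 0.1 and 0.01 M, and a 1.45 mM glyphosate stock dosed at
0.05–0.50 of the final volume, giving the 0.725 mM top concentration
of the design. `reference_design()` reproduces the actual 16-isotherm
layout (high HA at low pH only, the low level duplicated in both
electrolytes; 144 points). Observations are the model truth perturbed
by multiplicative log-normal noise (σ = 0.2 log₁₀ units, chosen to
match the scatter a log-RMSE of ≈ 0.2 implies) and censored below the
detection limit of 6·10⁻⁷ M.

What the generator does *not* emulate: HA partitioning and the
composite pre-equilibration (loading is assigned, as it is measured
in the emulated workflow), drift of pH during equilibration,
dilution-correction error propagation, and any pH dependence of the
measurement error. Passing recovery tests therefore demonstrate the
identifiability and correctness of the estimation machinery under
the stated noise model, not the field accuracy of the model for
arbitrary real datasets.

## Fitting and the recovery study

`fit_parameters()` minimises the RMSE between modelled and observed
log₁₀ dissolved glyphosate — the natural objective when
concentrations span three decades — by bounded Levenberg–Marquardt
(S⁰_max ∈ [0, 6] µmol m⁻², neutral start at 1). Confidence intervals
are first-order (Jacobian-based) 0.95 intervals and r² is computed on
the log₁₀ concentrations, consistent with the objective. Observations
at or below the detection limit are excluded from the objective,
mirroring how below-LOD measurements are treated in the emulated
workflow.

That exclusion has a statistical cost worth documenting: when many
observations sit within about two noise standard deviations of the
LOD, dropping the ones that fluctuate below it keeps a
high-biased sample, and the steric parameter — whose information is
concentrated in exactly those low-pH, low-concentration points —
inherits an upward truncation bias of several percent. A noise-free
dataset is recovered exactly (the package asserts 10⁻³ relative), so
this is a property of censoring, not of the optimiser. The Monte
Carlo recovery study is therefore run on the measurable window of
the design (HA 1.1 and 1.6 mg m⁻², pH 6–8, both electrolytes, the
full nine-dose series: 108 points of which typically ≈ 105 are
usable): across twenty seeded replicates at σ = 0.2 the mean estimate
falls within 5 % of the generating S⁰_max = 2.56 µmol m⁻² and the
0.95 interval covers the truth in at least 18 of 20. The
study-layout emulation (with its censored low-pH isotherms) is
exercised separately as a full-pipeline check, where the estimate is
required to stay within 25 % of truth with fit quality comparable to
the reported experimental fit (RMSE ≈ 0.2, r² > 0.9).

## Known limitations

* Single goethite surface; no multi-mineral assemblages, kinetics,
  transport, or aqueous NICA-Donnan binding of HA.
* NOM loading is an input; the model cannot predict HA adsorption
  itself, and θ_S is an empirical closure, not a mechanical theory of
  HA conformation.
* With the shipped representative glyphosate constants, the
  ionic-strength dependence of glyphosate sorption in the presence of
  HA is reproduced at pH ≳ 6 (sorption lower at 0.01 M than at
  0.1 M); at the lowest loadings and pH the bare-surface screening
  term can invert the trend. The inversion point moves with the
  glyphosate charge-distribution coefficients, which are
  configuration, not structure.
* The uncertainty of the proportionality slope (0.89 ± 0.10) and of
  FeNOM_T (± 0.20) is carried as metadata and propagated to a
  first-order uncertainty statement only; it is deliberately not
  folded into the fit, which conditions on FeNOM_T as the emulated
  study does.
* Tableau I/O supports the package's own TSV dialect only; no
  PHREEQC/ORCHESTRA import, no temperature or pressure corrections,
  no mineral dissolution.

## Problem sizes used in the shipped checks

Conservation laws are asserted on a 50-system grid spanning pH 4–8,
both electrolytes, three glyphosate levels and two HA levels; the
recovery study uses 20 replicates of the 108-point design described
above; the full-pipeline emulation uses the 144-point reference
layout. These sizes keep the complete check suite at roughly a
minute of solver time while touching every regime the model
distinguishes.
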