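---
title: "Model and methods behind alzsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind alzsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(alzsim)
```

# The model

`alzsim` integrates an eighteen-species network model of Alzheimer's disease
progression. The state couples three layers:

1. **Protein pathology.** Intraneuronal amyloid-β (`Abi`) is produced
   constitutively and overproduced under a reactive-oxygen-species (ROS)
   signal; its production and degradation both scale with the surviving
   neuron fraction `N/N_0`. The extracellular pool (`Abo`) is fed by dying
   neurons (which release their intraneuronal content at the neuronal death
   rate), by live neurons and by activated astrocytes, and is cleared by
   phagocytes. A soluble oligomer pool (`AO`) forms from `Abo` and is the
   diffusible, microglia-activating face of the amyloid pathology.
   Hyperphosphorylated tau (`tau`) is produced constitutively and under ROS,
   condenses into intracellular tangles (`Fi`), and tangles are released as
   extracellular NFT (`Fo`) when neurons die.
2. **Cells.** Live neurons (`N`) die through two saturating channels —
   intracellular tangles and TNF-α, the latter inhibited by IL-10 — and
   accumulate as dead neurons (`Nd`) until microglia and macrophages clear
   the debris. Astrocytes (`A`) are activated by TNF-α and amyloid.
   Resident microglia are activated by extracellular NFT and oligomers;
   peripheral macrophages enter the tissue at a rate gated by the chemokine
   MCP-1 through `α·P/(P+K_P)·(M_0 − M̂)`, an averaged form of a vessel-wall
   flux condition. Both populations split at activation into
   proinflammatory (`M1`, `Mh1`) and anti-inflammatory (`M2`, `Mh2`)
   phenotypes in proportion `βε₁ : ε₂`, where `ε₁` and `ε₂` are the
   saturated TNF-α and IL-10 signals and `β` weights the proinflammatory
   environment; TGF-β converts the proinflammatory phenotype to the
   anti-inflammatory one.
3. **Mediators.** TNF-α is produced by `M1`-type cells, TGF-β and IL-10 by
   `M2`-type cells, MCP-1 by astrocytes and `M2` microglia; HMGB-1 is shed
   by dead neurons. All six degrade linearly and, in spatial mode, diffuse.

The ROS input is not a state variable but a prescribed signal,
`R(t) = R_0·t/100` for the first 100 days and `R_0` afterwards
(`ros_forcing()`). The disease amplitude `R_0 = 6` is derived from the
ratio of diseased to healthy intraneuronal amyloid steady states.

Dimensional bookkeeping: concentrations are g/ml and cell densities g/cm³;
since 1 ml = 1 cm³ the two are numerically identical and the model mixes
them freely. `lambda_tau` carries units g/ml because it multiplies the
dimensionless ROS signal. Time is days throughout; "10 years" means 3650
days.

## Which clearance law, and why it matters

The constant set underlying this model was assembled from literature
measurements through steady-state balances, and the balance used for the
neuronal amyloid production rate treats phagocytic clearance of the plaque
pool as **linear (mass-action)** in `Abo`:

```
clearance = (d_AboMh·(Mh1 + θ·Mh2) + d_AboM·(M1 + θ·M2)) · Abo
```

A saturating Michaelis form `Abo/(Abo + Kbar_Abo)` with `Kbar_Abo = 7e-3`
g/ml is sometimes written for the same term. The two laws are not
interchangeable at these constants: under the saturating form the plaque
pool equilibrates near 5e-8 g/ml, two orders of magnitude below the
~7e-6 g/ml measured in end-stage disease tissue, and the production-rate
derivation chain stops reproducing its own published result
(`derive_appendix_parameters()` recovers the printed `lambda_N` only under
the linear law). The package therefore defaults to
`abeta_clearance = "mass_action"`, which reproduces the clinically anchored
end-stage amyloid level (8.8e-6 g/ml in the default run), and exposes
`"saturating"` as an explicit option for exploring the alternative reading.
Under the mass-action reading the `d_Abo*` constants are effective rates
per unit phagocyte density. Dead-neuron clearance keeps its printed
Michaelis form `Nd/(Nd + Kbar_Nd)`.

## Parameters and provenance

`ad_parameters()` returns the 75 constants with the tabulated defaults;
`ad_parameter_table()` adds units, description and a provenance class. Five
constants have a documented conflict between the tabulated default and the
value implied by the derivation chain (`lambda_tau0` 8.1e-11 vs 3.78e-11;
`d_NF` 3.4e-4 vs 2.4e-4; `d_NdM` 0.06 vs 0.6; `d_NdMh` 0.02 vs 0.2; `K_AO`
1e-7 vs 2.8e-7). The tabulated value is always the simulation default; the
alternate is stored, never silently substituted, so either reading can be
run by explicit override:

```{r}
ad_parameters(d_NdM = 0.6, d_NdMh = 0.2)
```

`derive_appendix_parameters()` re-executes the whole derivation chain from
its primary inputs — half-lives converted through `ln 2 / t½`
(`halflife_to_rate()`), diffusivities scaled by inverse cube root of
molecular weight from a 24-kDa reference (`derive_diffusion()`), cell
counts times cell volume for reference densities, and per-equation steady
balances — and flags each derived value that does not agree with its
published figure at printed precision. Two derivations are knowingly
irreproducible from their stated constraints (the astrocyte activation
rates and the neuron-death split `d_NF`/`d_NT`, whose printed balance
formula yields 3.04e-4/1.52e-4 at `γ = 1`); they are recorded as primary
values with conflict notes rather than re-derived.

## Initial state and trial protocol

`ad_initial_state()` is a diagnosed disease state: each variable starts
below (above) its expected long-run level if it grows (declines) with the
disease. Peripheral macrophages and dead neurons start at zero. The
oligomer pool has no published starting value; it starts at zero and
reaches its quasi-steady level within days (its relaxation time is
`1/d_AO ≈ 1` day), which is immaterial at the 10-year horizon.

Virtual trials run the untreated model to day 300 ("diagnosis") and apply
the drug continuously thereafter. Treatment switching is a hard
discontinuity, so the integrator restarts at each start day; the same
restart grid can be imposed on the untreated reference (`restart_at =`) so
that a zero-dose treatment reproduces the untreated trajectory bit for bit
— this is a tested invariant, not an approximation.

## Numerics

* **Well-mixed mode.** `deSolve::ode(method = "lsoda")` with `rtol = 1e-6`,
  `atol = 1e-12`. The rate constants span five orders of magnitude
  (TGF-β degrades at 333/day, extracellular NFT at 2.8e-4/day) and state
  magnitudes span 1e-11 to 1e-1 g/ml, so a stiff adaptive method with a
  tight absolute floor is required.
* **Degenerate denominators.** Every activation quotient `X/(X+K)` is 0 at
  `X = 0` (and transiently negative solver excursions are clamped to 0
  inside the right-hand side); the IL-10 inhibition factor is 1 at
  `I10 = 0`; the phenotype split is (0, 0) when both signals vanish, i.e.
  no activation without a cue. The macrophage influx `α(P)·(M_0 − M̂)` is
  floored at zero if `M̂` transiently exceeds `M_0`.
* **The |dN/dt| release terms.** The extracellular amyloid and NFT
  equations contain the magnitude of the neuron derivative. Since the
  neuron equation has only death terms, this magnitude equals the analytic
  death rate (`neuronal_death_rate()`), which keeps the system an
  autonomous ODE instead of requiring numerical differencing.
* **Spatial mode.** Method of lines on an `n × n` periodic grid over the
  unit square (default `n = 32`; the domain is taken at face value in cm).
  Diffusion uses the second-order five-point Laplacian. The chemotaxis
  terms `∇·(M∇H)` (microglia toward HMGB-1) and `∇·(M̂∇A_O)` (macrophages
  toward oligomer) are advective, and naive central differencing can drive
  cell densities negative; they are discretised in conservative flux form
  with donor-cell upwinding — face velocity from the attractant gradient,
  transported density from the upwind cell — which preserves positivity
  and conserves the domain sum to machine precision (tested). Upwinding is
  first-order accurate in space, which is acceptable because the
  physically meaningful regime here is weakly heterogeneous. Periodic wrap
  is applied to the cell fluxes as well as the diffusible species — the
  only self-consistent choice on a periodic domain. The semi-discrete
  system (18 n² equations) is integrated with the sparse stiff solver
  `lsodes`.
* **Spatial oracle.** With uniform initial fields both operators vanish
  identically and the domain means must reproduce the well-mixed
  trajectory; the suite checks agreement over the full 10-year horizon to
  0.1%. Initial fields default to uniform (the baseline reports averages
  only); `ad_initial_fields(perturb =, seed =)` provides a seeded random
  perturbation for exploration, and grid refinement 8 → 16 changes 10-year
  domain means by well under 1% on perturbed runs.

## Efficacy, synergy, sensitivity

`treatment_efficacy()` reports `E_N`, `E_Aβ` and the relative reduction in
cumulative neuronal death `((N(0)−N_u(T)) − (N(0)−N_t(T)))/(N(0)−N_u(T))`.
With ≈50% ten-year neuron loss the death reduction and `E_N` agree to
first order (both are reported; they differ by <1% relative in the default
runs). Maps share a single untreated reference across all cells, and
failed cells are flagged rather than aborting the map. `synergy_index()`
flags cells whose monotherapy denominator is not positive (the zero-dose
row and column) as undefined rather than erroring.

The sensitivity module perturbs eight quantities: `lambda_N`, `lambda_A`,
`d_NF`, `d_NT` over [½×, 2×] their defaults, and four group multipliers
over [½, 2] that scale parameter pairs jointly — `gamma_tilde` (TNF-α
production by both cell types; renamed from γ to avoid colliding with the
IL-10 inhibition ratio), `delta` (TGF-β production), `xi` (MCP-1
production), `epsilon` (amyloid clearance by both phagocyte types).
Distributions are uniform within the ranges. `lhs_sample()` produces a
seeded Latin hypercube (one point per equal-probability stratum per
factor); `prcc()` rank-transforms all columns (midranks on ties), removes
the other factors from each factor and from the output by linear
regression on ranks, correlates the residuals, and derives p-values from
`t = r·sqrt((n−2−p)/(1−r²))` with `p` conditioning factors. The engine is
validated in the test suite against an independent precision-matrix oracle
(partial correlations from the inverse rank-correlation matrix) and
against analytic Gaussian partial correlations. Failed or non-finite
simulations are excluded listwise with a reported count, since PRCC needs
complete rows. The published-scale design is `n = 2000`; the suite runs a
reduced `n = 200` (and smaller for unit tests), which preserves the sign
structure while weakening significance.

## What the defaults do and do not reproduce

With the tabulated defaults, the untreated run loses 50.1% of neurons over
ten years (5.0% of the initial density per year on average) and ends with
8.8e-6 g/ml extracellular amyloid-β; tau, intracellular NFT and all four
phagocyte populations settle within a factor two of the steady values
assumed in the derivation chain. Three mediators do not: TGF-β and IL-10
equilibrate 3.5–4× above their nominal half-saturation constants — a level
implied by the constant set itself (their production/degradation constants
and the assumed `M2`-type densities are mutually inconsistent with the
`K` values) — and HMGB-1 runs far below its nominal level because the
dead-neuron pool equilibrates near 4e-6 g/ml rather than the 2.5e-4
assumed when its release rate was derived.

Treatment responses show the same decoupling visible in the sensitivity
analysis: anti-amyloid treatment controls the amyloid endpoint strongly
(up to ~75% reduction at the largest mapped doses) while the neuron
endpoint improves by only ~6%, and the TNF-α channel saturates once `f`
exceeds about ten times the TNF-α degradation rate, so the neuron benefit
plateaus across the mapped dose range and the synergy index sits at
σ_N ≈ 1 rather than clearly above it. These are properties of the printed
constant set (the TNF-α-mediated share of neuronal death is ~10% under the
tabulated `d_NF`/`d_NT`/`K` values, and amyloid production is dominated by
the live-neuron term), and the package reports them as computed rather
than adjusting constants to steer them.

## Scope and limitations

* Gross anatomy is abstracted away: no vasculature geometry (the
  macrophage influx term replaces vessel-boundary fluxes), no white-matter
  structure, and the unit-square periodic domain is a verification and
  exploration device, not a brain map.
* Dendritic/synaptic pathology, GSK-3 and APP are not dynamic variables;
  ROS is an imposed signal, not a modelled species.
* No pharmacokinetics: treatments are constant-rate modifications from the
  start day, addressing efficacy only — no dosing schedules, drug
  clearance or toxicity constraints.
* No parameter re-estimation or calibration machinery; constants come from
  the recorded derivation chain and are overridable, not fitted.
* Test problem sizes are chosen for desk-scale determinism: spatial checks
  run on 8–16² grids and sensitivity tests at n ≤ 200; the published-scale
  settings (32² grid, n = 2000) are the documented defaults of the
  corresponding functions.
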