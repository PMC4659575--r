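---
title: "Methods: coupled electromechanics of the human atrium at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled electromechanics of the human atrium at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`atriamech` simulates the electromechanics of human atrial myocytes and of
small pieces of atrial tissue. Three coupled layers make up the model.

**Electrophysiology.** The membrane model is the Courtemanche–Ramirez–Nattel
(CRN) human atrial action-potential model: 21 electrophysiological state
variables (membrane potential, 15 Hodgkin–Huxley gates, Na⁺/K⁺/Ca²⁺
concentrations and two sarcoplasmic-reticulum Ca²⁺ compartments). All
conductances are per-capacitance (nS/pF); concentrations are mM. Regional
electrical heterogeneity is expressed as multiplicative scale factors on the
maximal conductances of I_Na, I_to, I_CaL, I_Kr and I_Kur relative to the
right-atrial (RA/PM) baseline (`region_profiles()`); persistent-AF
electrical remodelling (AFER) is a second factor set (I_CaL −70 %, I_Kur
−50 %, I_to −65 %, I_K1 +100 %, I_Ks +100 %, I_NaCa +55 %, SERCA +50 %, RyR
+300 %, SR leak +25 %; `remodeling_profiles()`). The two compositions are
multiplicative and commute, and each factor is applied exactly once
(`build_cell_parameters()`).

Two points about the factor application deserve explanation:

* **SR leak.** The base model defines its SR leak through the SERCA maximum
  (leak = I_up,max · Ca_up / Ca_up,max). Scaling that shared symbol by the
  SERCA factor therefore also scales the leak, after which the leak's own
  +25 % applies; the package keeps a separate `k_leak` parameter but applies
  both factors (×1.5 × 1.25 under AF) to preserve the base model's
  structure.
* **Pulmonary vein.** The published regional factor table has no PV row,
  while the PV action potential duration is reported. The PV profile
  follows the shape used throughout the atrial-heterogeneity modelling
  lineage — reduced I_CaL and I_to, enhanced I_Kr — with magnitudes
  (G_to ×0.75, G_CaL ×0.25, G_Kr ×1.90) fitted once so the control PV cell
  reproduces the reported 181 ms APD₉₀ at 1 Hz steady state. It is a fitted,
  config-overridable profile, exactly as the source models were themselves
  fitted to AP morphologies.

**Myofilament mechanics.** Contraction uses the Rice et al. approximate
cross-bridge/cooperativity model: regulatory-unit states (non-permissive /
permissive), two cross-bridge states (pre- and post-powerstroke) with mean
strains, low- and high-affinity troponin Ca²⁺ binding, thick/thin filament
overlap as a function of sarcomere length (SL), exponential titin and
collagen passive elements, and a cell-shortening mode in which SL contracts
against an internal viscoelastic plus series-elastic load. Temperature
enters through Q₁₀ factors referenced to 37 °C; the package runs at 37 °C,
so the base rates apply unscaled. All myofilament parameters sit in the same
flat parameter vector and can be overridden.

The series-elastic stiffness (`KSE`, normalised force per µm, default 1) is
the one myofilament constant we calibrated: with titin alone the
quasi-static twitch equilibrium over-shortens the sarcomere (> 20 %),
because the soft titin element is the only restoring force. With `KSE = 1`
the control twitch shortens ≈ 12 % and shortening tracks the active-force
deficit under AF, matching the published twitch morphology. The resting
sarcomere length `SL0` is 1.9 µm (the myofilament model's slack length; the
source publication does not print a value).

**Coupling.** The two layers exchange Ca²⁺: cytosolic Ca²⁺ (converted
mM → µM) drives troponin binding, and the total troponin-bound Ca²⁺ flux
dTropTot/dt (µM/ms, converted back with the printed ×1/1000) enters the
myoplasmic Ca²⁺ balance together with the sarcolemmal term
−C_m (I_CaL + I_bCa + I_pCa − 2 I_NaCa)/(2 V_myo F) and the SR term, all
under instantaneous calmodulin buffering
1/(1 + [CMDN]_max K_m,CMDN/([Ca²⁺]_i + K_m,CMDN)²). The SR term is
implemented in the base model's conservative orientation,
(V_nsr (I_leak − I_up) + I_rel V_jsr)/V_myo: the printed equation carries a
sign and a factor on I_rel that would break total-Ca conservation against
the unchanged SR compartment equations, and conservation (checked to
< 0.5 % of the transient amplitude per beat in the test suite) is
non-negotiable for 1000-beat protocols. The active strain is
γ = (SL − SL0)/SL0.

## Numerics

* **Gates**: Rush–Larsen exact-exponential updates (gates cannot leave
  [0, 1] by construction).
* **Junctional-SR Ca²⁺**: the AF RyR ×4 factor makes this compartment stiff
  (rates over 100 ms⁻¹); it takes an exponential update of its
  frozen-coefficient linear balance, which is unconditionally stable and
  positivity-preserving.
* **Sarcomere length**: the internal viscoelastic load has a fast time
  constant (mass/visc); SL takes the exponential update of its linear form.
* Everything else is forward Euler. The default single-cell step is
  `dt = 0.02` ms; halving it changes APD₉₀ by < 0.5 ms (tested), and the
  whole path is cross-checked against `deSolve::lsoda` at rtol 1e-8 on a
  paced beat. A fixed-step scheme was preferred over an adaptive stiff
  solver because the tissue solver advances all nodes in lockstep; the
  exponential updates carry the stiffness.
* **Stimulus**: rectangular, 2 ms, amplitude defaulting to twice the
  diastolic threshold found by bisection (`calibrate_stimulus()`); the
  stimulus charge is assigned to K⁺ so that 1000-beat pacing does not drift
  unboundedly.
* **Tissue**: deformation-aware monodomain
  ∂V/∂t = −(I_ion + I_stim)/C_m-normalised + ∇·(D C⁻¹ ∇V) on regular 1D/2D
  lattices, Strang splitting (half reaction, full Crank–Nicolson diffusion,
  half reaction), 9-point tensor-aware finite-difference fluxes with
  no-flux boundaries, matrix-free BiCGStab for the implicit solve. The
  effective tensor D C⁻¹ is checked for symmetric positive-definiteness and
  the solver refuses non-SPD fields. Default `dx = 0.25` mm,
  d_l = 1.26 mm²/ms, d_t = 0.42 mm²/ms (3:1). Reaction sub-steps are capped
  at 0.01 ms by default; the large 2D runs below use 0.05/0.025 ms steps,
  justified by the CV-convergence tests.
* **Mechanics surrogate**: organ-scale finite-element elasticity is out of
  scope; the staggered exchange is preserved by a kinematic surrogate. Every
  `dt_mech = 1` ms the local γ (from SL) builds F₀ = I + γ f⊗f with
  incompressible transverse compensation, and C = F₀ᵀF₀ rescales the
  conductivity tensor. A prescribed-C mode covers analytic checks (e.g.
  C = diag(λ², 1) rescales longitudinal CV by 1/λ).
* **Continuum kernels** are pure functions: multiplicative decomposition
  F = F_e F₀, Guccione energy W = C₁ e^Q (C₁ = 0.831 kPa, C₂ = 14.31,
  C₃ = 4.49, C₄ = 10) evaluated in a deterministic fibre frame, analytic
  second Piola–Kirchhoff stress (finite-difference verified to 1e-6),
  traction-free homogeneous active contraction with exact incompressibility
  (the pressure eliminated algebraically), and divergence-theorem cavity
  volumes on closed, outward-oriented triangulations. For symmetric strain
  the printed cross-term form E₁₂E₂₁ + E₁₃E₃₁ coincides with the squared
  form; the kernels require symmetry and use it.

## Protocols and problem sizes

Single-cell results use the S1–S2 protocol: 1000 S1 stimuli at 1 Hz
(pre-pacing to steady state), biomarkers measured on the final beat; APD₉₀
is measured from the instant of maximum upstroke velocity to 90 %
repolarisation of the amplitude V_max − V_dia with V_dia sampled
immediately before the stimulus (the convention is not printed in the
source; this is the package's choice). The test suite runs 300–400-beat
profiles — the drift bound (< 1 ms APD₉₀ over the last 10 of 200 beats) is
itself tested — while `scripts/acceptance.R` reruns the full 1000-beat
protocol. S2 biomarkers are computed but steady-state S1 values are the
reported ones.

The 2D re-entry analogue runs on an 84 × 84 mm AF-remodelled sheet with
conductivities scaled to 25 % (a desk-size analogue: wavelength = CV × APD
at full conductivity exceeds 240 mm, which no desk-scale sheet can hold;
scaling conductivity shrinks the wavelength by the square root of the
factor while preserving the dynamics). S1 is a plane wave, S2 a quadrant
(cross-field) stimulus; the vulnerable window was located by scanning the
S2 delay, and sustained re-entry means activity outlasting 1000 ms after
S2. The scan and a verification run used 0.6 mm spacing with 0.05/0.025 ms
steps (sustained through a 1250 ms window, dominant cycle ≈ 120 ms); the
routine test profile coarsens to 0.7 mm and 0.1/0.05 ms steps, under which
the same re-entry persists (cycle ≈ 136 ms) — the qualitative outcome is
robust to the discretisation.

## What the fixtures emulate — and what they do not

Cables, fibred sheets and icospheres are generated in code
(`make_cable()`, `make_sheet()`, `make_icosphere()`), with seeds recorded in
run manifests for the one stochastic option (fibre-angle jitter). They
emulate the printed conductivities, anisotropy ratio, regional composition
and the cross-field induction geometry. They do not emulate anatomical
atrial geometry, rule-based fibre fields, SAN-driven activation, bath
loading (endocardial pressure), or organ-scale volume changes: passing the
tissue tests shows the propagation/coupling machinery is right at desk
scale, not that organ-scale contraction is reproduced.

## Known limitations and open reproduction gaps

* With the published AF factor set applied to the unmodified CRN base
  model, the AF-remodelled APD₉₀ comes out near 135–150 ms rather than the
  reported 188 ms. Sensitivity analysis attributes the gap almost entirely
  to I_K1 +100 % (with I_K1 unscaled the model gives ≈ 200 ms). The source
  lineage's cell model carries modified K⁺-current formulations and an
  I_KACh current that the CRN base lacks; we implement the printed factors
  on the printed base model and report the discrepancy rather than tune.
  Quantities downstream of the AF action potential (diastolic Ca²⁺, SR
  content, force reduction) inherit part of this gap.
* The Rice myofilament parameters are the published rat/rabbit set adapted
  to 37 °C via its Q₁₀ structure; the exact adjustments used by the source
  are not printed. All are overridable.
* The monodomain solver is finite-difference on regular lattices, not FEM
  on anatomy; the mechanics feedback is kinematic, not a solved elasticity
  problem. The continuum kernels are written so an FEM layer could be added
  on top.
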