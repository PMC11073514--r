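---
title: "Electro-mechano-energetic modelling of hiPSC cardiomyocytes in ischemia and reperfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electro-mechano-energetic modelling of hiPSC cardiomyocytes in ischemia and reperfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`cardiox` simulates a single human induced pluripotent stem cell derived
cardiomyocyte (hiPSC-CM) as a system of 33 ordinary differential equations
coupling four layers:

1. **Electrophysiology** (22 states). Paci-family hiPSC-CM formulation:
   spontaneous (unstimulated) action potentials from the interplay of the
   funny current, the L-type Ca²⁺ window current and the Na⁺/Ca²⁺ exchanger;
   fast and late Na⁺ currents, L-type Ca²⁺ current with voltage- and
   Ca²⁺-dependent inactivation, rapid and slow delayed rectifiers, inward
   rectifier, transient outward current, Na⁺/K⁺ pump, NCX, sarcolemmal Ca²⁺
   pump, background currents, and a three-gate ryanodine-receptor release
   model with SR-load sensitivity. Internally SI units are used (volts,
   seconds, mM, A/F), as in the Paci lineage.
2. **SERCA** — a two-state thermodynamic, metabolite- and pH-sensitive pump
   (Tran-lineage). The cycle is lumped into a cytosol-facing state and a
   phosphorylated SR-facing state in rapid equilibrium with their ligands;
   the four apparent rates are

   $$ap_1 = k_1^+ \frac{\phi_{Ca,i}\,a_{ATP}}{D_{cyt}},\quad
     am_2 = k_2^- \frac{\phi_{H,i}\,a_{Pi}}{D_{cyt}}\,\mu_H,\quad
     ap_2 = k_2^+ \frac{\phi_{H,sr}}{D_{sr}}\,\mu_H,\quad
     am_1 = k_1^- \frac{\phi_{Ca,sr}\,a_{ADP}}{D_{sr}}$$

   with $\phi_{Ca,i} = ([\mathrm{Ca}]_i/K_{d,Ca_i})^2$,
   $\phi_{H} = ([\mathrm H]/K_{d,H})^{n_H}$, $a_X = [X]/K_{d,X}$, competitive
   site partitions $D$, and a modulatory proton factor $\mu_H$ applied to
   both directions of the luminal edge (kinetic, so thermodynamically
   neutral). The backward rate constant $k_2^-$ is **not free**: the Haldane
   relation ties it to $\Delta G_{ATP}$ so the cycle flux
   $$v = \frac{ap_1\,ap_2 - am_1\,am_2}{ap_1+ap_2+am_1+am_2}$$
   vanishes exactly where the free energy of
   $\mathrm{MgATP} + 2\,\mathrm{Ca}_i + n_H \mathrm H_{sr} \rightarrow
   \mathrm{MgADP} + \mathrm{P_i} + 2\,\mathrm{Ca}_{SR} + n_H \mathrm H_i$
   is zero (a unit test constructs such a state and verifies $v = 0$ to
   1e-10). The phosphorylation fraction (PSP) is the stationary occupancy of
   the SR-facing lump. The pump flux is $I_{up} = S\,v$; the scale $S$ is
   the ratio of the maximum of the legacy saturating uptake
   $V_{max}/(1+(K_{up}/[\mathrm{Ca}]_i)^2)$ to the maximum of $v$ over a
   steady control beat, iterated to its fixed point by
   `scripts/calibrate_states.R` and frozen (`serca_S = 0.02847`). By
   construction the two formulations share the same peak uptake in control.
3. **Contractile element** (10 states, Rice/Tran-lineage mean field):
   troponin with explicit Ca²⁺ on-rate $K_{on}$ (the Ca²⁺-sensitizer
   target), a nonpermissive/permissive tropomyosin switch (Hill coefficient
   4 on bound troponin), strongly bound pre- and post-rotation crossbridges
   with mean strains, sarcomere shortening against a passive spring, and a
   super-relaxed (SRX) myosin pool exchanging first-order with the
   disordered-relaxed (DRX) pool that feeds attachment (the SRX/DRX pair is
   modelled as a lumped force-independent pool). Metabolites enter as: Pi
   reverses the powerstroke, MgATP saturates detachment with MgADP product
   inhibition, H⁺ depresses force. Two couplings matter downstream:
   the **ATPase rate** (mM/s) — crossbridge detachment turnover plus a basal
   DRX turnover — feeds the oxygen balance, and **crossbridge load slows
   troponin Ca²⁺ release** (`ce_xbfb`), which is what lets a Ca²⁺
   sensitizer redirect Ca²⁺ flux toward the myofilament and away from SERCA.
4. **Oxygen** (1 state). Pericellular O₂ relaxes toward the source
   concentration at rate ε and is consumed by ATP turnover:
   $$\frac{d[\mathrm O_2]_e}{dt} = \varepsilon([\mathrm O_2]_s -
   [\mathrm O_2]_e) - \Omega\,(\beta\,\gamma\,(I_{NaK}+I_{pCa}) +
   \mathit{ATPase})$$
   with Ω = 1.6 mM O₂ per mM ATP, γ = C_m/(F·V_c) ≈ 0.1163 mM/s per A/F and
   β = 0.2658 weighting the pump (maintenance) share so a steady control
   beat splits ≈79% contraction / 21% maintenance. Source oxygen feeds back
   on the Na⁺/K⁺ and sarcolemmal Ca²⁺ pumps through the ouabain-like curve
   ρ (below). −d[O₂]_e/dt is reported as the oxygen consumption rate (OCR).

The ATP-sensitive K⁺ current uses the Ferrero-lineage nucleotide gate
$f_{KATP} = 1/(1+([\mathrm{ATP}]/K_m)^H)$ with $K_m$ and $H$ functions of
MgADP, and a maximal conductance scaling with $(K_o/5.4)^{0.24}$.

### The ρ coupling and its constants

ρ maps source oxygen to normalized pump activity. The raw curve is the
c = −1 Hill (Michaelis) form $\rho_{raw}(x) = (a x + b K)/(x + K)$ on
$x = [\mathrm O_2]_s / 0.133\,\mathrm{mM}$ with a = 1.215, b = 0.215 and
K = 0.15 (the half-effect sits at 15% of the maximum concentration, the
ouabain analogy); pump scalings use ρ normalized to 1 at baseline, so the
control condition is exactly the identity. The severity source-oxygen
levels are obtained by inverting ρ at 0.80 (20% pump inhibition, SEV1,
0.0375 mM) and 0.69 (31%, SEV2, 0.0228 mM).

### The ε discrepancy

With the packaged D = 2.5×10⁻¹⁰ m²/s and Δx = 10 µm the bare Fick ratio
D/Δx² is 2.5 s⁻¹, while the packaged exchange rate is ε = 5 s⁻¹.
`cdx_diffusion_rate()` exposes both: the default applies a two-sided planar
geometry factor of 2, reproducing the 5 s⁻¹ used by all protocols, and
`geometry = 1` returns the bare ratio. ε is an ordinary overridable
parameter (`o2_epsilon`).

## Protocols

* **control** — 800 s of spontaneous beating from the packaged steady state.
* **sev1 / sev2** — acute-ischemia severities: hyperkalemia (K_o 6.25 / 9
  mM), acidosis (pH 7.0 / 6.7; fast/late Na⁺ and L-type conductances −12.5%
  / −25%), metabolite depletion (MgATP 5.7 / 4.6 mM, MgADP 57 / 99 µM,
  Pi 6 / 11 mM) and hypoxia via ρ. Timeline: control 0–250 s, ouabain-like
  switch 250–350 s, full ischemia from 350 s.
* **ir** — the five-phase ischemia–reperfusion timeline (control 0–250,
  switch 250–350, SEV1 ischemia 350–850 with an additional 85% I_Kr/I_Ks
  block, reperfusion transition 850–950, physoxia 950–1100 s), with the
  EAD-predisposing SET conductance profile applied throughout.

Every scheduled quantity moves between phases along the normalized ρ shape
evaluated on a linear time ramp, `w(s) = s(1+K)/(s+K)` with K = 0.15 — a
continuous, monotone, fast-onset path; the environment never jumps.

All transitions, the nucleotide values and the conductance scalings are
configuration, exposed through `cdx_severity_config()`, `cdx_modifiers()`
and the protocol constructors.

### Ischemic SERCA recalibration

The baseline pump parameters, calibrated for control, do not produce the
ischemic Ca²⁺ phenotype; the packaged recalibration multiplies selected
constants within 0.1–5× of baseline (the documented search bounds),
found by informed manual tuning (10/20/50% steps) under the constraint that
the rate-versus-pCa curve keeps its rightward (acidic-zone) shift with
acidification. The recalibration is severity-resolved: mild multipliers for
SEV1 (1.3 / 0.85 / 1.25 / 1 / 0.8 on k₁⁺, k₂⁺, K_d,Hsr, K_d,Pi, K_d,Cai)
and stronger ones for SEV2 (5 / 0.45 / 3.2 / 1 / 0.18). A single shared set
either overloads the SR at SEV1 or under-drives SEV2 in this
implementation. Raising K_d,Hsr widens the gap between cytosol-facing and
luminal proton affinities, which elevates SR Ca²⁺ in ischemia — the
competitive-proton-binding mechanism the recalibration encodes. Because the
backward rate constant is Haldane-derived, multipliers on K_d,Pi or K_d,Hi
cancel identically (their kinetic and thermodynamic roles offset); the
effective levers are k₁⁺, k₂⁺, K_d,Hsr and K_d,Cai.

### Levosimendan

Three mechanisms, combined multiplicatively into one modifier bundle:

1. **Troponin-C Ca²⁺ sensitization** — K_on scales of 1.125 / 1.544 / 1.90
   at 0.3 / 2 / 10 µM (log-dose interpolation between points). The 0.3 µM
   scalar is calibrated so the SEV1 peak-tension increase is 25%.
2. **K_ATP opening** — f_KATP scales 1.08 / 1.36 / 1.84, anchored to an
   84% current increase at 10 µM (E_max = 46.8 A/F normalization).
3. **Channel block** — a Hill pore-block table (hERG-dominant IC₅₀ 60 µM,
   I_Ks 150 µM, I_CaL 300 µM, I_Na 1.5 mM, all h = 1); at the studied doses
   the blocks are a few percent, giving the marginal repolarization
   prolongation expected of the compound.

All three scalar sets are re-derived calibrations of this package (the
dose–response sources are external), shipped as configuration in
`cdx_levo_spec()`.

### SET (EAD-predisposing) profile

IR runs tune the maximal conductances globally with the packaged `set_ead`
profile (g_Na 0.85, g_CaL 1.25, g_Kr 0.8, g_Ks 0.8, g_NaL 1.3, g_K1 0.55)
— a re-derived calibration chosen so the ischemic phase with the 85%
I_Kr/I_Ks block develops early afterdepolarizations and diastolic
aftercontractions, both abolished by an enhanced slow delayed rectifier or
by 2 µM levosimendan. The EADs are calcium-driven: a spontaneous mid-plateau
SR release pushes the forward-mode NCX inward and reverses repolarization.

## Calibration of the control condition

The control model is calibrated once, not per run, toward the biomarker
anchors of the model family: spontaneous rate 0.61 Hz, maximum upstroke
velocity 34.9 V/s, maximum diastolic potential −78 mV, APD₉₀ ≈ 270 ms, CaT
decay (90→10%) 317 ms, ≈79/21 contraction/maintenance ATP split, pericellular
O₂ ≈ 0.117 mM. Levers and their frozen values: g_Na 2230 S/F (with a +6 mV
rightward shift of I_Na steady-state inactivation, needed for sustained
spontaneous beating under hyperkalemic depolarization), g_Kr 41.81, g_NaL 8,
k_NCX 2679.5, P_NaK 2.6, VmaxUp 0.90 mM/s, RyR gate thresholds re-derived in
µM units for the realized Ca²⁺ range. The upstroke-velocity anchor is met by
the plain control configuration; the IR-configured (SET) ischemic phase shows
the depressed ~5–10 V/s upstroke.

The packaged steady state (`cdx_steady_state("control")`) is the final phase
point of a >2000 s settle; the recipe is `scripts/calibrate_states.R`.

## Numerical choices

* Stiff variable-step integration: `deSolve::lsoda` (BDF/Adams switching,
  the accuracy contract of MATLAB's ode15s) on a compiled right-hand side;
  rtol 1e-6, atol 1e-8. A tolerance-tightening test bounds biomarker drift
  below 0.5%.
* Two independent transcriptions of the full right-hand side exist — the
  reference in R and the production version in C — held together by an
  equivalence test at random states (1e-12).
* Output is sampled at 1 ms in analysis windows (10 ms elsewhere for long
  protocols); threshold-crossing biomarkers are computed on a uniform 1 ms
  grid by linear interpolation, so they do not depend on internal solver
  steps. APD_x is measured from the upstroke to the final crossing of the
  peak-relative threshold; CaT decay from 90% to 10% of the
  baseline-referenced peak on the decay limb; double-peaked transients are
  measured from the global beat maximum and flagged.
* EAD detector: positive dV/dt above 0.05 V/s sustained ≥5 ms between the AP
  peak and 90% repolarization. Aftercontraction detector: diastolic tension
  peaks with prominence ≥5% of the twitch amplitude after decay below 30% of
  peak. Both thresholds are arguments.
* NCX sign convention: positive current = reverse mode (Ca²⁺ influx),
  matching the exchanger equation; the reverse-mode mask is `I_NCX > 0`.
* Degenerate inputs: all-zero SERCA rates return zero flux (flagged);
  a quiescent trace yields an empty beat table, not an error; non-finite
  states abort with the offending state named.
* Steady-state analysis windows: control biomarkers use 700–800 s of the
  800-s run; severity metrics use 950–1050 s of an extended ischemic
  plateau, because intracellular Na⁺ in this model needs ~600 s after the
  switch to settle. The protocol timeline itself is unchanged.

## What the packaged protocols do and do not show

The severity environments emulate acute ischemia as piecewise metabolite /
ion / oxygen clamps: real ischemia has continuously evolving metabolite
pools, pH buffering dynamics, osmotic and mechanical changes, and
mitochondrial responses — none of which are modelled (no mitochondrial ATP
production; the Na⁺/K⁺ pump is not ATP-gated, so its reflection in the OCR
is a simplification; crossbridge cycling is mean-field). Passing tests
therefore certify the model's internal consistency and its agreement with
the calibration anchors, not quantitative prediction for any particular cell
line.

Known limitations worth restating: the levosimendan response of SEV2 peak
tension saturates near +20–30% in this contractile element (the thin
filament is closer to full activation at SEV2 than the anchors assume), and
the reverse-mode NCX augmentation in severe ischemia runs above its anchor
because the depolarized diastole sustains a reverse-mode trickle between
beats. Both are properties of the re-derived contractile and exchanger
balance, documented rather than hidden.
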