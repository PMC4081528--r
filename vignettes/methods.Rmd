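---
title: "Models and numerics behind cochperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind cochperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochperm)
```

# The physiological problem

The cochlear duct epithelium (CDE) seals the endolymph in the scala media
(SM) off from the perilymph in the scala vestibuli (SV) and scala tympani
(ST). Two classical in vivo experiment types quantify how water crosses
this barrier:

1. **Diffusional exchange**: perfuse one or both perilymphatic scalae with
   tritiated water and record the endolymphatic tracer concentration. The
   rise is summarised by an exchange rate constant $P'$ (min$^{-1}$), and
   the diffusional water permeability is $P_D = P' V_e / A$, with $V_e$
   the endolymph volume and $A$ the wetted barrier area.
2. **Osmotic challenge**: perfuse the perilymph with a hypertonic solution
   (+94 mM sucrose) and track the rise of an impermeant volume marker
   (TMA$^+$) in endolymph. A relative solute increase SI over 20 min
   implies a transepithelial volume flow $J_v = V_e (\mathrm{SI}/100)/20$
   and an osmotic permeability $P_f = J_v / (\bar V_w A \Delta c)$.

A ratio $P_f/P_D > 1$ indicates water movement through aqueous pores
(aquaporins) rather than solubility–diffusion through the lipid bilayer.
`cochperm` implements the full computational chain — morphometry,
tracer-dispersal simulation, uptake-kinetics regression, and the
closed-form permeability arithmetic — plus a synthetic-data generator
that stands in for the in vivo records.

# Morphometry

Per-half-turn widths $w_i$ of the two barrier partitions (Reissner's
membrane and the organ of Corti) and longitudinal segment lengths $l_i$
enter the trapezoid rule $A_i = l_i (w_i + w_{i+1})/2$ over the 8.5
half-turns (hook + I…VIII). Two conventions close the two unbounded ends:

- the **hook** is a rectangle using the half-turn I width ($w_I\,l_h$),
  following the source convention;
- the **apical half-turn VIII** has no apical neighbour, so it is treated
  as a rectangle at its own width ($w_{VIII}\,l_{VIII}$), mirroring the
  hook rule. This is a declared design choice: the two ends of the spiral
  are handled symmetrically.

Replicate summaries use the sample standard deviation ($n-1$), which
reproduces the published per-specimen tables exactly. All areas are
carried internally in cm² for the permeability arithmetic; µm² and mm²
appear only at I/O boundaries, as exact decimal scale factors.

**The packaged table is a synthetic fixture.** The per-half-turn widths
and lengths were published only as a figure panel, not as numbers. The
packaged table (`cochperm_fixture_table()`, also under `inst/extdata/`)
is a smooth base-to-apex profile whose widths are rescaled by one factor
per partition — the totals are linear in the widths — so the trapezoid
totals equal the published 11.46 mm² (RM) and 9.78 mm² (OC) exactly. Any
green test built on it validates the area algebra and the downstream
chain, not the anatomical measurements themselves.

# Tracer-dispersal simulator

Each scala is a 1-D domain with a tabulated cross-section $A(x)$. Per
scala the solver integrates

$$A(x)\,\partial_t C = \partial_x\!\big(D\,A(x)\,\partial_x C\big)
  - Q\,\partial_x C
  + \textstyle\sum_j s_{ij}(x)(C_j - C_i) - k_{b,i}\,A(x)\,C_i$$

with perfusion flow $Q$ active between the entry (0.1 mm from base) and
exit (apical end) of a perfused scala, pairwise scala–scala exchange, and
uniform first-order clearance to blood.

**Half-time semantics.** The communication parameters are half-times
$t_{1/2}$ of first-order equilibration. We define them so that the
*local concentration difference* between the paired compartments decays
as $e^{-kt}$ with $k = \ln 2 / t_{1/2}$ — i.e. $t_{1/2}$ is the
observable half-time of the difference. The conservative flux achieving
this is volume-weighted with the harmonic combination
$J = k\,\frac{V_a V_b}{V_a + V_b}\,\Delta C$ per grid cell. (A flux rule
$J = k\,V_{\min}\Delta C$ would make the difference decay at up to $2k$
for equal volumes and would not match the closed-form two-compartment
oracle the tests assert.) The external program the reference workflow
used does not document its convention; ours is declared and tested.

**Numerics.** Operator splitting per time step (default $\Delta x$ =
0.1 mm, $\Delta t$ = 0.5 s):

1. diffusion by Crank–Nicolson in conservative flux form (unconditionally
   stable; conserves mass to machine precision with zero-flux ends);
2. advection by *implicit* first-order upwind in flux form — the
   perfusion velocity $Q/A(x)$ can exceed the explicit CFL limit at the
   tapered apex, and the implicit sweep is unconditionally stable and
   positivity-preserving. The inlet is a conservative advective inflow
   flux $Q\,C_{in}$ rather than a hard Dirichlet reset; at 8 µl/min the
   entry cell saturates to the inlet concentration within seconds, and
   flux-form bookkeeping keeps the mass ledger exact;
3. exchange and blood clearance by their exact exponential updates.

Because every operator is conservative or accounted, the mass-balance
report (`mass_balance()`) closes to ~1e-14 relative; the 0.1% acceptance
bound is therefore a genuine consistency check, not a tuned tolerance.

**Geometry fixture.** SV ends 15.5 mm and ST 16.2 mm from the base; the
SM profile is uniform with volume forced to $V_e$ = 1.2 µl; SV/ST taper
linearly with volumes of ~4.8 and ~6.2 µl. These profiles are synthetic.
Consequently simulated rate constants reproduce the reference values
*qualitatively* (our default SV+ST/SM fit gives $P' \approx 0.69$
min$^{-1}$ vs the reference 0.869): the quantitative acceptance targets
are the closed-form computations, and the simulator is held to property
tests (conservation, closed-form limits, calibration closure) instead.

**Calibration** (`calibrate_half_time()`) bisects on $\log t_{1/2}$ until
the simulated probe concentration at the observation time matches the
target to 0.1% relative, relying on the (tested) monotonicity of probe
concentration in every feeding half-time. Targets of zero return the
bracket's slow end with an `"unreachable"` flag; targets outside the
bracket's reachable range raise an error reporting both endpoints.

# Uptake kinetics

The endolymphatic uptake model is

$$C_e(t) = C_0\left[\frac{P'}{P''} +
  \frac{\alpha P' - 0.5 P' P''}{P''(P''-\alpha)} e^{-P' t} -
  \frac{0.5 P'}{P''-\alpha} e^{-\alpha t}\right].$$

Evaluation uses the algebraically identical re-grouping

$$C_e(t) = C_0\left[\frac{P'}{P''}\big(1 - e^{-P' t}\big) +
  \frac{0.5 P'\big(e^{-P' t} - e^{-\alpha t}\big)}{P'' - \alpha}\right],$$

which is exactly zero at $t = 0$ in floating point and exposes the
plateau $C_0 P'/P''$ directly.

**The $P'' = \alpha$ locus is a pole, not a removable singularity.** We
verified symbolically that for $P' \ne P''$ the model diverges as
$\alpha \to P''$ (the $1/(P''-\alpha)$ term multiplies
$e^{-P't}-e^{-\alpha t}$, which does not vanish there). A series-limit
evaluation "at the singularity" therefore cannot exist. The
implementation rejects parameter sets with $|P''-\alpha| < 10^{-6}$
min$^{-1}$ with a structured error, and the fitter's objective penalises
that band. The continuity property retained in the tests is that the
re-grouped and the literally-printed forms agree to $10^{-8}$ relative
just outside the guard band. The fitted triples of interest sit far from
the pole ($P'' \approx 0.9$, $\alpha \approx 0.5$).

**Fitting.** $C_0$ is fixed at 100% (perfusate-normalised) unless freed.
The fit is bounded least squares over $\log(P', P'', \alpha)$ — bounds
$[10^{-4}, 10^3]$, positivity by construction — via L-BFGS-B from three
feature-based starts (the tail mean fixes the $P'/P''$ ratio; a coarse
grid covers the rate scales), followed by a derivative-free Nelder–Mead
polish, which matters on noiseless round-trip data where gradient steps
stall near machine-zero residuals. Ties break on lowest RSS, then lowest
$P'$. Standard errors come from the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$.

**Identifiability under noise.** With 1% multiplicative noise on 120
one-minute samples, $P'$ and $P''$ trade off along the plateau ratio and
$P'$ becomes weakly identified: the seeded Monte-Carlo oracle (100
replicates) gives a *median* relative error of ~5% but a 90th percentile
of ~27%, with the best-fit RSS below the truth's RSS in the worst cases
(so this is a property of the likelihood surface, not the optimiser).
The test suite asserts the Monte-Carlo-calibrated bounds (median < 5%,
q90 < 30%) rather than a blanket per-replicate 5%, which the model does
not support at these parameter values.

# Permeability arithmetic and units

All coefficients are computed in CGS internally: $P'$/60 → s$^{-1}$,
µl → cm³ (×10⁻³), mm² → cm² (×10⁻²), mol l$^{-1}$ → mol cm$^{-3}$
(×10⁻³). $\bar V_w$ = 18 cm³ mol$^{-1}$ is a named, overridable constant.
$\Delta c$ defaults to 0.094 mol l$^{-1}$ — the 94 mM sucrose added to
the perfusate, equating osmolar and molar concentration for sucrose.

**Reproduction convention.** Golden tests and the acceptance report feed
the *printed, rounded* intermediates (e.g. $J_v$ = 7.37 × 10⁻³ µl/min,
$A_{OSC}$ = 0.04627 mm²) because the published results were themselves
computed from those rounded values: 7.37e-3 yields $P_f$ = 156.89e-3
≈ the printed 156.90e-3, whereas the unrounded chain yields 156.98e-3.
The pipeline keeps full precision end to end and its own chained values
are asserted within 0.1% of the printed ones.

**Channel density.** $n = P_f / p_f$ with $p_f$(AQP5) = 5 × 10⁻¹⁴
cm³ s$^{-1}$ gives 3.138 × 10⁴ µm$^{-2}$ for the shunt, not the published
3.45 × 10⁴; the source of that discrepancy is undocumented. The function
returns the computed quotient and attaches the note; the value is
excluded from acceptance targets.

# Synthetic data: what the generator states, and what a green test means

- **Noise model**: multiplicative log-normal truncated at ±3σ for lengths
  (cannot go negative); additive normal clipped to [0, 100] for
  concentrations. Default replicate CV 3%, inside the 2.02–9.10%
  between-subject variation reported for the immunolabelling lengths.
  The measurement noise of the tracer probe readings is not reported
  anywhere; the default observation CV of 3% is a declared assumption.
- **Ground truth is always serialised next to the noisy record**, so
  recovery tests compare against stored truth, never against a
  re-derivation from noise.
- Generators are bit-reproducible given (seed, config) and leave the
  caller's RNG stream untouched.

A green end-to-end closure test (synthetic observation → calibration →
simulation → fit → $P_D$ within 2% of the forward truth at zero noise)
establishes the internal consistency of the chain on the stated synthetic
world. It does not establish anatomical fidelity of the fixture geometry,
nor the in vivo values of the half-times.

# Design choices on genuinely open points

- **Widths at segment boundaries vs midpoints**: the trapezoid formula
  implies boundary values while the source figure labels one width per
  half-turn. We treat $w_i$ as the basal-boundary width of half-turn $i$;
  under the calibration step this choice only redistributes area among
  segments, leaving totals fixed.
- **Perfusion in the dual-perfusion model**: 8 µl/min is applied per
  perfused scala (the reference states a single rate without
  disambiguation); the alternative — one total split evenly — can be
  expressed by passing half the rate.
- **Blood clearance** is applied uniformly per position (the external
  program's behaviour is undocumented); with first-order kinetics a
  lumped variant would give identical well-mixed totals.
- **Calibration scope**: the SV/SM scenario calibrates the SV–SM
  half-time, ST/SM the ST–SM one; the dual-perfusion scenario calibrates
  SV–SM while holding ST–SM, matching the reference order in which the
  single-scala experiments pin the individual pathways.
- The in vivo 7-min concentrations used by the reference workflow were
  published only as diagrams, so calibration demonstrations use
  synthetic or user-supplied targets throughout.

# Known limitations

- The fixture geometry is synthetic; simulated rate constants are
  qualitative (see above). Anyone with real per-half-turn measurements or
  area profiles can substitute them through the documented CSV/config
  interfaces and the whole chain applies unchanged.
- The osmotic experiment is handled analytically (fixed geometry); the
  simulator does not move boundaries or model endolymph volume change.
- No unstirred-layer or temperature corrections (assumed negligible under
  continuous perfusion, following the reference assumptions).
- The uptake model is used as printed, including its inherited 0.5
  factors and its pole at $P'' = \alpha$; it is a regression summary, not
  a mechanistic derivation.
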