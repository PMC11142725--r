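---
title: "A reaction-diffusion model of apical-basal polarity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reaction-diffusion model of apical-basal polarity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polarsim)
```

## The model

`polarsim` simulates the establishment of apical-basal polarity in a renal
epithelial cell as a system of twelve coupled reaction-diffusion equations
on the 1D axis from the basal membrane (x = 0, in contact with the
extracellular matrix) to the apical membrane (x = L). Each of six protein
families — integrins, the Rho-GTPases Cdc42, Rac and Rho, and the Par and
Scribble polarity complexes — is split into two interconverting fractions
(active/inactive, or complex-bound/unbound) whose sum is conserved.

The signaling structure is:

* **Integrins** activate only where the cell touches the matrix (the basal
  sixth of the domain); active integrin is immobilized by its ECM
  attachment, inactive integrin diffuses (vesicular transport).
* **Rac** is activated by active integrin (gain `alpha_I`) plus a baseline
  input `I_R`, and is jointly inhibited by active Rho and the Par complex
  through a single shared Hill denominator
  `1 + (rho_a/beta_rho)^n + (P_C/beta_PR)^n`.
* **Rho** is activated at rate `I_rho` under Hill inhibition by Rac
  (`beta_R`) — the mutual Rac/Rho antagonism at the heart of the pattern.
* **Cdc42** is activated by Rho (`alpha_rho`) plus a baseline `I_C`.
* **Par** assembly is boosted by active Cdc42 (`alpha_C`) and inhibited by
  Scribble (`beta_SP`); **Scribble** assembly is inhibited by Par
  (`beta_PS`) — a mutually inhibitory bistable pair.

Every activation term is proportional to the inactive (or unbound)
fraction divided by the family total, every inhibition is a Hill factor
`1/(1 + (c/beta)^n)` with a common coefficient n = 4, and every active
form decays (or dissociates) at a first-order rate. Active, membrane-bound
forms diffuse at 0.1-0.2 um^2/s; inactive cytosolic forms at 2-10 um^2/s.
Together with no-flux boundaries this gives the wave-pinning mechanism:
bistable local kinetics support a traveling activation front, and mass
conservation of each family stalls it into a stationary polarized pattern.

All parameter defaults (see `?polar_params`) are the published values for
MDCK-type cells; the total GTPase concentrations (4.4, 2.4, 4.0 uM for
Cdc42, Rac, Rho) derive from quantitative immunoblotting, a calculation
reproduced by `blot_to_concentration()`: band intensity relative to a
control band of known mass, scaled to mass per cell, converted through the
molecular weight (21 kDa) and the Avogadro constant to molecules per cell,
and divided by the volume of a 10-um sphere.

## Numerics

The solver (`simulate_polarity()`, compiled core) uses explicit Euler
steps with second-order central differences for diffusion. The boundary
closure writes the end-node Laplacian in flux form (`(f[2]-f[1])/dx^2`),
which makes the discrete diffusion operator exactly conservative; an
unperturbed run conserves each family's node sum to ~1e-15 relative.
Defaults: L = 10 um (a typical cell diameter; the domain length is implied
by the cue region spanning one-sixth of the domain ~ 1.67 um), 30
subdomains (31 nodes), dt = 0.005 s — satisfying the stability bound
dt <= dx^2/(2 D_max) = 0.00556 s, which the constructor enforces. Negative
round-off is clipped at zero (the largest clipped magnitude is recorded in
the trajectory; it is 0 for the baseline run).

**Initial conditions.** Active GTPases and bound complexes start uniform
(C_a 0.8, rho_a 1.0, R_a 1.75, P_C = S_C 0.6 uM); inactive/unbound fields
are the complements to the totals. Note that R_a(0) = 1.75 uM is ~73% of
the total Rac — we use these printed values verbatim even though the
accompanying narrative suggests ~30% GTP-bound fractions were intended;
the steady state does not depend on this choice, but transient race
outcomes (below) can. Active integrin starts as a steep decay over the
basal cue region, `I_a = (1/x^2) exp(1/x^2 - 1) I_tot` with x = 1..5 on
the default grid.

**Cue region at other resolutions.** The activation mask and the initial
integrin profile are defined on the physical region x < L/6, with the
decay profile parameterized by distance in units of L/30. On the default
grid this reduces exactly to "the first five nodes" with integer profile
arguments; on finer grids it samples the same physical shape. Defining the
region by node count instead would change the physics with the mesh and
make any convergence statement meaningless.

**Convergence.** Final states at dt = 0.005 and 0.001 s agree to ~2e-5
relative. Apical-basal differences agree within a few percent across
30-60 subdomains. At 100 subdomains, however, the GTPase pattern of the
default run collapses to the homogeneous (Rho-dominant) state: the active
forms' reaction-diffusion boundary layer, sqrt(D_act/delta) ~ 0.32 um, is
under-resolved at the default dx = 1/3 um, and the coarse mesh
systematically strengthens the basal Rac peak that wins the
pattern-forming race. The package therefore treats the 31-node grid as
*the model as published* — its results are mesh-converged only in the
30-60 subdomain range, and the corresponding 30-vs-100 property test is
expected to fail for the GTPase outputs. (Halving dt at 100 subdomains
does not change this, ruling out a time-stepping artifact.)

## Polarization metrics

An output's polarization is the absolute concentration difference between
the two boundary nodes (the 1D stand-ins for the apical and basal
membranes; interior averaging was rejected for determinism and
simplicity). The delta-P statistic expresses this difference as a
percentage of the same difference in the default-parameter reference run;
a run is *polarized* for an output iff delta-P > 20% (strict — exactly 20%
is unpolarized).

`steady_state_time()` reports the earliest snapshot time after which the
max-norm relative change per second of the bound Par and Scribble profiles
stays below a tolerance through the end of the run. The default tolerance
is 1e-3 per second — "steady" means the profiles change by less than 0.1%
per second — which detects the baseline steady state at 77 s. The final
approach is a slow exponential mode (time constant ~13 s), so the detected
time shifts logarithmically with the tolerance: a 10x stricter 1e-4/s
fires only at ~107 s, although the profiles are visually indistinguishable
well before either time. We chose 0.1%/s as the level at which no further
change is meaningful relative to the ~1.4 uM apical-basal signal.

## Sensitivity analysis

`run_mpsa()` varies the 21 interaction parameters (activation inputs,
decay rates, Hill half-points, association/dissociation rates, and the
integrin constants — not the measured totals, the Hill coefficient, or the
diffusion coefficients) simultaneously over 20-500% of their baseline
values using Latin hypercube sampling (uniform per-parameter stratification
on the linear interval, one draw per stratum; the `lhs` package). Each
sampled run is labeled accepted (delta-P > 20%) or unaccepted per output,
and each parameter is scored by the Kolmogorov-Smirnov distance between
the empirical CDFs of its values in the two classes — large distances mean
the parameter's value separates polarizing from non-polarizing runs.

Significance is calibrated with 21 *dummy* variables: inert quantities
with baseline 1, sampled over the same 20-500% range, that never enter the
simulator. Per output, the maximum dummy K-S distance is the significance
threshold; a parameter is influential iff it exceeds it. Degenerate cases
(an output with all runs in one class) return distance 0 with a warning
rather than aborting the ensemble, and runs that fail to integrate at
extreme parameter combinations are labeled unaccepted and flagged (at the
full design, a handful out of 3000). The ensemble is a sequential map over
samples, so results are identical regardless of execution environment
given the seed.

Because the threshold is a maximum over 21 null draws and the irrelevant
parameters are nulls too, occasional chance exceedances are expected at
small sample counts; the analyses and tests therefore use the full
3000-sample design (about two minutes with the compiled core).

## Perturbation experiments

The degradation/upregulation protocol (`run_perturbation()`) has three
100-s phases. Phase 1 runs the unperturbed model into its polarized steady
state. In phase 2, after every Euler step the targeted GTPase's active
field is rescaled so that its node-summed amount follows
`100 + a (1 - exp(-0.043 (t - 100)))` percent of its amount at t = 100 s
(a < 0 degrades, a > 0 upregulates): the spatial shape is free to evolve
but the total active amount is pinned to the prescribed exponential, which
realizes the protocol deterministically (pure per-step ratio
multiplication would let the reactions replenish the active pool and drift
far off the curve). Degraded protein leaves the system — the inactive pool
is untouched — and the targeted species' rate law uses its current
spatial-mean total instead of the fixed parameter, so that an a = 0
protocol reproduces the unperturbed run to ~1e-9 (a per-node total would
not, since differential diffusion makes per-node totals non-uniform even
without perturbation). In phase 3 both fields of the targeted species are
frozen — they still appear in the other species' rate laws — because
holding only the active field would leave the inactive one evolving
against a clamped partner with no defensible rule.

The integrin dose sweep replaces the integrin total (which jointly scales
the initial active profile and the conserved pool — scaling only the
initial profile would be transient, as the integrin subsystem relaxes to a
steady state set by the total) and classifies each 100-s run against the
default reference. The directional-cue experiment mirrors the cue to the
apical side and checks that the final states are node-wise mirror images.

## Known limitations and deviations

Three quantitative outcomes of this implementation differ from the
original study's printed results; all three sit on bistable boundaries
where small discretization details (e.g. the intra-step update order of a
different code base) can tip the outcome, and none was tuned toward or
away from the printed values:

1. **Integrin threshold.** The GTPase pattern shows the reported
   switch-like dose threshold, but one 1-uM step above the printed value:
   at 18 uM the default run still falls into the homogeneous Rho-dominant
   state, at 19 uM it polarizes. Moreover, in this implementation the
   Par/Scribble pair pins a stable front (stationary from ~150 s onward)
   even when the GTPases are homogeneous — seeded by the early Rac
   transient — so the sweep's Par/Scribble-based classification reports
   every tested amplitude down to 10 uM as polarized, whereas the original
   study shows homogeneous complexes below threshold.
2. **Partial Cdc42 degradation.** At a = -80 (21% of active Cdc42
   remaining) the Scribble front invades the apical domain between
   t ~ 180-220 s and the Par complex collapses, while the original study
   reports polarity preserved up to 80% degradation for all three
   GTPases. All other degradation/upregulation outcomes (full Rho/Cdc42
   loss breaking polarity, Rac loss sparing the complexes, partial
   degradation at -20..-60, all upregulations) match. Four alternative
   enforcement readings of the ramp were tested; all collapse at -80.
3. **Mesh convergence at 100 subdomains** (discussed above).

Beyond these, the model's scope limits what conclusions transfer to real
cells: it is 1D (no integrin clustering, no cell-cell junctions), it
reaches steady state in ~80 s whereas cells polarize over hours (only
protein sorting is modeled, not adhesion, trafficking or cytoskeletal
remodeling), mechanotransduction is absent (so stiffness-dependent loss of
polarity cannot appear), and the Par/Scribble complexes are single
effective species. The simulator is deterministic; molecular noise, which
matters at the copy numbers implied by the measured concentrations, is not
represented.
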