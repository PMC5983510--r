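---
title: "A deterministic model of the reversible quiescence-proliferation transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic model of the reversible quiescence-proliferation transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g0switch)
```

## The biological problem

Mammalian cells move reversibly between quiescence (G0) and proliferation.
Two commitment points order this decision in G1. At the restriction point
(R-point), hyper-phosphorylation of the retinoblastoma protein (Rb) releases
the transcription factor E2F and the cell no longer needs mitogen to keep
going. Later, at the G1/S boundary, inactivation of the ubiquitin ligase
APC/C-Cdh1 makes the transition irreversible even against stress: stress
signals (which raise Cdk-inhibitor levels) can push a cell back to
quiescence after Rb hyper-phosphorylation, but only until APC/C-Cdh1 has
been switched off.

`g0switch` implements a deterministic ODE model of this machinery: two
bistable switches — Rb-E2F (mitogen-controlled) and APC/C-Cdh1-Emi1
(stress-controlled) — coupled by Cyclin E:Cdk2, which both
hyper-phosphorylates Rb (low activity threshold) and phosphorylates Cdh1
(high activity threshold). The distinct thresholds temporally separate the
R-point from the G1/S transition and create the window in which stress can
still revert the cell.

## The reaction network

State variables (19 species, concentrations in arbitrary units, time in
hours) are listed by `species_names()`. The interactions:

* **Mitogen and Myc.** Mitogen level `S` is a dimensionless input. Myc
  follows `S` with a ~2 h relaxation time and stands for the late phase of
  mitogen signalling; only Myc-dependent synthesis responds to it. We chose
  a single Myc ODE rather than separate early/late signalling variables:
  the relaxation delay is the only aspect of the two-phase structure that
  the downstream network can sense.
* **Cyclin D:Cdk4/6** is synthesised mitogen- and Myc-dependently
  (`k_scycds`, `k_scycdm`), mono-phosphorylates Rb, and sequesters the Cdk
  inhibitor (CKI, a p21/p27 lump) — its main route to activating Cyclin
  E:Cdk2 — without itself activating E2F (mono-phosphorylated Rb still
  inhibits E2F).
* **Rb and E2F.** Rb has un-, mono- and hyper-phosphorylated forms; the
  first two bind E2F in stoichiometric inhibitory complexes. Cyclin E:Cdk2
  (and Cyclin A:Cdk2) convert mono- to hyper-phosphorylated Rb and can also
  hyper-phosphorylate un-phosphorylated Rb directly at a lower rate
  (`k_pprbue`); only hyper-phosphorylation releases E2F. (De)phosphorylation
  follows Michaelis-Menten kinetics; a single constant `k_dprbp` governs
  both dephosphorylation steps. Free E2F drives synthesis of Cyclin E,
  Cyclin A, Emi1 and itself through a Hill function with n = 1.
* **CKI** binds all three cyclin:Cdk complexes stoichiometrically. It is
  synthesised at `k_scki` (raised to 0.6 by stress) and degraded basally
  and — after the G1/S transition — by the lumped SCF-Skp2/CRL4-Cdt2
  ubiquitin-ligase activity `Ubl` in a Cdk2-dependent manner. `Ubl` itself
  is an APC/C-Cdh1 substrate, so CKI destruction only arms once Cdh1 is off.
* **APC/C-Cdh1 and Emi1.** Cdh1 is inactivated by Cyclin E:Cdk2
  phosphorylation (Michaelis-Menten) and by stoichiometric Emi1 binding;
  Emi1 is itself an APC/C-Cdh1 substrate. Free active Cdh1 degrades both
  free and Cdh1-bound Emi1 by mass action (`k_demi1c`). This form gives the
  Emi1 removal flux an N-shape in total Emi1 — proportional to
  `Cdh1_free x Emi1_total` while Cdh1 is in excess, collapsing once Emi1
  sequesters the activity that would destroy it — which is what makes the
  double-negative loop genuinely bistable. Saturating (Michaelis-Menten)
  variants we explored either destroy the Cdh1-active state (the complex
  shields Emi1 from a capacity shared across pools) or remove the
  Emi1-high state (complex-only cis degradation recycles Emi1 too fast).
* **Cyclin A:Cdk2** accumulates E2F-dependently once Cdh1 (which degrades
  it) is off, and then promotes degradation of Cyclin E and E2F — the
  S-phase decline of both. Its weight on Cdh1 phosphorylation (`k_icdh1a`)
  is kept small so that Cyclin E carries Cdh1 inactivation, consistent with
  the observation that Cyclin A knockdown leaves inactivation kinetics
  unchanged.

All complexes are tracked explicitly (no rapid-equilibrium reduction), so
the Rb moiety (5 pools) and Cdh1 moiety (3 pools) are conserved exactly by
the equations; conservation along numerical trajectories is an accuracy
check, asserted to 1e-6 relative. The CKI moiety is conserved only when its
turnover is frozen (see the Rb-E2F subsystem below).

## Parameters

`default_parameters()` documents every constant; the same table ships as
`inst/extdata/parameters_default.cfg`. Perturbation values that define the
model's canonical experiments are fixed:
stress `k_scki = 0.6`; Cyclin D removal `k_dcycd = 0.1` with synthesis
stopped; Cyclin D knockout `k_scycdm = k_scycds = 0`; the Myc-dependent
synthesis rates `k_se2fm = 0.0015` and `k_scycem = 0.0005` (with Myc ~50
a.u. at S = 1, these correspond to E2F/Cyclin E influxes of 0.075 and
0.025 a.u./h). The remaining constants were calibrated, once, so that the
default model reproduces the full set of qualitative behaviours: a stable
quiescent state at S = 0; at S = 1 the event order Cyclin D rise, Rb
mono-phosphorylation peak, Rb hyper-phosphorylation/E2F activation, Emi1
accumulation, Cdh1 half-inactivation, CKI collapse; commitment located at
Cdh1 inactivation; the hysteresis structure of both switches; and the
threshold-sensitivity pattern. The calibrated quiescent CKI pool
(`k_scki / k_dcki` = 0.5 a.u.) matches the `CKI_total` default used as the
conserved total in subsystem analysis.

### The Cdk2-inhibition preset

Cdk2 inhibition (the dashed condition of the Emi1-null experiment) is
modelled as an activity knockout with concomitant cyclin stabilisation:
`e_cdk2 = 0` (a multiplier on every Cyclin E/A:Cdk2 kinase term) together
with `k_dcyce = 0.01`, `k_dcyca = 0.01` — drug-inhibited cyclin:Cdk2
complexes are poor substrates of the activity-dependent (Fbw7-type)
degradation route, so their turnover drops to near-basal values. A pure
enhanced-degradation reading of those rate values cannot act on the
experiment's timescale (0.01/h is a ~70 h half-life), which is why the
activity multiplier exists.

### The Cyclin-D-inhibition preset

Anti-Cyclin D treatment neutralises existing *and* newly made protein; it
is encoded as `{k_scycdm = 0, k_scycds = 0, k_dcycd = 0.1}` (synthesis
stopped, existing pool cleared at 0.1/h). With synthesis left on, a pure
degradation increase merely lowers the steady state and can never revert an
early cell.

## Simulation

`find_quiescent_state()` settles the system at S = 0 and polishes the
steady state with Newton iterations (residual below 1e-10; stability
verified through the conservation-reduced Jacobian).
`run_timecourse()` integrates with `deSolve::lsoda` (atol 1e-9, rtol 1e-6)
and restarts the integrator hard at every timed perturbation, so no
interpolation crosses a parameter discontinuity. `event_times()` extracts
first crossings: total Cyclin E over total CKI; Rb hyper-phosphorylated
fraction up through 0.5; Cdh1 active fraction down through 0.5; total Emi1
up through 10% of its trajectory maximum. The 0.5 and 10% thresholds are
reporting conventions (the events themselves are defined by the
transitions); both are arguments.

`commitment_probe()` applies a perturbation template over a grid of times
and classifies the state at t = 100 h by free E2F against the midpoint of
the quiescent and proliferative reference levels — a separatrix proxy that
needs no extra parameters; outcomes within 10% of the midpoint are flagged
unsettled. The switching time is the latest application time that still
reverts the cell.

## Equilibria and continuation

Steady-state analysis runs on a reduced system (`make_system()`): any
species can be clamped to a constant, and one member of each conserved
family (`RbPP`, `Cdh1P`, and `CKI` when CKI turnover is frozen) is
eliminated through its conservation law, removing the structural zero
eigenvalues so stability is readable from the reduced Jacobian. Jacobians
are central finite differences (relative step 1e-6; the model is smooth and
small, so analytic Jacobians would buy little).

`continue_branch()` is a pseudo-arclength predictor-corrector: tangents
from the bordered Jacobian, Newton correction orthogonal to the tangent
(tolerance 1e-10), step halving on corrector failure between bounds 1e-4
and 0.1, and per-coordinate scaling of the arclength metric so that large
species (Myc) do not starve the step. Folds are detected where the
parameter component of the tangent changes sign and refined by bisection to
1e-6 in the parameter. Hopf points are not tracked (the model has no
reported oscillations); complex eigenvalue crossings would surface in the
recorded spectra. `find_equilibria_bruteforce()` — damped Newton from Latin
hypercube starts, deduplicated at 1e-6 — is the independent oracle the
continuation is tested against.

`track_fold_2par()` continues the extended system {f = 0, J v = 0,
|v| = 1} in a second parameter, with adaptive sub-stepping; it powers the
two-parameter mitogen/CKI diagram and the threshold-sensitivity scans.

### Subsystems

* **Rb-E2F subsystem** (mitogen response): the Cdh1 block (`Cdh1`,
  `Cdh1P`, `Emi1`, `Emi1Cdh1`, `Ubl`) is clamped at its G1 configuration
  (Cdh1 fully active, Emi1 absent, Ubl at its Cdh1-suppressed level) and
  CKI turnover is frozen so total CKI is the conserved quantity
  `CKI_total` — which is precisely the second axis of the two-parameter
  analysis. The clamp set is an argument of `make_system()` for users who
  want a different reduction.
* **Cdh1-Emi1 subsystem** (G1/S): only `Cdh1`, `Emi1`, `Emi1Cdh1` remain
  dynamic; free Cyclin E:Cdk2 is clamped as the bifurcation parameter; E2F
  is clamped at a late-G1 level of 0.5 a.u. — roughly its value as the
  G1/S window opens, and low enough that Emi1 synthesis does not by itself
  overwhelm the Cdh1-active state (at the full proliferative E2F level the
  active state has already yielded, which is the point of the switch).
  Cyclin A and the CKI pools are clamped to zero.

`threshold_sensitivity()` re-tracks a fold across multiplicative factors of
each parameter on a 13-point log grid spanning 1/5 to 5, reporting
thresholds normalised by the base threshold. The steepness summary is the
maximum |d log threshold / d log factor|; a parameter whose fold
annihilates (or whose threshold reaches zero) inside the window has
extinguished or un-gated the switch within a five-fold change and is
reported as infinitely steep.

## Scenario presets

`run_scenario()` packages each canonical computational experiment with its
qualitative checks (orderings, persistence, reversibility — the model's
results are trajectories and diagrams, not single numbers). Timed
perturbations are self-calibrating: stress is applied 1 h after Rb
hyper-phosphorylation (pre-G1/S variant) or 1 h after Cdh1 inactivation
(post-G1/S variant); Cyclin D inhibition 1 h after total Cyclin E first
exceeds total CKI; Cdk2 inhibition in the Emi1-null scenario at 1.5x the
wild-type Cdh1-inactivation time.

The mitotic-exit preset re-interprets the stimulation protocol for cycling
cells: Rb hyper-phosphorylated, Cdh1 fully active, Emi1 low, no CKI, and an
intermediate Cyclin E:Cdk2 activity (`cdk2_init`, default 0.15 a.u. —
between the activity that maintains Rb hyper-phosphorylation under
re-accumulation and the Cdh1-inactivation threshold; the exact value is
deliberately exposed as a free initial condition). It carries the
Myc-dependent synthesis rates, representing the mitogen-induced
transcriptional program that cycling cells shift into G2: with mitogen,
E2F/Cyclin E re-accumulate and APC/C-Cdh1 is inactivated within ~4 h;
without mitogen the re-accumulation fails and the cell enters quiescence
even with no CKI at all. No new mechanism is introduced — only initial
conditions and those two rates.

## What the defaults do and do not show

The default parameter set is one calibration that exhibits the network's
qualitative repertoire; rate constants are not fitted to any measured
kinetics, concentrations are in arbitrary units, and absolute times (e.g.
the ~18 h from stimulation to Rb hyper-phosphorylation) should be read as
ordinal, not quantitative. The model is deterministic: cell-to-cell
variability, stochastic commitment, population structure and the rest of
the cell cycle (S/G2/M progression, mitosis itself) are out of scope.

## Numerical choices

* lsoda with atol 1e-9 / rtol 1e-6; halving tolerances moves event times
  by < 1% (asserted in the tests).
* Newton tolerance 1e-12 for steady states (residual check 1e-10), 1e-10
  for continuation correctors; fold bisection 1e-6.
* Brute-force deduplication at 1e-6 in the max norm; stability threshold
  at max Re(eigenvalue) < -1e-8.
* Continuation may traverse (unphysical) negative parameter values — that
  is how "no deactivation fold at any S > 0" is demonstrated: the fold is
  located at S < 0.
* States are validated non-negative to 1e-6; integration keeps
  conservation errors near 1e-10.

## A worked run

```{r example, eval = FALSE}
p <- default_parameters()
q <- find_quiescent_state(p, S = 0)
tr <- run_timecourse(p, q, t_end = 100, dt_out = 0.25)
event_times(tr)
# stress just before vs just after Cdh1 inactivation
commitment_probe(p, "stress", t_grid = 18:28, init = q)$switching_time
```
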