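# g0switch

Deterministic ODE model of the reversible transition between quiescence
(G0) and proliferation in mammalian cells, for systems biologists studying
cell-cycle commitment.

Two coupled bistable switches order the G1 decisions. The Rb–E2F switch:
mitogen → Myc → Cyclin D:Cdk4/6, which sequesters the Cdk inhibitor (CKI,
p21/p27 lumped) and mono-phosphorylates Rb; Cyclin E:Cdk2 then
hyper-phosphorylates Rb, releasing E2F, which drives synthesis of Cyclin E,
Cyclin A, Emi1 and itself (Hill, n = 1) — passage of the restriction point
(R-point), after which mitogen is dispensable. The APC/C^Cdh1–Emi1 switch:
Cyclin E:Cdk2 initiates Cdh1 phosphorylation; Emi1 — an APC/C^Cdh1
substrate *and* stoichiometric inhibitor — then runs away and buries the
remaining activity, making G1/S inactivation switch-like and irreversible.
Between the two commitments lies a window where stress (CKI synthesis
`k_scki = 0.6`) still reverts the cell to quiescence; after Cdh1
inactivation, Cdh1-repressed ubiquitin ligases (SCF^Skp2/CRL4^Cdt2,
lumped as `Ubl`) destroy CKI and the window closes.

Multi-site (de)phosphorylation of Rb and Cdh1 uses Michaelis–Menten
kinetics; E2F-dependent synthesis uses a Hill function with n = 1; all
other reactions are mass action, with every stoichiometric complex (Rb:E2F,
CKI:cyclin–Cdk, Emi1:Cdh1) tracked explicitly. Units: a.u. for
concentrations, hours for time.

The package provides:

* `default_parameters()`, `load_parameters()` — the calibrated rate table,
  shipped as a plain-text config (`inst/extdata/parameters_default.cfg`);
* `find_quiescent_state()`, `run_timecourse()`, `event_times()`,
  `commitment_probe()` — stiff simulation (deSolve) with timed parameter
  perturbations, event extraction and commitment probing;
* `make_system()`, `rb_e2f_subsystem()`, `cdh1_emi1_subsystem()`,
  `find_equilibria_bruteforce()`, `continue_branch()`,
  `track_fold_2par()`, `threshold_sensitivity()` — equilibrium analysis:
  multistart root finding, pseudo-arclength continuation with saddle-node
  detection, two-parameter fold tracking, 5-fold sensitivity scans;
* `run_scenario()` — 13 named presets reproducing the model's canonical
  computational experiments, each with machine-checked qualitative
  assertions;
* `import_xpp_trajectory()`, `write_trajectory()` — XPPAUT `.dat` import
  and CSV output;
* a command-line tool, `exec/g0switch`.

## A worked example

```r
library(g0switch)

p  <- default_parameters()          # S = 1 (mitogen present)
q  <- find_quiescent_state(p, S = 0)
tr <- run_timecourse(p, q, t_end = 100, dt_out = 0.25)
round(event_times(tr), 2)
#> CycE_exceeds_CKI    Rb_hyper_half Cdh1_inactivation        Emi1_rise
#>            21.98            18.38             21.04            19.91
```

Read: after mitogen exposure at t = 0, Rb is half hyper-phosphorylated
(R-point proxy) at ~18.4 h, Emi1 accumulation follows at ~19.9 h, and
APC/C^Cdh1 crosses half-inactivation (G1/S commitment) at ~21.0 h — a
~2.7 h window in which stress can still force the cell back to quiescence:

```r
pr <- commitment_probe(p, "stress", t_grid = 17:25, init = q)
pr$switching_time
#> [1] 22
```

Stress applied at or before ~22 h reverts the cell (Cdh1 reactivates, Rb is
dephosphorylated, E2F re-bound); applied later, CKI is degraded faster than
it is made and proliferation continues.

Bifurcation of the Rb–E2F subsystem in mitogen:

```r
sys <- rb_e2f_subsystem(p)
br  <- continue_model_branch(sys, "S", p_range = c(-0.8, 3),
                             start = unname(q[sys$free]), p0 = 0,
                             direction = 1)
br$folds$p
#> [1]  0.2077441312 -0.0063171663
```

The low-E2F (quiescent) branch is annihilated at S ≈ 0.21 — the activation
threshold — while the deactivation fold sits at S < 0: once on, the high-E2F
state survives complete mitogen withdrawal (irreversibility of R-point
passage with respect to mitogen).

## Command line

```sh
g0switch simulate --t-end 100 --out traj.csv
g0switch continuation --free S --out branch.csv
g0switch scenario --name fig2b_no_cyclinD --out results/
g0switch scenario --list
```

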