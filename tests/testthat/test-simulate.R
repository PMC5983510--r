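test_that("the quiescent state is a stable, low-E2F, active-Cdh1 state", {
  q <- quiescent0()
  obs <- attr(q, "observables")
  expect_lt(attr(q, "resid"), 1e-10)
  expect_gt(obs[["Cdh1_active_fraction"]], 0.9)
  expect_lt(obs[["E2F_free"]], 0.05)
  expect_true(all(Re(attr(q, "eigenvalues")) < 0))
})

test_that("quiescent CKI pool follows its synthesis/turnover balance", {
  p_hi <- set_parameters(default_p(), c(k_scki = 0.3))
  q_hi <- find_quiescent_state(p_hi, S = 0)
  cm <- conserved_moieties(q_hi, p_hi)
  expect_gt(cm[["CKI_sum"]], conserved_moieties(quiescent0(), default_p())[["CKI_sum"]])
  expect_equal(cm[["CKI_sum"]], unname(p_hi["k_scki"] / p_hi["k_dcki"]),
               tolerance = 0.05)
})

test_that("a trajectory started at a steady state stays there", {
  p0 <- set_parameters(default_p(), c(S = 0))
  tr <- run_timecourse(p0, quiescent0(), t_end = 50, dt_out = 1)
  drift <- vapply(species_names(), function(sp) {
    max(abs(tr[[sp]] - tr[[sp]][1]))
  }, numeric(1))
  expect_lt(max(drift), 1e-6)
})

test_that("moiety conservation holds along a stimulated trajectory", {
  tr <- wt_run()$traj
  p <- default_p()
  rb <- tr$Rb + tr$RbP + tr$RbPP + tr$RbE2F + tr$RbPE2F
  cdh1 <- tr$Cdh1 + tr$Cdh1P + tr$Emi1Cdh1
  expect_lt(max(abs(rb - p[["Rb_total"]])) / p[["Rb_total"]], 1e-6)
  expect_lt(max(abs(cdh1 - p[["Cdh1_total"]])) / p[["Cdh1_total"]], 1e-6)
})

test_that("perturbations are validated and logged", {
  expect_error(perturbation(5, c(bogus = 1)), "bogus")
  expect_error(run_timecourse(default_p(), quiescent0(), t_end = 10,
    perturbations = list(perturbation(20, c(S = 0)))), "t_end")
  tr <- run_timecourse(default_p(), quiescent0(), t_end = 5,
    perturbations = list(perturbation(2, c(S = 0))), dt_out = 0.5)
  expect_length(attr(tr, "perturbations"), 1)
  expect_equal(unname(attr(tr, "final_params")["S"]), 0)
})

test_that("event times are absent on a constant quiescent trajectory", {
  p0 <- set_parameters(default_p(), c(S = 0))
  tr <- run_timecourse(p0, quiescent0(), t_end = 30, dt_out = 0.5)
  ev <- event_times(tr)
  expect_true(all(is.na(ev[c("Rb_hyper_half", "Cdh1_inactivation")])))
})

test_that("halving integrator tolerances moves event times by < 1%", {
  ev1 <- wt_run()$events
  tr2 <- run_timecourse(default_p(), quiescent0(), t_end = 100,
                        dt_out = 0.25, atol = 5e-10, rtol = 5e-7)
  ev2 <- event_times(tr2)
  for (nm in names(ev1)) {
    expect_lt(abs(ev2[[nm]] - ev1[[nm]]) / ev1[[nm]], 0.01, label = nm)
  }
})

test_that("raising Cyclin E synthesis narrows the R-point-to-G1/S window", {
  ev <- wt_run()$events
  gap_wt <- ev[["Cdh1_inactivation"]] - ev[["Rb_hyper_half"]]
  p2 <- set_parameters(default_p(), c(k_scyce = 2 * default_p()[["k_scyce"]]))
  q2 <- find_quiescent_state(p2, S = 0)
  tr2 <- run_timecourse(p2, q2, t_end = 100, dt_out = 0.25)
  ev2 <- event_times(tr2)
  gap2 <- ev2[["Cdh1_inactivation"]] - ev2[["Rb_hyper_half"]]
  expect_lt(gap2, gap_wt)
})

test_that("commitment outcome is monotone in stress application time", {
  ev <- wt_run()$events
  tci <- ev[["Cdh1_inactivation"]]
  pr <- commitment_probe(default_p(), "stress",
                         t_grid = seq(floor(tci) - 4, ceiling(tci) + 4, by = 2),
                         init = quiescent0(), t_end = 100)
  expect_true(pr$monotone)
  expect_false(is.na(pr$switching_time))
})
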