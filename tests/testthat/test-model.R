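test_that("synthesis from the empty state drives only the expected species", {
  p <- set_parameters(default_p(), c(S = 0, k_smyc = 0, k_scyceb = 0,
                                     k_se2fb = 0, k_subl = 0))
  d <- g0_rhs(make_state(), params = p)
  expect_gt(d[["CKI"]], 0)                       # k_scki synthesis
  expect_equal(unname(d[["CKI"]]), unname(p["k_scki"]))
  expect_equal(unname(d[["Myc"]]), 0)
  expect_equal(unname(d[["CycD"]]), 0)
  expect_equal(unname(d[["Emi1"]]), 0)
})

test_that("the right-hand side conserves the Rb and Cdh1 moieties exactly", {
  set.seed(11)
  for (i in 1:25) {
    st <- stats::setNames(runif(19, 0, 1.2), species_names())
    d <- g0_rhs(st, params = default_p())
    expect_equal(sum(d[c("Rb", "RbP", "RbPP", "RbE2F", "RbPE2F")]), 0,
                 tolerance = 1e-12)
    expect_equal(sum(d[c("Cdh1", "Cdh1P", "Emi1Cdh1")]), 0, tolerance = 1e-12)
    # CKI moiety changes only through synthesis and degradation
    dcki_moiety <- sum(d[c("CKI", "CycDCKI", "CycECKI", "CycACKI")])
    expect_lt(dcki_moiety, unname(default_p()["k_scki"]) + 1e-12)
  }
})

test_that("rhs rejects invalid states", {
  st <- make_state(Rb = -0.5)
  expect_error(g0_rhs(st), "negative")
  expect_error(g0_rhs(c(make_state(), bogus = 1)), "bogus|length")
})

test_that("rhs vanishes at the quiescent state and is smooth there", {
  q <- quiescent0()
  p0 <- set_parameters(default_p(), c(S = 0))
  expect_lt(max(abs(g0_rhs(q, params = p0))), 1e-8)
  # finite-difference Jacobian is step-size consistent (smoothness)
  sys <- make_system(p0)
  x <- unname(q[sys$free])
  J1 <- jacobian_fd(sys$f, x, h_rel = 1e-5)
  J2 <- jacobian_fd(sys$f, x, h_rel = 1e-6)
  expect_lt(max(abs(J1 - J2)) / max(abs(J1)), 1e-5)
})

test_that("without mitogen Myc relaxes to zero", {
  p0 <- set_parameters(default_p(), c(S = 0))
  tr <- run_timecourse(p0, make_state(Myc = 30, Rb = 1.5, Cdh1 = 1, CKI = 0.5),
                       t_end = 30, dt_out = 1)
  expect_lt(tr$Myc[nrow(tr)], 1e-4)
})

test_that("observables satisfy their range invariants", {
  p <- default_p()
  # E2F entirely Rb-bound
  ob <- g0_observables(make_state(RbE2F = 0.8, Rb = 0.7, Cdh1 = 1), p)
  expect_equal(unname(ob["E2F_free"]), 0)
  expect_gt(ob[["E2F_total"]], 0)
  # CKI-free Cyclin E is fully active
  ob2 <- g0_observables(make_state(CycE = 0.4, Rb = 1.5, Cdh1 = 1), p)
  expect_equal(unname(ob2["CycE_Cdk2_activity"]), 0.4)
  # fractions bounded on a whole trajectory
  tr <- wt_run()$traj
  expect_true(all(tr$Cdh1_active_fraction >= -1e-9 & tr$Cdh1_active_fraction <= 1 + 1e-9))
  expect_true(all(tr$Rb_hyper_fraction >= -1e-9 & tr$Rb_hyper_fraction <= 1 + 1e-9))
  expect_true(all(tr$E2F_free <= tr$E2F_total + 1e-9))
})

test_that("conserved_moieties sums the declared pools", {
  p <- default_p()
  st <- make_state(Rb = unname(p["Rb_total"]))
  cm <- conserved_moieties(st, p)
  expect_equal(unname(cm["Rb_sum"]), unname(p["Rb_total"]))
  # CKI split arbitrarily across pools still sums to the total
  st2 <- make_state(CKI = 0.2, CycDCKI = 0.1, CycECKI = 0.15, CycACKI = 0.05,
                    Rb = 1.5, Cdh1 = 1)
  expect_equal(unname(conserved_moieties(st2, p)["CKI_sum"]), 0.5)
})
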