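test_that("every documented scenario preset is registered", {
  expect_setequal(list_scenarios(), c(
    "fig2a_wildtype", "fig2b_no_cyclinD", "fig2c_cyclinD_inhibition",
    "fig2d_stress_preG1S", "fig3_emi1_null", "fig4a_bifurcation_S",
    "fig4b_two_par_S_CKI", "fig5_cdh1_emi1_vs_cycE", "s3_myc_dependent",
    "s4_stress_postG1S", "s5_rb_threshold_sensitivity",
    "s6_cdh1_threshold_sensitivity", "mitotic_exit"))
  expect_error(run_scenario("nonsense"))
})

test_that("scenario outputs are reproducible and written to disk", {
  out <- withr::local_tempdir()
  r1 <- run_scenario("fig2b_no_cyclinD", out_dir = out)
  r2 <- run_scenario("fig2b_no_cyclinD")
  expect_true(all(r1$checks$pass))
  expect_equal(r1$checks$value, r2$checks$value, tolerance = 0)
  expect_true(file.exists(file.path(out, "fig2b_no_cyclinD_trajectory.csv")))
  expect_true(file.exists(file.path(out, "fig2b_no_cyclinD_checks.json")))
  rep <- jsonlite::read_json(file.path(out, "fig2b_no_cyclinD_checks.json"))
  expect_equal(rep$name, "fig2b_no_cyclinD")
})

test_that("Cyclin D inhibition is ineffective once Cyclin E exceeds CKI", {
  res <- run_scenario("fig2c_cyclinD_inhibition")
  expect_true(all(res$checks$pass))
})

test_that("mitotic exit commits with mitogen and quiesces without", {
  res <- run_scenario("mitotic_exit")
  expect_true(all(res$checks$pass))
  # commitment from mitotic exit is much faster than from quiescence
  t_me <- res$checks$value[res$checks$check == "with_mitogen_immediate_commitment"]
  expect_lt(t_me, 0.5 * wt_run()$events[["Cdh1_inactivation"]])
})

test_that("the stress scenarios bracket the G1/S commitment", {
  pre <- run_scenario("fig2d_stress_preG1S")
  post <- run_scenario("s4_stress_postG1S")
  expect_true(all(pre$checks$pass))
  expect_true(all(post$checks$pass))
})
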