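test_that("default parameter set is valid and matches the shipped table", {
  p <- default_p()
  expect_s3_class(p, "g0_parameters")
  expect_true(all(p >= 0))
  # golden file: the shipped config is an exact transcription of the defaults
  cfg <- system.file("extdata", "parameters_default.cfg", package = "g0switch")
  expect_true(nzchar(cfg))
  shipped <- load_parameters(cfg)
  expect_identical(names(shipped), names(p))
  expect_equal(unclass(shipped), unclass(p), tolerance = 0)
})

test_that("construction rejects malformed parameter sets", {
  v <- unclass(default_p())
  expect_error(g0_parameters(v[-match("k_dprbp", names(v))]), "k_dprbp")
  expect_error(g0_parameters(c(v, bogus = 1)), "bogus")
  v2 <- v; v2["k_scki"] <- -1
  expect_error(g0_parameters(v2), "negative")
  v3 <- v; v3["J_prb"] <- 0
  expect_error(g0_parameters(v3), "Michaelis")
})

test_that("overrides apply by name and reject unknown keys", {
  p <- set_parameters(default_p(), c(k_scki = 0.6))
  expect_equal(unname(p["k_scki"]), 0.6)
  expect_error(set_parameters(default_p(), c(nope = 1)), "nope")
  p2 <- default_parameters(c(S = 2))
  expect_equal(unname(p2["S"]), 2)
})
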