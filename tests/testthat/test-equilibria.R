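test_that("finite-difference Jacobian matches an analytic Jacobian", {
  f <- function(x) c(x[1]^2 - x[2], sin(x[1]) + exp(x[2]))
  x <- c(0.7, -0.3)
  J_true <- rbind(c(2 * x[1], -1), c(cos(x[1]), exp(x[2])))
  expect_equal(jacobian_fd(f, x), J_true, tolerance = 1e-8)
})

test_that("Newton iteration recovers the fixed point of a linear system", {
  A <- rbind(c(-2, 1), c(0.5, -3))
  b <- c(1, -2)
  xstar <- solve(A, -b)
  f <- function(x) as.numeric(A %*% x + b)
  for (x0 in list(c(0, 0), c(5, -5), c(-3, 4))) {
    res <- newton_solve(f, x0, tol = 1e-12)
    expect_true(res$converged)
    expect_equal(res$x, xstar, tolerance = 1e-9)
  }
})

test_that("brute-force search finds the quiescent equilibrium at S = 0", {
  p0 <- set_parameters(default_p(), c(S = 0))
  eq <- find_equilibria_bruteforce(p0, n_starts = 60, seed = 7)
  expect_gt(length(eq), 0)
  resid <- vapply(eq, function(e) e$resid, numeric(1))
  expect_true(all(resid < 1e-9))
  q <- quiescent0()
  d <- vapply(eq, function(e) max(abs(e$state - q)), numeric(1))
  i <- which.min(d)
  expect_lt(d[i], 1e-6)
  expect_equal(eq[[i]]$stability, "stable")
})

test_that("stability flags agree with simulation from a perturbed start", {
  p0 <- set_parameters(default_p(), c(S = 0))
  q <- quiescent0()
  # nudge only species outside the conserved moieties, so the perturbed
  # trajectory can relax back to the same equilibrium
  st <- q
  st[c("CycE", "CKI", "Emi1", "Ubl", "Myc")] <-
    st[c("CycE", "CKI", "Emi1", "Ubl", "Myc")] + 1e-3
  tr <- run_timecourse(p0, st, t_end = 300, dt_out = 10)
  end <- trajectory_state(tr, 300)
  expect_lt(max(abs(end - q)), 1e-4)
})
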