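# The cubic normal form dy/dt = p + y - y^3 has folds at p = +/- 2/(3 sqrt 3);
# with dy/dt = p + y - q y^3 the fold curve is p*(q) = 2 / (3 sqrt(3 q)).

test_that("pseudo-arclength continuation recovers the cubic normal-form folds", {
  f <- function(x, p) p + x - x^3
  br <- continue_branch(f, x0 = -1.5, p0 = -1.3425, p_range = c(-1.5, 1.5),
                        direction = 1, h0 = 0.05, h_max = 0.1)
  expect_false(br$truncated)
  expect_equal(nrow(br$folds), 2)
  expect_equal(sort(br$folds$p), c(-2 / (3 * sqrt(3)), 2 / (3 * sqrt(3))),
               tolerance = 1e-4)
  # stability flips across the folds: outer branches stable, middle unstable
  mid <- br$points$p > -0.2 & br$points$p < 0.2 & abs(br$points$x1) < 0.5
  expect_true(all(br$points$stability[mid] == "unstable"))
})

test_that("two-parameter fold tracking matches the analytic fold curve", {
  f1 <- function(x, p) p + x - x^3
  br <- continue_branch(f1, x0 = -1.5, p0 = -1.3425, p_range = c(-1.5, 1.5),
                        direction = 1, h0 = 0.05, h_max = 0.1)
  i <- which.max(br$folds$p)
  f2 <- function(x, p, q) p + x - q * x^3
  curve <- track_fold_2par(f2, as.numeric(br$folds[i, -1]), br$folds$p[i],
                           1, c(1.25, 1.5, 2, 3, 4))
  expect_equal(curve$p1, 2 / (3 * sqrt(3 * curve$p2)), tolerance = 1e-6)
})

test_that("continuation equilibria agree with brute-force search across S", {
  rb <- rb_branch()
  sys <- rb$sys; br <- rb$branch
  set.seed(42)
  slices <- runif(4, 0.02, 1.2)
  for (S_i in slices) {
    eq <- find_equilibria_bruteforce(
      sys = make_system(set_parameters(default_p(), c(S = S_i)),
                        clamp = sys$clamp, conserve_cki = TRUE),
      n_starts = 80, seed = 101)
    # refine branch crossings of this slice and match
    pts <- br$points
    cross <- which(diff(sign(pts$p - S_i)) != 0)
    f <- sys$with_param("S")
    for (e in eq) {
      d <- vapply(cross, function(k) {
        w <- (S_i - pts$p[k]) / (pts$p[k + 1] - pts$p[k])
        xi <- (1 - w) * as.numeric(pts[k, sys$free]) +
          w * as.numeric(pts[k + 1, sys$free])
        res <- newton_solve(function(x) f(x, S_i), xi, tol = 1e-10)
        if (!res$converged) return(Inf)
        max(abs(res$x - unname(e$x)))
      }, numeric(1))
      expect_lt(min(d), 1e-5, label = sprintf("slice S=%.3f", S_i))
    }
  }
})

test_that("a slow Cyclin E ramp shows hysteresis at the continuation folds", {
  p <- default_p()
  sys <- cdh1_emi1_subsystem(p, cyce = 0)
  eq <- find_equilibria_bruteforce(sys = sys, n_starts = 100, seed = 3)
  cd <- vapply(eq, function(e) e$state[["Cdh1"]], 1)
  on <- eq[[which.max(cd)]]
  br <- continue_model_branch(sys, "CycE", p_range = c(-0.05, 1.2),
                              start = on$x, p0 = 0, direction = 1,
                              h0 = 0.01, h_max = 0.05, max_steps = 500,
                              stability = FALSE)
  fold_up <- max(br$folds$p)
  # staircase ramp: integrate the clamped subsystem while stepping CycE
  f <- sys$with_param("CycE")
  ramp <- function(values, x0, t_step = 8) {
    x <- x0
    out <- numeric(length(values))
    for (i in seq_along(values)) {
      sol <- deSolve::lsoda(x, c(0, t_step),
                            function(t, y, parms) list(f(y, values[i])),
                            NULL, atol = 1e-10, rtol = 1e-8)
      x <- sol[nrow(sol), -1]
      out[i] <- x[match("Cdh1", sys$free)]
    }
    list(cdh1 = out, x = x)
  }
  up_vals <- seq(0, 0.6, by = 0.02)
  up <- ramp(up_vals, unname(on$x))
  jump_up <- up_vals[min(which(up$cdh1 < 0.3))]
  expect_equal(jump_up, fold_up, tolerance = 0.06)
  # ramp back down: the inactive state persists to zero Cyclin E
  down <- ramp(rev(up_vals), up$x)
  expect_true(all(down$cdh1 < 0.3))
})
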