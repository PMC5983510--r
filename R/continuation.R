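# Pseudo-arclength continuation of equilibrium branches, saddle-node (fold)
# detection and refinement, two-parameter fold tracking, and the
# threshold-sensitivity scans built on it.

# Tangent to the branch at z = (x, p): unit null vector of [J_x | J_p],
# oriented consistently with t_prev.
.branch_tangent <- function(f, x, p, t_prev) {
  n <- length(x)
  fx <- function(z) f(z, p)
  Jx <- jacobian_fd(fx, x)
  hp <- 1e-6 * max(abs(p), 1)
  Jp <- (f(x, p + hp) - f(x, p - hp)) / (2 * hp)
  A <- rbind(cbind(Jx, Jp), t_prev)
  b <- c(rep(0, n), 1)
  t_new <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(t_new) || any(!is.finite(t_new))) {
    # fall back to SVD null space
    M <- cbind(Jx, Jp)
    v <- svd(M, nu = 0, nv = n + 1)$v[, n + 1]
    t_new <- if (sum(v * t_prev) < 0) -v else v
  }
  t_new / sqrt(sum(t_new^2))
}

# One pseudo-arclength step of size h from (x, p) along tangent tv.
# Corrector: Newton on [f; tv . (z - z_pred)].
.pa_step <- function(f, x, p, tv, h, tol = 1e-10) {
  n <- length(x)
  z_pred <- c(x, p) + h * tv
  G <- function(z) c(f(z[1:n], z[n + 1]), sum(tv * (z - z_pred)))
  res <- newton_solve(G, z_pred, tol = tol, maxit = 25)
  if (!res$converged) return(NULL)
  list(x = res$x[1:n], p = res$x[n + 1])
}

#' Continue an equilibrium branch in one parameter
#'
#' Pseudo-arclength predictor-corrector continuation, traversing stable and
#' unstable segments and rounding folds. Folds (saddle-node points) are
#' detected where the parameter component of the branch tangent changes sign
#' and refined by bisection in arclength until the parameter is bracketed to
#' `fold_tol`.
#'
#' @param f function `f(x, p)` returning the reduced right-hand side; built
#'   with `sys$with_param(name)` for model work, or any closure for generic
#'   use (e.g. normal forms).
#' @param x0 equilibrium at `p0` (free coordinates).
#' @param p0 starting parameter value.
#' @param p_range numeric length-2; continuation stops once the branch
#'   leaves this interval.
#' @param direction +1/-1, initial direction of parameter change.
#' @param h0,h_min,h_max initial/minimal/maximal arclength steps.
#' @param max_steps step budget.
#' @param corrector_tol Newton tolerance of the corrector.
#' @param fold_tol bisection tolerance on the fold parameter.
#' @param stability compute eigenvalue stability flags per point.
#' @param scale positive per-coordinate scales; the arclength metric and
#'   predictor steps operate on `x / scale`, so coordinates of very
#'   different magnitude share the continuation step fairly. Stability is
#'   always evaluated on the unscaled system.
#' @return object of class `g0_branch`: list with `points` (data frame:
#'   `p`, `arclength`, `stability`, `max_re`, then one column per free
#'   coordinate `x1..xn` or species names), `folds` (data frame `p`,
#'   coordinates), `truncated` (TRUE if the minimal step was underrun),
#'   `names` (coordinate names).
#' @export
continue_branch <- function(f, x0, p0, p_range, direction = 1,
                            h0 = 0.01, h_min = 1e-4, h_max = 0.1,
                            max_steps = 3000, corrector_tol = 1e-10,
                            fold_tol = 1e-6, stability = TRUE,
                            coord_names = NULL, scale = NULL) {
  n <- length(x0)
  if (is.null(coord_names)) coord_names <- paste0("x", seq_len(n))
  f_orig <- f
  if (!is.null(scale)) {
    stopifnot(length(scale) == n, all(scale > 0))
    f <- function(u, p) f_orig(u * scale, p)
    x0 <- x0 / scale
  }
  # polish the starting point
  st <- newton_solve(function(x) f(x, p0), x0, tol = corrector_tol)
  if (!st$converged) stop("starting point is not an equilibrium at p = ", p0)
  x <- st$x; p <- p0
  tv <- .branch_tangent(f, x, p, c(rep(0, n), direction))

  pts_x <- matrix(NA_real_, max_steps + 1, n)
  pts_p <- numeric(max_steps + 1)
  pts_s <- numeric(max_steps + 1)
  stab <- character(max_steps + 1)
  mre <- numeric(max_steps + 1)
  record <- function(i, x, p, s) {
    xr <- if (is.null(scale)) x else x * scale
    pts_x[i, ] <<- xr; pts_p[i] <<- p; pts_s[i] <<- s
    if (stability) {
      cls <- classify_stability(NULL, xr, f = function(z) f_orig(z, p))
      stab[i] <<- cls$stability; mre[i] <<- cls$max_re
    } else { stab[i] <<- NA_character_; mre[i] <<- NA_real_ }
  }
  record(1, x, p, 0)

  folds <- list()
  truncated <- FALSE
  h <- h0
  s_arc <- 0
  i <- 1
  while (i <= max_steps) {
    step <- .pa_step(f, x, p, tv, h, corrector_tol)
    if (is.null(step)) {
      h <- h / 2
      if (h < h_min) { truncated <- TRUE; break }
      next
    }
    tv_new <- .branch_tangent(f, step$x, step$p, tv)
    # fold: parameter component of the tangent changes sign
    if (sign(tv[n + 1]) != 0 && sign(tv_new[n + 1]) != 0 &&
        sign(tv[n + 1]) != sign(tv_new[n + 1])) {
      fold <- .refine_fold(f, x, p, tv, h, fold_tol, corrector_tol)
      if (!is.null(fold)) {
        xf <- if (is.null(scale)) fold$x else fold$x * scale
        folds[[length(folds) + 1]] <- c(p = fold$p,
                                        stats::setNames(xf, coord_names))
      }
    }
    s_arc <- s_arc + h
    x <- step$x; p <- step$p; tv <- tv_new
    i <- i + 1
    record(i, x, p, s_arc)
    if (h < h_max) h <- min(h * 1.4, h_max)
    if (p < min(p_range) - 1e-12 || p > max(p_range) + 1e-12) break
    if (max(abs(x)) > 1e3) { truncated <- TRUE; break }
  }
  if (i >= max_steps) truncated <- TRUE

  keep <- seq_len(i)
  pts <- data.frame(p = pts_p[keep], arclength = pts_s[keep],
                    stability = stab[keep], max_re = mre[keep])
  xm <- pts_x[keep, , drop = FALSE]
  colnames(xm) <- coord_names
  pts <- cbind(pts, as.data.frame(xm))
  folds_df <- if (length(folds)) as.data.frame(do.call(rbind, folds))
  else data.frame(p = numeric(0))
  structure(list(points = pts, folds = folds_df, truncated = truncated,
                 names = coord_names),
            class = "g0_branch")
}

# Bisection in arclength step size between a point and the fold-crossing
# step, driving the parameter-component of the tangent to zero.
.refine_fold <- function(f, x, p, tv, h, fold_tol, corrector_tol) {
  n <- length(x)
  tp_at <- function(sigma) {
    st <- .pa_step(f, x, p, tv, sigma, corrector_tol)
    if (is.null(st)) return(NULL)
    tvn <- .branch_tangent(f, st$x, st$p, tv)
    list(tp = tvn[n + 1], x = st$x, p = st$p)
  }
  lo <- 0; hi <- h
  s_lo <- tv[n + 1]
  best <- NULL
  p_lo <- p
  hi_eval <- tp_at(hi)
  if (is.null(hi_eval)) return(NULL)
  p_hi <- hi_eval$p
  for (k in 1:60) {
    if (abs(p_hi - p_lo) < fold_tol) break
    mid <- (lo + hi) / 2
    ev <- tp_at(mid)
    if (is.null(ev)) return(best)
    best <- ev
    if (sign(ev$tp) == sign(s_lo)) { lo <- mid; p_lo <- ev$p }
    else { hi <- mid; p_hi <- ev$p }
  }
  if (is.null(best)) best <- hi_eval
  list(p = (p_lo + p_hi) / 2, x = best$x)
}

#' @export
print.g0_branch <- function(x, ...) {
  cat("<g0_branch> ", nrow(x$points), " points, p in [",
      format(min(x$points$p), digits = 4), ", ",
      format(max(x$points$p), digits = 4), "], ",
      nrow(x$folds), " fold(s)",
      if (x$truncated) " [truncated]" else "", "\n", sep = "")
  invisible(x)
}

#' Continue a model equilibrium branch
#'
#' Convenience wrapper around [continue_branch()] for a clamped/reduced
#' model system: the free parameter may be a model parameter (e.g. `S`) or a
#' clamped species (e.g. `CycE` in the Cdh1-Emi1 subsystem).
#'
#' @param sys a `g0_system`.
#' @param free_param parameter (or clamped-species) name.
#' @param p_range continuation interval.
#' @param start full state vector or free-coordinate vector of a verified
#'   equilibrium at `p0`.
#' @param p0 starting parameter value (defaults to the current value).
#' @param ... passed to [continue_branch()].
#' @return a `g0_branch` whose coordinate columns are the system's free
#'   species.
#' @export
continue_model_branch <- function(sys, free_param, p_range, start,
                                  p0 = NULL, ...) {
  f <- sys$with_param(free_param)
  if (is.null(p0)) {
    p0 <- if (free_param %in% names(sys$params)) sys$params[[free_param]]
    else sys$clamp[[free_param]]
  }
  x0 <- if (length(start) == length(species_names())) unname(as_state(start)[sys$free])
  else unname(start)
  sc <- unname(.state_upper_bounds(sys$params)[sys$free])
  continue_branch(f, x0, p0, p_range, coord_names = sys$free, scale = sc, ...)
}

#' Track a fold in two parameters
#'
#' Continues the extended fold-defining system \{f(x, p1, p2) = 0,
#' J_x v = 0, |v| = 1\} in the second parameter, starting from a fold
#' located on a one-parameter branch. The directional derivative J_x v is
#' evaluated by central differences, so no analytic Jacobian is required.
#'
#' @param f2 function `f2(x, p1, p2)` returning the reduced right-hand side.
#' @param x_fold,p1_fold fold location from a one-parameter continuation.
#' @param p2_0 current value of the second parameter.
#' @param p2_values values of the second parameter at which to re-locate the
#'   fold (continuation proceeds through them in order, with intermediate
#'   sub-steps inserted adaptively on corrector failure).
#' @param tol Newton tolerance for the extended system.
#' @return data frame `p2`, `p1` (fold location) and the fold-state
#'   coordinates; rows are the values reached before the fold was lost (if
#'   it annihilates, the curve is truncated and attribute `lost_at` records
#'   the first failing `p2`).
#' @export
track_fold_2par <- function(f2, x_fold, p1_fold, p2_0, p2_values,
                            tol = 1e-9) {
  n <- length(x_fold)
  fold_system <- function(z, p2) {
    x <- z[1:n]; v <- z[(n + 1):(2 * n)]; p1 <- z[2 * n + 1]
    fx <- f2(x, p1, p2)
    eps <- 1e-6 * max(sqrt(sum(x^2)), 1)
    jv <- (f2(x + eps * v, p1, p2) - f2(x - eps * v, p1, p2)) / (2 * eps)
    c(fx, jv, sum(v^2) - 1)
  }
  # initial null vector from the Jacobian at the fold
  J <- jacobian_fd(function(x) f2(x, p1_fold, p2_0), x_fold)
  sv <- svd(J)
  v0 <- sv$v[, n]
  z <- c(x_fold, v0, p1_fold)
  res <- newton_solve(function(zz) fold_system(zz, p2_0), z, tol = tol)
  if (!res$converged) stop("could not sharpen the starting fold point")
  z <- res$x

  solve_at <- function(z_init, p2) {
    r <- newton_solve(function(zz) fold_system(zz, p2), z_init, tol = tol)
    if (r$converged) r$x else NULL
  }

  rows <- list()
  lost_at <- NA_real_
  p2_prev <- p2_0
  for (p2 in p2_values) {
    # adaptive sub-stepping from p2_prev to p2
    target <- p2
    cur_from <- p2_prev
    z_try <- z
    ok <- TRUE
    nsub <- 1
    repeat {
      step_vals <- seq(cur_from, target, length.out = nsub + 1)[-1]
      z_tmp <- z_try
      failed <- FALSE
      for (pv in step_vals) {
        zz <- solve_at(z_tmp, pv)
        if (is.null(zz)) { failed <- TRUE; break }
        z_tmp <- zz
      }
      if (!failed) { z_try <- z_tmp; break }
      nsub <- nsub * 2
      if (nsub > 64) { ok <- FALSE; break }
    }
    if (!ok) { lost_at <- p2; break }
    z <- z_try
    p2_prev <- p2
    rows[[length(rows) + 1]] <- c(p2 = p2, p1 = z[2 * n + 1],
                                  stats::setNames(z[1:n], paste0("x", 1:n)))
  }
  out <- if (length(rows)) as.data.frame(do.call(rbind, rows))
  else data.frame(p2 = numeric(0), p1 = numeric(0))
  attr(out, "lost_at") <- lost_at
  out
}

#' Sensitivity of a saddle-node threshold to parameter fold-changes
#'
#' For each parameter, the fold (threshold) located at base parameters is
#' re-tracked across multiplicative factors spanning `fold_range`
#' (log-spaced grid through 1), using two-parameter fold continuation.
#' Output thresholds are normalised by the base threshold.
#'
#' @param sys a `g0_system` for the subsystem carrying the fold.
#' @param free_param bifurcation parameter of the one-parameter branch
#'   (e.g. `"S"`, or clamped `"CycE"`).
#' @param x_fold,p1_fold the base fold (from [continue_model_branch()]).
#' @param param_list parameters to scan.
#' @param fold_range multiplicative range, default `c(1/5, 5)`.
#' @param n_grid points per side of the factor grid.
#' @return data frame: `param`, `factor`, `threshold`, `threshold_norm`
#'   (threshold / base threshold); attribute `lost` names parameters whose
#'   fold annihilated inside the range, with the boundary factor.
#' @export
threshold_sensitivity <- function(sys, free_param, x_fold, p1_fold,
                                  param_list, fold_range = c(1 / 5, 5),
                                  n_grid = 4) {
  f1 <- sys$with_param(free_param)
  rows <- list()
  lost <- list()
  for (pm in param_list) {
    base <- if (pm %in% names(sys$params)) sys$params[[pm]]
    else sys$clamp[[pm]]
    if (base == 0) stop("cannot scan a zero-valued parameter: ", pm)
    f2 <- function(x, p1, p2) {
      # p2 is the scanned parameter's absolute value
      if (pm %in% names(sys$params)) {
        pset <- unclass(sys$params); pset[[pm]] <- p2
        if (free_param %in% names(pset)) {
          pset[[free_param]] <- p1
          sys$f(x, sys$clamp, pset)
        } else {
          cl <- sys$clamp; cl[[free_param]] <- p1
          sys$f(x, cl, pset)
        }
      } else {
        cl <- sys$clamp; cl[[pm]] <- p2
        if (free_param %in% names(sys$params)) {
          pset <- unclass(sys$params); pset[[free_param]] <- p1
          sys$f(x, cl, pset)
        } else {
          cl[[free_param]] <- p1
          sys$f(x, cl, sys$params)
        }
      }
    }
    up <- exp(seq(0, log(max(fold_range)), length.out = n_grid + 1))[-1]
    dn <- exp(seq(0, log(min(fold_range)), length.out = n_grid + 1))[-1]
    res_up <- track_fold_2par(f2, x_fold, p1_fold, base, base * up)
    res_dn <- track_fold_2par(f2, x_fold, p1_fold, base, base * dn)
    for (side in list(list(r = res_dn, fac = dn, rev = TRUE),
                      list(r = res_up, fac = up, rev = FALSE))) {
      r <- side$r
      if (nrow(r)) {
        fac <- r$p2 / base
        rows[[length(rows) + 1]] <- data.frame(
          param = pm, factor = fac, threshold = r$p1)
      }
      if (!is.na(attr(r, "lost_at"))) {
        lost[[pm]] <- attr(r, "lost_at") / base
      }
    }
    rows[[length(rows) + 1]] <- data.frame(param = pm, factor = 1,
                                           threshold = p1_fold)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$param, out$factor), ]
  out$threshold_norm <- out$threshold / p1_fold
  rownames(out) <- NULL
  attr(out, "lost") <- lost
  out
}

#' Steepness of a sensitivity curve
#'
#' Maximum absolute log-log slope of the threshold-shift curve per
#' parameter: max |d log(threshold) / d log(factor)| over adjacent grid
#' points. A parameter whose fold annihilates inside the scanned range, or
#' whose threshold reaches zero or changes sign there, extinguishes or
#' un-gates the switch within a five-fold change: its steepness is reported
#' as `Inf` (maximal sensitivity). Larger values mean the threshold
#' responds more steeply to a fold-change in the parameter.
#'
#' @param sens output of [threshold_sensitivity()].
#' @return named numeric vector, sorted decreasing.
#' @export
sensitivity_steepness <- function(sens) {
  lost <- attr(sens, "lost")
  sp <- split(sens, sens$param)
  out <- vapply(sp, function(d) {
    pm <- d$param[1]
    d <- d[order(d$factor), ]
    if (!is.null(lost[[pm]])) return(Inf)
    if (any(d$threshold <= 0)) return(Inf)
    max(abs(diff(log(d$threshold)) / diff(log(d$factor))))
  }, numeric(1))
  sort(out, decreasing = TRUE)
}
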