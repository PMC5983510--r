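# Equilibrium solving, finite-difference Jacobians and stability analysis.

#' Finite-difference Jacobian
#'
#' Central differences with step `h_rel * max(|x_j|, 1)` per component
#' (the model is smooth on the non-negative orthant, so central differences
#' at 1e-6 relative step give ~1e-5 relative accuracy).
#'
#' @param f vector-valued function of one vector argument.
#' @param x evaluation point.
#' @param h_rel relative step size.
#' @return Jacobian matrix (length(f(x)) rows, length(x) columns).
#' @export
jacobian_fd <- function(f, x, h_rel = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Damped Newton iteration: full step, halved until the residual norm
# decreases. Returns list(x, fx, converged, iter).
newton_solve <- function(f, x0, tol = 1e-12, maxit = 60, h_rel = 1e-6) {
  x <- x0
  fx <- f(x)
  for (it in seq_len(maxit)) {
    nrm <- max(abs(fx))
    if (!is.finite(nrm)) return(list(x = x, fx = fx, converged = FALSE, iter = it))
    if (nrm < tol) return(list(x = x, fx = fx, converged = TRUE, iter = it))
    J <- jacobian_fd(f, x, h_rel)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(x = x, fx = fx, converged = FALSE, iter = it))
    }
    lambda <- 1
    improved <- FALSE
    for (k in 1:40) {
      xn <- x + lambda * step
      fn <- f(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < nrm) {
        x <- xn; fx <- fn; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      # accept a tiny step anyway; next iteration re-linearises
      x <- x + lambda * step
      fx <- f(x)
    }
  }
  list(x = x, fx = fx, converged = max(abs(fx)) < tol, iter = maxit)
}

#' Classify the stability of an equilibrium of a reduced system
#'
#' @param sys a `g0_system` (see [make_system()]).
#' @param x equilibrium in the system's free coordinates.
#' @param f optional function replacing `sys$f` (used during continuation
#'   when a parameter is varied).
#' @return list with `stability` ("stable"/"unstable"), `eigenvalues`
#'   (complex vector) and `max_re`.
#' @export
classify_stability <- function(sys, x, f = NULL) {
  if (is.null(f)) f <- function(z) sys$f(z)
  J <- jacobian_fd(f, x)
  ev <- eigen(J, only.values = TRUE)$values
  mre <- max(Re(ev))
  list(stability = if (mre < -1e-8) "stable" else "unstable",
       eigenvalues = ev, max_re = mre)
}

#' Multi-start brute-force equilibrium search
#'
#' Damped Newton iterations started from Latin-hypercube points inside a
#' physically admissible box, deduplicated and verified. Serves as the
#' independent oracle for the continuation code.
#'
#' @param params a [g0_parameters] object.
#' @param clamp optional named clamp vector (see [make_system()]).
#' @param n_starts number of Latin-hypercube starting points.
#' @param conserve_cki passed to [make_system()].
#' @param sys optionally a prebuilt `g0_system` (overrides
#'   `params`/`clamp`/`conserve_cki`).
#' @param seed RNG seed for the Latin hypercube.
#' @param dedup_tol pairwise max-norm distance below which two solutions are
#'   considered the same equilibrium.
#' @param resid_tol residual infinity-norm for acceptance.
#' @return list of equilibrium points; each is a list with `x` (free
#'   coordinates), `state` (full state vector), `stability`, `eigenvalues`.
#' @export
find_equilibria_bruteforce <- function(params = default_parameters(),
                                       clamp = NULL, n_starts = 100,
                                       conserve_cki = FALSE, sys = NULL,
                                       seed = 1, dedup_tol = 1e-6,
                                       resid_tol = 1e-9) {
  stopifnot(n_starts >= 1)
  if (is.null(sys)) sys <- make_system(params, clamp, conserve_cki)
  p <- sys$params
  upper <- .state_upper_bounds(p)[sys$free]
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, length(sys$free))
  sols <- list()
  for (i in seq_len(n_starts)) {
    x0 <- u[i, ] * upper
    res <- newton_solve(sys$f, x0, tol = resid_tol)
    if (!res$converged) next
    st <- sys$reconstruct(res$x)
    if (any(st < -1e-6)) next
    dup <- FALSE
    for (s in sols) {
      if (max(abs(s$x - res$x)) < dedup_tol) { dup <- TRUE; break }
    }
    if (dup) next
    cls <- classify_stability(sys, res$x)
    sols[[length(sols) + 1]] <- list(
      x = stats::setNames(res$x, sys$free), state = st,
      stability = cls$stability, eigenvalues = cls$eigenvalues,
      resid = max(abs(res$fx)))
  }
  sols
}

# Heuristic admissible upper bounds per species, used for multistart boxes.
.state_upper_bounds <- function(p) {
  cap <- function(x) min(max(x, 0.1), 50)
  myc_hi <- cap(1.5 * p[["k_smyc"]] * max(p[["S"]], 0.2) / max(p[["k_dmyc"]], 1e-3))
  ub <- c(
    Myc = myc_hi,
    CycD = cap((p[["k_scycds"]] * max(p[["S"]], 0.2) + p[["k_scycdm"]] * myc_hi) /
                 max(p[["k_dcycd"]], 0.02)),
    CycDCKI = p[["CKI_total"]] + 0.1,
    CycE = cap((p[["k_scyceb"]] + p[["k_scyce"]] + p[["k_scycem"]] * myc_hi) /
                 max(p[["k_dcyce"]], 0.02)),
    CycECKI = p[["CKI_total"]] + 0.1,
    CycA = cap(p[["k_scyca"]] / max(p[["k_dcyca"]], 0.02)),
    CycACKI = p[["CKI_total"]] + 0.1,
    CKI = cap(2 * p[["CKI_total"]] + 0.5),
    E2F = cap(2 * (p[["k_se2fb"]] + p[["k_se2f"]] + p[["k_se2fm"]] * myc_hi) /
                max(p[["k_de2f"]], 0.02)),
    Rb = p[["Rb_total"]], RbP = p[["Rb_total"]], RbPP = p[["Rb_total"]],
    RbE2F = p[["Rb_total"]], RbPE2F = p[["Rb_total"]],
    Cdh1 = p[["Cdh1_total"]], Cdh1P = p[["Cdh1_total"]],
    Emi1 = cap(2 * p[["k_semi1"]] / max(p[["k_demi1"]], 1e-3)),
    Emi1Cdh1 = p[["Cdh1_total"]],
    Ubl = cap(1.5 * p[["k_subl"]] / max(p[["k_dubl"]], 1e-3))
  )
  ub[species_names()]
}
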