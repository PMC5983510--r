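# Time-course integration with timed parameter overrides, quiescent-state
# initialisation, event extraction and commitment probing.

#' Timed parameter override
#'
#' @param at_time application time (h, >= 0).
#' @param overrides named numeric vector of parameter overrides; every key
#'   must be a model parameter.
#' @return object of class `g0_perturbation`.
#' @export
perturbation <- function(at_time, overrides) {
  if (is.list(overrides)) overrides <- unlist(overrides)
  stopifnot(is.numeric(at_time), length(at_time) == 1, at_time >= 0)
  bad <- setdiff(names(overrides), names(.g0_default_values()))
  if (length(bad)) stop("unknown parameter(s) in perturbation: ",
                        paste(bad, collapse = ", "))
  structure(list(at_time = at_time, overrides = overrides),
            class = "g0_perturbation")
}

#' Named perturbation templates
#'
#' The perturbations used by the model's computational experiments:
#' \describe{
#'   \item{cyclinD_inhibition}{neutralisation of Cyclin D (anti-Cyclin D
#'     treatment): synthesis stopped, existing protein cleared at
#'     `k_dcycd = 0.1`.}
#'   \item{stress}{stress-induced CKI synthesis, `k_scki = 0.6`.}
#'   \item{mitogen_withdrawal}{`S = 0`.}
#'   \item{cdk2_inhibition}{Cdk2 activity knockout (`e_cdk2 = 0`) with the
#'     drug-stabilised cyclin turnover `k_dcyce = 0.01`, `k_dcyca = 0.01`.}
#' }
#' @return named list of override vectors.
#' @export
perturbation_templates <- function() {
  list(
    cyclinD_inhibition = c(k_scycdm = 0, k_scycds = 0, k_dcycd = 0.1),
    stress = c(k_scki = 0.6),
    mitogen_withdrawal = c(S = 0),
    cdk2_inhibition = c(e_cdk2 = 0, k_dcyce = 0.01, k_dcyca = 0.01)
  )
}

#' Find the quiescent steady state
#'
#' Integrates from a cold start (un-phosphorylated Rb, active Cdh1, no
#' cyclins) to the neighbourhood of the low-E2F attractor, polishes it with
#' Newton iterations on the conservation-reduced system, and verifies
#' stability through the reduced Jacobian.
#'
#' @param params a [g0_parameters] object.
#' @param S mitogen level at which the quiescent state is sought (overrides
#'   `params["S"]`; default 0, the pre-stimulation level).
#' @param t_settle settling horizon for the initial integration (h).
#' @return named state vector with attributes `resid` (infinity norm of the
#'   right-hand side), `eigenvalues` and `observables`.
#' @export
find_quiescent_state <- function(params = default_parameters(), S = 0,
                                 t_settle = 500) {
  params <- set_parameters(params, c(S = S))
  init <- make_state(Rb = unname(params["Rb_total"]),
                     Cdh1 = unname(params["Cdh1_total"]),
                     CKI = unname(params["k_scki"] / max(params["k_dcki"], 1e-8)))
  tr <- run_timecourse(params, init, t_end = t_settle, dt_out = t_settle / 50)
  end <- trajectory_state(tr, t_settle)
  sys <- make_system(params)
  x0 <- unname(end[sys$free])
  res <- newton_solve(sys$f, x0, tol = 1e-12)
  st <- sys$reconstruct(res$x)
  resid <- max(abs(.g0_rhs_raw(st, params)))
  if (!res$converged || resid > 1e-10 || any(st < -1e-8)) {
    stop("no steady state found at S = ", S,
         " (residual ", format(resid, digits = 3), ")")
  }
  st <- pmax(st, 0)
  cls <- classify_stability(sys, unname(st[sys$free]))
  obs <- g0_observables(st, params)
  if (cls$stability != "stable") {
    stop("steady state at S = ", S, " is unstable (max Re eigenvalue ",
         format(cls$max_re, digits = 3), "): no stable quiescent state")
  }
  if (obs[["E2F_free"]] > 0.5 * obs[["E2F_total"]] ||
      obs[["Cdh1_active_fraction"]] < 0.5) {
    stop("stable state at S = ", S, " is not quiescent ",
         "(high free E2F or inactive Cdh1)")
  }
  attr(st, "resid") <- resid
  attr(st, "eigenvalues") <- cls$eigenvalues
  attr(st, "observables") <- obs
  st
}

#' Integrate a time course with timed perturbations
#'
#' Stiff integration (lsoda, absolute tolerance 1e-9, relative 1e-6) with a
#' hard restart at every perturbation time: the integrator is stopped, the
#' parameter overrides applied, and integration resumed from the interrupted
#' state, so no interpolation crosses the discontinuity.
#'
#' @param params a [g0_parameters] object.
#' @param init named initial state vector.
#' @param t_end end time (h).
#' @param perturbations list of [perturbation()] objects (times < `t_end`).
#' @param dt_out output sampling interval (h).
#' @param atol,rtol integrator tolerances.
#' @return a `g0_trajectory`: data frame with `time`, one column per
#'   species, one per observable; attributes `params` (base set),
#'   `perturbations`, `final_params`.
#' @export
run_timecourse <- function(params, init, t_end, perturbations = list(),
                           dt_out = 0.1, atol = 1e-9, rtol = 1e-6) {
  params <- as_g0_parameters(params)
  init <- check_state(init)
  if (inherits(perturbations, "g0_perturbation")) {
    perturbations <- list(perturbations)
  }
  for (pb in perturbations) {
    if (!inherits(pb, "g0_perturbation")) stop("perturbations must be g0_perturbation objects")
    if (pb$at_time >= t_end) stop("perturbation time must be < t_end")
  }
  times_p <- vapply(perturbations, function(x) x$at_time, numeric(1))
  o <- order(times_p)
  perturbations <- perturbations[o]
  times_p <- times_p[o]

  deriv <- function(t, y, parms) list(unname(.g0_rhs_raw(
    stats::setNames(y, species_names()), parms)))

  bounds <- unique(c(0, times_p, t_end))
  cur <- params
  y <- unname(init)
  pieces <- list()
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    applied <- which(times_p == t0)
    for (i in applied) cur <- set_parameters(cur, perturbations[[i]]$overrides)
    tt <- unique(c(seq(t0, t1, by = dt_out), t1))
    out <- deSolve::lsoda(y, tt, deriv, unclass(cur), atol = atol,
                          rtol = rtol, maxsteps = 50000)
    if (attr(out, "istate")[1] < 0) {
      stop("integration failed near t = ", format(out[nrow(out), 1]), " h")
    }
    colnames(out) <- c("time", species_names())
    y <- unname(out[nrow(out), -1])
    if (min(y) < -.g0_neg_tol) {
      stop("integration produced negative concentrations beyond tolerance")
    }
    y <- pmax(y, 0)
    pieces[[k]] <- if (k == length(bounds) - 1) out else out[-nrow(out), , drop = FALSE]
  }
  tab <- as.data.frame(do.call(rbind, pieces))
  obs <- .observables_frame(tab, params)
  tab <- cbind(tab, obs)
  attr(tab, "params") <- params
  attr(tab, "final_params") <- cur
  attr(tab, "perturbations") <- perturbations
  class(tab) <- c("g0_trajectory", class(tab))
  tab
}

.observables_frame <- function(tab, params) {
  p <- as_g0_parameters(params)
  data.frame(
    E2F_total = tab$E2F + tab$RbE2F + tab$RbPE2F,
    E2F_free = tab$E2F,
    CycE_Cdk2_activity = p[["e_cdk2"]] * tab$CycE,
    CycA_Cdk2_activity = p[["e_cdk2"]] * tab$CycA,
    Cdh1_active_fraction = tab$Cdh1 / p[["Cdh1_total"]],
    Rb_hyper_fraction = tab$RbPP / p[["Rb_total"]],
    CycE_total = tab$CycE + tab$CycECKI,
    CycD_total = tab$CycD + tab$CycDCKI,
    CKI_total_dyn = tab$CKI + tab$CycDCKI + tab$CycECKI + tab$CycACKI,
    Emi1_total = tab$Emi1 + tab$Emi1Cdh1
  )
}

#' Extract the state vector at (or nearest to) a trajectory time
#' @param traj a `g0_trajectory`.
#' @param t time (h).
#' @return named state vector.
#' @export
trajectory_state <- function(traj, t) {
  i <- which.min(abs(traj$time - t))
  stats::setNames(as.numeric(traj[i, species_names()]), species_names())
}

#' First-crossing event times of a trajectory
#'
#' Events (thresholds are artifact conventions, configurable):
#' \describe{
#'   \item{CycE_exceeds_CKI}{first time total Cyclin E exceeds total CKI.}
#'   \item{Rb_hyper_half}{Rb hyper-phosphorylated fraction crosses
#'     `rb_threshold` upward.}
#'   \item{Cdh1_inactivation}{Cdh1 active fraction crosses `cdh1_threshold`
#'     downward.}
#'   \item{Emi1_rise}{total Emi1 first crosses `emi1_frac` of its
#'     trajectory maximum upward.}
#' }
#'
#' @param traj a `g0_trajectory`.
#' @param params parameter set (defaults to the trajectory's).
#' @param rb_threshold,cdh1_threshold,emi1_frac event thresholds.
#' @return named numeric vector of event times (h); `NA` where the event
#'   does not occur. Attribute `multiple` lists events with more than one
#'   crossing (the first is reported).
#' @export
event_times <- function(traj, params = attr(traj, "params"),
                        rb_threshold = 0.5, cdh1_threshold = 0.5,
                        emi1_frac = 0.1) {
  cross <- function(x, thr, dir) {
    s <- x - thr
    if (dir > 0) idx <- which(s[-1] > 0 & s[-length(s)] <= 0)
    else idx <- which(s[-1] < 0 & s[-length(s)] >= 0)
    idx
  }
  interp <- function(x, thr, i) {
    t0 <- traj$time[i]; t1 <- traj$time[i + 1]
    x0 <- x[i]; x1 <- x[i + 1]
    if (x1 == x0) return(t0)
    t0 + (thr - x0) / (x1 - x0) * (t1 - t0)
  }
  ev <- c(CycE_exceeds_CKI = NA_real_, Rb_hyper_half = NA_real_,
          Cdh1_inactivation = NA_real_, Emi1_rise = NA_real_)
  multiple <- character(0)
  take <- function(name, x, thr, dir) {
    idx <- cross(x, thr, dir)
    if (length(idx) > 1) multiple <<- c(multiple, name)
    if (length(idx)) ev[name] <<- interp(x, thr, idx[1])
  }
  take("CycE_exceeds_CKI", traj$CycE_total - traj$CKI_total_dyn, 0, +1)
  take("Rb_hyper_half", traj$Rb_hyper_fraction, rb_threshold, +1)
  take("Cdh1_inactivation", traj$Cdh1_active_fraction, cdh1_threshold, -1)
  emax <- max(traj$Emi1_total)
  if (emax > 0) take("Emi1_rise", traj$Emi1_total, emi1_frac * emax, +1)
  attr(ev, "multiple") <- multiple
  ev
}

#' Probe the commitment point with a timed perturbation
#'
#' Applies a perturbation template at each time of a grid, classifies the
#' long-time outcome (state at `t_end`) as `proliferate` or `quiesce`, and
#' reports the switching time: the latest application time that still
#' reverts the cell to quiescence.
#'
#' Classification uses free E2F at `t_end` against the midpoint between the
#' quiescent and proliferative reference levels (a separatrix proxy);
#' outcomes inside `ambiguous_band` of the midpoint are flagged unsettled.
#'
#' @param params a [g0_parameters] object (the stimulated condition,
#'   normally `S = 1`).
#' @param template name of a [perturbation_templates()] entry, or a named
#'   override vector.
#' @param t_grid application times to probe (h).
#' @param init initial state; default the quiescent state at S = 0.
#' @param t_end classification horizon (h).
#' @param base_perturbations perturbations present in every run (for probing
#'   inside a composite scenario).
#' @param dt_out trajectory sampling (h).
#' @return list with `outcomes` (data frame: `t_perturb`, `outcome`,
#'   `E2F_free_end`, `Cdh1_end`, `ambiguous`), `switching_time` (NA if the
#'   perturbation never/always reverts), `monotone` (single switch along the
#'   grid), `threshold` (the E2F midpoint used).
#' @export
commitment_probe <- function(params = default_parameters(),
                             template = "stress",
                             t_grid = seq(1, 30, by = 1),
                             init = NULL, t_end = 100,
                             base_perturbations = list(), dt_out = 0.25) {
  params <- as_g0_parameters(params)
  if (is.character(template)) {
    tpl <- perturbation_templates()[[template]]
    if (is.null(tpl)) stop("unknown perturbation template: ", template)
  } else tpl <- template
  if (is.null(init)) init <- find_quiescent_state(params, S = 0)

  ref <- run_timecourse(params, init, t_end = t_end,
                        perturbations = base_perturbations, dt_out = dt_out)
  e2f_hi <- ref$E2F_free[nrow(ref)]
  q <- find_quiescent_state(params, S = unname(params["S"]) * 0)
  e2f_lo <- unname(q["E2F"])
  mid <- (e2f_hi + e2f_lo) / 2
  band <- 0.1 * (e2f_hi - e2f_lo)

  out <- data.frame(t_perturb = t_grid, outcome = NA_character_,
                    E2F_free_end = NA_real_, Cdh1_end = NA_real_,
                    ambiguous = FALSE)
  for (i in seq_along(t_grid)) {
    pb <- c(base_perturbations, list(perturbation(t_grid[i], tpl)))
    tr <- run_timecourse(params, init, t_end = t_end, perturbations = pb,
                         dt_out = dt_out)
    ef <- tr$E2F_free[nrow(tr)]
    out$E2F_free_end[i] <- ef
    out$Cdh1_end[i] <- tr$Cdh1_active_fraction[nrow(tr)]
    out$outcome[i] <- if (ef > mid) "proliferate" else "quiesce"
    out$ambiguous[i] <- abs(ef - mid) < band
  }
  qi <- which(out$outcome == "quiesce")
  switching <- if (length(qi)) t_grid[max(qi)] else NA_real_
  monotone <- !is.na(switching) &&
    all(out$outcome[t_grid <= switching] == "quiesce") &&
    all(out$outcome[t_grid > switching] == "proliferate")
  if (!length(qi)) monotone <- all(out$outcome == "proliferate")
  list(outcomes = out, switching_time = switching, monotone = monotone,
       threshold = mid)
}
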