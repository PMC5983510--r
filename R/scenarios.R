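# Named scenario presets: each reproduces one of the model's canonical
# computational experiments end-to-end (parameter deltas, initial
# condition, timed perturbations, analysis, qualitative checks).
#
# Timed perturbations are self-calibrating: application times are derived
# from event times of the wild-type run (e.g. "1 h after Rb
# hyper-phosphorylation") rather than hard-coded hours.

.g0_scenario_names <- c(
  "fig2a_wildtype", "fig2b_no_cyclinD", "fig2c_cyclinD_inhibition",
  "fig2d_stress_preG1S", "fig3_emi1_null", "fig4a_bifurcation_S",
  "fig4b_two_par_S_CKI", "fig5_cdh1_emi1_vs_cycE", "s3_myc_dependent",
  "s4_stress_postG1S", "s5_rb_threshold_sensitivity",
  "s6_cdh1_threshold_sensitivity", "mitotic_exit")

#' List the registered scenario presets
#' @return character vector of scenario names.
#' @export
list_scenarios <- function() .g0_scenario_names

# Wild-type reference: quiescent start at S = 0, stimulation with S = 1.
.wt_reference <- function(params, t_end = 100) {
  q <- find_quiescent_state(params, S = 0)
  tr <- run_timecourse(params, q, t_end = t_end, dt_out = 0.25)
  list(q = q, traj = tr, events = event_times(tr))
}

.check <- function(name, pass, value) {
  data.frame(check = name, pass = isTRUE(pass), value = as.numeric(value)[1])
}

# Myc-dependent (G2-shifted) transcriptional program used by the S3 and
# mitotic-exit presets.
.myc_program <- c(k_se2fm = 0.0015, k_scycem = 0.0005)

#' Mitotic-exit initial condition
#'
#' Rb hyper-phosphorylated, APC/C-Cdh1 fully active, Cyclin E:Cdk2 at an
#' intermediate level (between the Rb hyper-phosphorylation-maintenance
#' and Cdh1-inactivation thresholds), Emi1 low, no CKI. Myc is taken at its
#' mitogen-determined G2 level.
#'
#' @param params a [g0_parameters] object (its `S` sets the Myc level).
#' @param cdk2_init intermediate Cyclin E:Cdk2 activity (a.u.); free
#'   initial-condition parameter.
#' @param e2f_init residual free E2F after its S/G2 decline (a.u.).
#' @return named state vector.
#' @export
mitotic_exit_state <- function(params = default_parameters(),
                               cdk2_init = 0.15, e2f_init = 0.05) {
  params <- as_g0_parameters(params)
  make_state(
    RbPP = unname(params["Rb_total"]),
    Cdh1 = unname(params["Cdh1_total"]),
    CycE = cdk2_init, E2F = e2f_init,
    Myc = unname(params["k_smyc"] * params["S"] / params["k_dmyc"]),
    Ubl = unname(params["k_subl"] /
                   (params["k_dubl"] + params["k_dublc"] * params["Cdh1_total"])))
}

#' Run a named scenario
#'
#' Executes the scenario's computation, evaluates its qualitative checks,
#' and (optionally) writes trajectory/branch CSVs and a JSON check report.
#' Failed checks are reported, not fatal.
#'
#' @param name scenario name (see [list_scenarios()]).
#' @param params base parameter set.
#' @param out_dir if non-NULL, directory to write outputs into.
#' @param fast reduce grids for quicker (coarser) sensitivity scans.
#' @return list with `name`, `checks` (data frame: check, pass, value) and
#'   `outputs` (scenario-specific result objects).
#' @export
run_scenario <- function(name, params = default_parameters(),
                         out_dir = NULL, fast = FALSE) {
  name <- match.arg(name, .g0_scenario_names)
  res <- switch(name,
    fig2a_wildtype = .sc_fig2a(params),
    fig2b_no_cyclinD = .sc_fig2b(params),
    fig2c_cyclinD_inhibition = .sc_fig2c(params),
    fig2d_stress_preG1S = .sc_stress(params, after = FALSE),
    s4_stress_postG1S = .sc_stress(params, after = TRUE),
    fig3_emi1_null = .sc_fig3(params),
    fig4a_bifurcation_S = .sc_fig4a(params),
    fig4b_two_par_S_CKI = .sc_fig4b(params),
    fig5_cdh1_emi1_vs_cycE = .sc_fig5(params),
    s3_myc_dependent = .sc_s3(params),
    s5_rb_threshold_sensitivity = .sc_s5(params, fast),
    s6_cdh1_threshold_sensitivity = .sc_s6(params, fast),
    mitotic_exit = .sc_mitotic_exit(params))
  res$name <- name
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res$outputs)) {
      obj <- res$outputs[[nm]]
      fp <- file.path(out_dir, paste0(name, "_", nm, ".csv"))
      if (inherits(obj, "g0_trajectory")) write_trajectory(obj, fp)
      else if (inherits(obj, "g0_branch")) {
        utils::write.csv(obj$points, fp, row.names = FALSE)
      } else if (is.data.frame(obj)) utils::write.csv(obj, fp, row.names = FALSE)
    }
    jsonlite::write_json(
      list(name = name, checks = res$checks),
      file.path(out_dir, paste0(name, "_checks.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}

.sc_fig2a <- function(params) {
  ref <- .wt_reference(params)
  tr <- ref$traj; ev <- ref$events
  rbm <- tr$RbP + tr$RbPE2F
  t_rbm <- tr$time[which.max(rbm)]
  t_cycd <- tr$time[min(which(tr$CycD_total > 0.1 * max(tr$CycD_total)))]
  t_cki <- tr$time[min(which(tr$CKI_total_dyn < 0.5 * tr$CKI_total_dyn[1]))]
  checks <- rbind(
    .check("cycd_rise_before_rb_mono_peak", t_cycd < t_rbm, t_cycd),
    .check("rb_mono_peak_before_rb_hyper", t_rbm < ev[["Rb_hyper_half"]], t_rbm),
    .check("rb_hyper_before_emi1_rise",
           ev[["Rb_hyper_half"]] < ev[["Emi1_rise"]], ev[["Rb_hyper_half"]]),
    .check("emi1_rise_before_cdh1_inactivation",
           ev[["Emi1_rise"]] < ev[["Cdh1_inactivation"]], ev[["Emi1_rise"]]),
    .check("cdh1_inactivation_before_cki_collapse",
           ev[["Cdh1_inactivation"]] < t_cki, ev[["Cdh1_inactivation"]]),
    .check("cdh1_fully_inactivated",
           tr$Cdh1_active_fraction[nrow(tr)] < 0.1,
           tr$Cdh1_active_fraction[nrow(tr)]),
    .check("rb_hyperphosphorylated",
           tr$Rb_hyper_fraction[nrow(tr)] > 0.9,
           tr$Rb_hyper_fraction[nrow(tr)]))
  list(checks = checks, outputs = list(trajectory = tr), events = ev)
}

.sc_fig2b <- function(params) {
  ref <- .wt_reference(params)
  p2 <- set_parameters(params, c(k_scycdm = 0, k_scycds = 0))
  tr <- run_timecourse(p2, ref$q, t_end = 100, dt_out = 0.5)
  plateau_wt <- ref$traj$E2F_free[nrow(ref$traj)]
  plateau <- tr$E2F_free[nrow(tr)]
  checks <- .check("no_exit_without_cyclinD", plateau < 0.05 * plateau_wt,
                   plateau / plateau_wt)
  list(checks = checks, outputs = list(trajectory = tr))
}

.sc_fig2c <- function(params) {
  ref <- .wt_reference(params)
  tpl <- perturbation_templates()$cyclinD_inhibition
  t_late <- ref$events[["CycE_exceeds_CKI"]] + 1
  t_early <- 0.25 * ref$events[["Rb_hyper_half"]]
  thr <- 0.5 * ref$traj$E2F_free[nrow(ref$traj)]
  late <- run_timecourse(params, ref$q, t_end = 100,
    perturbations = list(perturbation(t_late, tpl)), dt_out = 0.5)
  early <- run_timecourse(params, ref$q, t_end = 100,
    perturbations = list(perturbation(t_early, tpl)), dt_out = 0.5)
  checks <- rbind(
    .check("no_effect_after_cyce_exceeds_cki",
           late$E2F_free[nrow(late)] > thr, late$E2F_free[nrow(late)]),
    .check("early_inhibition_blocks_exit",
           early$E2F_free[nrow(early)] < thr, early$E2F_free[nrow(early)]))
  list(checks = checks, outputs = list(late = late, early = early))
}

.sc_stress <- function(params, after) {
  ref <- .wt_reference(params)
  tci <- ref$events[["Cdh1_inactivation"]]
  t_app <- if (after) tci + 1 else ref$events[["Rb_hyper_half"]] + 1
  tr <- run_timecourse(params, ref$q, t_end = 100,
    perturbations = list(perturbation(t_app, c(k_scki = 0.6))), dt_out = 0.5)
  cdh1_end <- tr$Cdh1_active_fraction[nrow(tr)]
  checks <- if (after) {
    .check("stress_after_g1s_cannot_revert", cdh1_end < 0.1, cdh1_end)
  } else {
    rbind(
      .check("stress_before_g1s_reverts", cdh1_end > 0.9, cdh1_end),
      .check("rb_dephosphorylated_on_reversion",
             tr$Rb_hyper_fraction[nrow(tr)] < 0.1,
             tr$Rb_hyper_fraction[nrow(tr)]))
  }
  list(checks = checks, outputs = list(trajectory = tr), t_applied = t_app)
}

.sc_fig3 <- function(params) {
  ref <- .wt_reference(params)
  p3 <- set_parameters(params, c(k_semi1 = 0))
  solid <- run_timecourse(p3, ref$q, t_end = 100, dt_out = 0.5)
  t_inh <- 1.5 * ref$events[["Cdh1_inactivation"]]
  dashed <- run_timecourse(p3, ref$q, t_end = 100,
    perturbations = list(perturbation(t_inh,
      perturbation_templates()$cdk2_inhibition)), dt_out = 0.5)
  wt_end <- ref$traj$Cdh1_active_fraction[nrow(ref$traj)]
  # compare at the wild type's inactivation time: without Emi1 the decline
  # must lag behind the wild type
  i_tci <- which.min(abs(solid$time - ref$events[["Cdh1_inactivation"]]))
  checks <- rbind(
    .check("cdh1_inactivation_slowed_without_emi1",
           solid$Cdh1_active_fraction[i_tci] >
             ref$traj$Cdh1_active_fraction[
               which.min(abs(ref$traj$time - solid$time[i_tci]))] + 0.2,
           solid$Cdh1_active_fraction[i_tci]),
    .check("never_reaches_wildtype_terminal_level",
           min(solid$Cdh1_active_fraction) > wt_end + 0.1,
           min(solid$Cdh1_active_fraction)),
    .check("cdk2_inhibition_reactivates_cdh1",
           dashed$Cdh1_active_fraction[nrow(dashed)] > 0.5,
           dashed$Cdh1_active_fraction[nrow(dashed)]))
  list(checks = checks, outputs = list(solid = solid, dashed = dashed),
       t_inhibition = t_inh)
}

.sc_fig4a <- function(params) {
  q <- find_quiescent_state(params, S = 0)
  sys <- rb_e2f_subsystem(params)
  br <- continue_model_branch(sys, "S", p_range = c(-0.8, 3),
                              start = unname(q[sys$free]), p0 = 0,
                              direction = 1, h0 = 0.02, h_max = 0.08,
                              max_steps = 800)
  fa <- if (nrow(br$folds)) max(br$folds$p) else NA_real_
  fd <- if (nrow(br$folds)) min(br$folds$p) else NA_real_
  checks <- rbind(
    .check("bistable_window_at_low_intermediate_S",
           is.finite(fa) && fa > 0.02 && fa < 1, fa),
    .check("no_deactivation_fold_at_positive_S",
           is.finite(fd) && fd <= 0, fd),
    .check("monostable_high_E2F_at_S1",
           sum(abs(br$points$p - 1) < 0.05 & br$points$stability == "stable") > 0 &&
             !any(abs(br$points$p - 1) < 0.05 & br$points$E2F < 0.1), fa))
  list(checks = checks, outputs = list(branch = br),
       S_act = fa, S_deact = fd)
}

.sc_fig4b <- function(params) {
  f4 <- .sc_fig4a(params)
  br <- f4$outputs$branch
  sys <- rb_e2f_subsystem(params)
  fa_row <- br$folds[which.max(br$folds$p), ]
  f2 <- function(x, p1, p2) {
    pset <- unclass(as_g0_parameters(params))
    pset[["S"]] <- p1; pset[["CKI_total"]] <- p2
    sys$f(x, sys$clamp, pset)
  }
  base_cki <- as_g0_parameters(params)[["CKI_total"]]
  x_fold <- as.numeric(fa_row[-1])
  down <- track_fold_2par(f2, x_fold, fa_row$p, base_cki,
                          c(0.35, 0.2, 0.1, 0.05, 0.02))
  up <- track_fold_2par(f2, x_fold, fa_row$p, base_cki, c(0.75, 1, 1.5, 2))
  wedge <- rbind(
    data.frame(CKI_total = rev(down$p2), S_act = rev(down$p1)),
    data.frame(CKI_total = base_cki, S_act = fa_row$p),
    data.frame(CKI_total = up$p2, S_act = up$p1))
  corner <- wedge$S_act[1]
  checks <- rbind(
    .check("bistable_extent_grows_with_cki", all(diff(wedge$S_act) > 0),
           max(wedge$S_act)),
    .check("near_zero_cki_bistable_only_at_very_low_S",
           nrow(down) == 5 && corner > 0 && corner < 0.05, corner))
  list(checks = checks, outputs = list(wedge = wedge), wedge = wedge)
}

.sc_fig5 <- function(params) {
  sys <- cdh1_emi1_subsystem(params, cyce = 0)
  eq <- find_equilibria_bruteforce(sys = sys, n_starts = 200, seed = 3)
  stab <- vapply(eq, function(e) e$stability, "")
  cd <- vapply(eq, function(e) e$state[["Cdh1"]], 1)
  on <- eq[[which.max(cd)]]
  off <- eq[[which.min(replace(cd, stab != "stable", Inf))]]
  br_on <- continue_model_branch(sys, "CycE", p_range = c(-0.05, 1.5),
                                 start = on$x, p0 = 0, direction = 1,
                                 h0 = 0.01, h_max = 0.05, max_steps = 600)
  br_off <- continue_model_branch(sys, "CycE", p_range = c(-0.01, 1.5),
                                  start = off$x, p0 = 0, direction = 1,
                                  h0 = 0.02, h_max = 0.08, max_steps = 400)
  cyce_star <- if (nrow(br_on$folds)) max(br_on$folds$p) else NA_real_
  off_stable_everywhere <- all(br_off$points$stability == "stable")
  checks <- rbind(
    .check("bistable_at_zero_cyce",
           sum(stab == "stable") == 2 && max(cd) > 0.5 &&
             min(cd[stab == "stable"]) < 0.1, sum(stab == "stable")),
    .check("cyce_initiates_inactivation_at_fold",
           is.finite(cyce_star) && cyce_star > 0.05, cyce_star),
    .check("inactive_branch_persists_to_zero_cyce",
           off_stable_everywhere && min(br_off$points$p) <= 0 &&
             all(br_off$points$Cdh1 < 0.1), min(br_off$points$Cdh1)))
  list(checks = checks, outputs = list(on_branch = br_on, off_branch = br_off),
       cyce_threshold = cyce_star)
}

.sc_s3 <- function(params) {
  ref <- .wt_reference(params)
  p3 <- set_parameters(params, c(c(k_scycdm = 0, k_scycds = 0), .myc_program))
  tr <- run_timecourse(p3, ref$q, t_end = 300, dt_out = 1)
  ev <- event_times(tr)
  e2f_wt <- ref$traj$E2F_free[nrow(ref$traj)]
  # free E2F lags total E2F: compare times at which each reaches half of
  # its own plateau
  t_half <- function(x) {
    plateau <- x[length(x)]
    tr$time[min(which(x > 0.5 * plateau))]
  }
  checks <- rbind(
    .check("exit_without_cyclinD", tr$E2F_free[nrow(tr)] > 0.5 * e2f_wt,
           tr$E2F_free[nrow(tr)]),
    .check("exit_delayed_vs_wildtype",
           ev[["Rb_hyper_half"]] > ref$events[["Rb_hyper_half"]] + 2,
           ev[["Rb_hyper_half"]]),
    .check("free_e2f_lags_total_e2f",
           t_half(tr$E2F_free) > t_half(tr$E2F_total), t_half(tr$E2F_free)))
  list(checks = checks, outputs = list(trajectory = tr), events = ev)
}

.sc_s5 <- function(params, fast = FALSE) {
  q <- find_quiescent_state(params, S = 0)
  sys <- rb_e2f_subsystem(params)
  br <- continue_model_branch(sys, "S", p_range = c(-0.8, 3),
                              start = unname(q[sys$free]), p0 = 0,
                              direction = 1, h0 = 0.02, h_max = 0.08,
                              max_steps = 800, stability = FALSE)
  fa <- br$folds[which.max(br$folds$p), ]
  fd <- br$folds[which.min(br$folds$p), ]
  named5 <- c("k_scyceb", "k_dcyce", "k_se2fb", "k_de2f", "Rb_total")
  gradual <- c("CKI_total", "k_dcycd")
  sens <- threshold_sensitivity(sys, "S", as.numeric(fa[-1]), fa$p,
                                param_list = c(named5, gradual),
                                n_grid = if (fast) 3 else 6)
  st <- sensitivity_steepness(sens)
  # k_dprbp acts on the opposite (activation->inactivation) threshold
  fdp <- function(x, p1, p2) {
    pset <- unclass(as_g0_parameters(params))
    pset[["S"]] <- p1; pset[["k_dprbp"]] <- p2
    sys$f(x, sys$clamp, pset)
  }
  base <- as_g0_parameters(params)[["k_dprbp"]]
  trp <- track_fold_2par(fdp, as.numeric(fd[-1]), fd$p, base,
                         base * c(2, 3.5, 5))
  checks <- rbind(
    .check("cyce_e2f_rb_parameters_steepest",
           min(st[named5]) > max(st[gradual]), min(st[named5])),
    .check("k_dprbp_increase_brings_mitogen_dependence",
           nrow(trp) >= 1 && max(trp$p1) > 0, suppressWarnings(max(trp$p1))))
  list(checks = checks, outputs = list(sensitivity = sens),
       steepness = st, dprbp_fold = trp)
}

.sc_s6 <- function(params, fast = FALSE) {
  f5 <- .sc_fig5(params)
  sys <- cdh1_emi1_subsystem(params, cyce = 0)
  br <- f5$outputs$on_branch
  fa <- br$folds[which.max(br$folds$p), ]
  steep2 <- c("k_semi1", "k_demi1c")
  gradual2 <- c("k_acdh1", "k_icdh1e")
  sens <- threshold_sensitivity(sys, "CycE", as.numeric(fa[-1]), fa$p,
                                param_list = c(steep2, gradual2),
                                n_grid = if (fast) 3 else 6)
  st <- sensitivity_steepness(sens)
  checks <- .check("emi1_turnover_steepest_for_cdh1_threshold",
                   min(st[steep2]) > max(st[gradual2]), min(st[steep2]))
  list(checks = checks, outputs = list(sensitivity = sens), steepness = st)
}

.sc_mitotic_exit <- function(params) {
  pme <- set_parameters(params, .myc_program)
  run_one <- function(Sv) {
    pp <- set_parameters(pme, c(S = Sv))
    run_timecourse(pp, mitotic_exit_state(pp), t_end = 100, dt_out = 0.5)
  }
  tr1 <- run_one(1)
  tr0 <- run_one(0)
  t_inact <- event_times(tr1)[["Cdh1_inactivation"]]
  checks <- rbind(
    .check("with_mitogen_immediate_commitment",
           is.finite(t_inact) && t_inact < 8 &&
             tr1$Cdh1_active_fraction[nrow(tr1)] < 0.1, t_inact),
    .check("without_mitogen_enters_quiescence",
           tr0$Cdh1_active_fraction[nrow(tr0)] > 0.9 &&
             tr0$E2F_free[nrow(tr0)] < 0.05,
           tr0$Cdh1_active_fraction[nrow(tr0)]))
  list(checks = checks, outputs = list(with_mitogen = tr1,
                                       without_mitogen = tr0))
}
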