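#' Dynamic species of the model
#'
#' The state vector tracks every free protein form and every stoichiometric
#' complex explicitly (no rapid-equilibrium reduction):
#'
#' \describe{
#'   \item{Myc}{Myc transcription-factor activity.}
#'   \item{CycD, CycDCKI}{free Cyclin D:Cdk4/6 and its CKI complex.}
#'   \item{CycE, CycECKI}{free Cyclin E:Cdk2 and its CKI complex.}
#'   \item{CycA, CycACKI}{free Cyclin A:Cdk2 and its CKI complex.}
#'   \item{CKI}{free Cdk inhibitor (p21/p27 lumped).}
#'   \item{E2F}{free (transcriptionally active) E2F.}
#'   \item{Rb, RbP, RbPP}{free un-, mono- and hyper-phosphorylated Rb.
#'     Only the hyper-phosphorylated form has released E2F.}
#'   \item{RbE2F, RbPE2F}{E2F bound to un-/mono-phosphorylated Rb
#'     (both complexes inhibit E2F).}
#'   \item{Cdh1, Cdh1P}{active and phosphorylated (inactive) APC/C-Cdh1.}
#'   \item{Emi1, Emi1Cdh1}{free Emi1 and its stoichiometric inhibitory
#'     complex with active Cdh1.}
#'   \item{Ubl}{lumped SCF-Skp2/CRL4-Cdt2 ubiquitin-ligase activity.}
#' }
#'
#' Conserved moieties (constant totals): Rb = Rb + RbP + RbPP + RbE2F +
#' RbPE2F; Cdh1 = Cdh1 + Cdh1P + Emi1Cdh1. The CKI moiety (CKI + the three
#' cyclin-bound pools) is conserved only when its synthesis and degradation
#' are frozen, as in the Rb-E2F subsystem analysis.
#'
#' @return character vector of species names, in state-vector order.
#' @export
species_names <- function() {
  c("Myc", "CycD", "CycDCKI", "CycE", "CycECKI", "CycA", "CycACKI",
    "CKI", "E2F", "Rb", "RbP", "RbPP", "RbE2F", "RbPE2F",
    "Cdh1", "Cdh1P", "Emi1", "Emi1Cdh1", "Ubl")
}

# Tolerance below which a (numerically) negative concentration is clipped
# rather than rejected.
.g0_neg_tol <- 1e-6

as_state <- function(state) {
  sp <- species_names()
  if (is.null(names(state))) {
    if (length(state) != length(sp)) stop("state has wrong length")
    names(state) <- sp
    return(state)
  }
  missing <- setdiff(sp, names(state))
  if (length(missing)) stop("state missing species: ",
                            paste(missing, collapse = ", "))
  extra <- setdiff(names(state), sp)
  if (length(extra)) stop("unknown species: ", paste(extra, collapse = ", "))
  state[sp]
}

check_state <- function(state, tol = .g0_neg_tol) {
  state <- as_state(state)
  if (any(state < -tol)) {
    stop("negative concentration beyond tolerance: ",
         paste(names(state)[state < -tol], collapse = ", "))
  }
  pmax(state, 0)
}

#' Build a state vector
#'
#' Unspecified species are zero.
#'
#' @param ... named species concentrations (a.u.).
#' @return named numeric state vector.
#' @examples
#' st <- make_state(Rb = 1.5, Cdh1 = 1, CKI = 0.5)
#' @export
make_state <- function(...) {
  v <- c(...)
  st <- stats::setNames(numeric(length(species_names())), species_names())
  if (length(v)) {
    bad <- setdiff(names(v), species_names())
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    st[names(v)] <- v
  }
  st
}

#' Right-hand side of the model ODEs
#'
#' Kinetic forms: multi-site (de)phosphorylation of Rb and Cdh1 follow
#' Michaelis-Menten kinetics; E2F-dependent synthesis of Cyclin E, Cyclin A,
#' Emi1 and E2F itself follows a Hill function with n = 1 in free E2F; all
#' remaining reactions are mass action. Cyclin E:Cdk2 and Cyclin A:Cdk2
#' kinase activities are the free (CKI-unbound) complex concentrations times
#' the activity multiplier `e_cdk2`.
#'
#' @param state named numeric state vector (see [species_names()]).
#' @param t time in hours (the system is autonomous; `t` is accepted for
#'   solver compatibility and ignored).
#' @param params a [g0_parameters] object or named numeric vector.
#' @param check validate non-negativity of `state` (default TRUE; the
#'   integrator-facing internal path skips it).
#' @return named numeric vector of time derivatives d(state)/dt, in a.u./h.
#' @export
g0_rhs <- function(state, t = 0, params = default_parameters(), check = TRUE) {
  params <- as_g0_parameters(params)
  state <- if (check) check_state(state) else as_state(state)
  .g0_rhs_raw(state, params)
}

# Unchecked core used by integrators and Newton iterations. `state` must be
# a full named vector in canonical order; `p` a full parameter vector.
.g0_rhs_raw <- function(state, p) {
  s <- state
  mm <- function(x, J) x / (J + x)

  VD <- s[["CycD"]]                               # Cdk4/6 activity
  VE <- p[["e_cdk2"]] * s[["CycE"]]               # Cyclin E:Cdk2 activity
  VA <- p[["e_cdk2"]] * s[["CycA"]]               # Cyclin A:Cdk2 activity
  hE <- s[["E2F"]] / (p[["J_e2f"]] + s[["E2F"]])  # Hill, n = 1

  dcki  <- p[["k_dcki"]] + p[["k_dckiu"]] * s[["Ubl"]] * (VE + VA)
  ddE   <- p[["k_dcyce"]] + p[["k_dcycea"]] * VA
  ddA   <- p[["k_dcyca"]] + p[["k_dcycac"]] * s[["Cdh1"]]
  dde2f <- p[["k_de2f"]] + p[["k_de2fa"]] * VA
  # Emi1 is an APC/C-Cdh1 substrate: free active Cdh1 degrades both free
  # and Cdh1-bound Emi1 (degradation of complexed Emi1 releases active
  # Cdh1). Together with stoichiometric sequestration this yields the
  # double-negative Emi1/Cdh1 feedback: abundant Emi1 buries the activity
  # that would destroy it.
  demi  <- p[["k_demi1"]] + p[["k_demi1c"]] * s[["Cdh1"]]

  ## Rb phosphorylation fluxes (Michaelis-Menten in the substrate)
  pm_R   <- p[["k_pprbd"]] * VD * mm(s[["Rb"]],     p[["J_prb"]])
  pm_RE  <- p[["k_pprbd"]] * VD * mm(s[["RbE2F"]],  p[["J_prb"]])
  ph_RP  <- p[["k_pprbe"]] * (VE + VA) * mm(s[["RbP"]],    p[["J_prb"]])
  ph_RPE <- p[["k_pprbe"]] * (VE + VA) * mm(s[["RbPE2F"]], p[["J_prb"]])
  pu_R   <- p[["k_pprbue"]] * (VE + VA) * mm(s[["Rb"]],    p[["J_prb"]])
  pu_RE  <- p[["k_pprbue"]] * (VE + VA) * mm(s[["RbE2F"]], p[["J_prb"]])
  dp_RPP <- p[["k_dprbp"]] * mm(s[["RbPP"]],   p[["J_dprb"]])
  dp_RP  <- p[["k_dprbp"]] * mm(s[["RbP"]],    p[["J_dprb"]])
  dp_RPE <- p[["k_dprbp"]] * mm(s[["RbPE2F"]], p[["J_dprb"]])

  ## Cdh1 (de)phosphorylation fluxes
  a_cdh1 <- p[["k_acdh1"]] * mm(s[["Cdh1P"]], p[["J_acdh1"]])
  i_cdh1 <- (p[["k_icdh1e"]] * VE + p[["k_icdh1a"]] * VA) *
    mm(s[["Cdh1"]], p[["J_icdh1"]])

  ## CKI binding fluxes
  b_cd <- p[["k_ascd"]] * s[["CycD"]] * s[["CKI"]] - p[["k_dscd"]] * s[["CycDCKI"]]
  b_ce <- p[["k_asce"]] * s[["CycE"]] * s[["CKI"]] - p[["k_dsce"]] * s[["CycECKI"]]
  b_ca <- p[["k_asca"]] * s[["CycA"]] * s[["CKI"]] - p[["k_dsca"]] * s[["CycACKI"]]
  ## Rb:E2F binding fluxes
  b_re  <- p[["k_asre"]] * s[["E2F"]] * s[["Rb"]]  - p[["k_dsre"]] * s[["RbE2F"]]
  b_rpe <- p[["k_asre"]] * s[["E2F"]] * s[["RbP"]] - p[["k_dsre"]] * s[["RbPE2F"]]
  ## Emi1:Cdh1 binding flux
  b_ec <- p[["k_asec"]] * s[["Emi1"]] * s[["Cdh1"]] - p[["k_dsec"]] * s[["Emi1Cdh1"]]

  d <- numeric(length(s))
  names(d) <- names(s)

  d[["Myc"]] <- p[["k_smyc"]] * p[["S"]] - p[["k_dmyc"]] * s[["Myc"]]

  d[["CycD"]] <- p[["k_scycds"]] * p[["S"]] + p[["k_scycdm"]] * s[["Myc"]] -
    p[["k_dcycd"]] * s[["CycD"]] - b_cd + dcki * s[["CycDCKI"]]
  d[["CycDCKI"]] <- b_cd - (p[["k_dcycd"]] + dcki) * s[["CycDCKI"]]

  d[["CycE"]] <- p[["k_scyceb"]] + p[["k_scyce"]] * hE +
    p[["k_scycem"]] * s[["Myc"]] - ddE * s[["CycE"]] - b_ce +
    dcki * s[["CycECKI"]]
  d[["CycECKI"]] <- b_ce - (ddE + dcki) * s[["CycECKI"]]

  d[["CycA"]] <- p[["k_scyca"]] * hE - ddA * s[["CycA"]] - b_ca +
    dcki * s[["CycACKI"]]
  d[["CycACKI"]] <- b_ca - (ddA + dcki) * s[["CycACKI"]]

  d[["CKI"]] <- p[["k_scki"]] - dcki * s[["CKI"]] -
    b_cd - b_ce - b_ca +
    p[["k_dcycd"]] * s[["CycDCKI"]] + ddE * s[["CycECKI"]] +
    ddA * s[["CycACKI"]]

  d[["E2F"]] <- p[["k_se2fb"]] + p[["k_se2f"]] * hE +
    p[["k_se2fm"]] * s[["Myc"]] - dde2f * s[["E2F"]] -
    b_re - b_rpe + ph_RPE + pu_RE

  d[["Rb"]]  <- -pm_R - pu_R + dp_RP - b_re + dde2f * s[["RbE2F"]]
  d[["RbP"]] <- pm_R - ph_RP + dp_RPP - dp_RP - b_rpe + dde2f * s[["RbPE2F"]]
  d[["RbPP"]] <- ph_RP + pu_R + ph_RPE + pu_RE - dp_RPP
  d[["RbE2F"]]  <- b_re - pm_RE - pu_RE + dp_RPE - dde2f * s[["RbE2F"]]
  d[["RbPE2F"]] <- b_rpe + pm_RE - ph_RPE - dp_RPE - dde2f * s[["RbPE2F"]]

  d[["Cdh1"]]  <- a_cdh1 - i_cdh1 - b_ec + demi * s[["Emi1Cdh1"]]
  d[["Cdh1P"]] <- i_cdh1 - a_cdh1
  d[["Emi1"]]  <- p[["k_semi1"]] * hE - demi * s[["Emi1"]] - b_ec
  d[["Emi1Cdh1"]] <- b_ec - demi * s[["Emi1Cdh1"]]

  d[["Ubl"]] <- p[["k_subl"]] -
    (p[["k_dubl"]] + p[["k_dublc"]] * s[["Cdh1"]]) * s[["Ubl"]]

  d
}

#' Conserved-moiety sums
#'
#' @param state named numeric state vector.
#' @param params parameter set (used only for the reference totals in the
#'   attribute `expected`).
#' @return named numeric vector with components `Rb_sum`, `CKI_sum`,
#'   `Cdh1_sum`; attribute `expected` carries the corresponding totals from
#'   `params`.
#' @export
conserved_moieties <- function(state, params = default_parameters()) {
  params <- as_g0_parameters(params)
  s <- as_state(state)
  out <- c(
    Rb_sum   = unname(s["Rb"] + s["RbP"] + s["RbPP"] + s["RbE2F"] + s["RbPE2F"]),
    CKI_sum  = unname(s["CKI"] + s["CycDCKI"] + s["CycECKI"] + s["CycACKI"]),
    Cdh1_sum = unname(s["Cdh1"] + s["Cdh1P"] + s["Emi1Cdh1"])
  )
  attr(out, "expected") <- c(Rb_sum = unname(params["Rb_total"]),
                             CKI_sum = unname(params["CKI_total"]),
                             Cdh1_sum = unname(params["Cdh1_total"]))
  out
}

#' Derived observables at one state
#'
#' @param state named numeric state vector.
#' @param params parameter set (totals and `e_cdk2`).
#' @return named numeric vector: `E2F_total`, `E2F_free`,
#'   `CycE_Cdk2_activity` (CKI-free Cyclin E:Cdk2 times `e_cdk2`),
#'   `CycA_Cdk2_activity`, `Cdh1_active_fraction`, `Rb_hyper_fraction`,
#'   `CycE_total`, `CycD_total`, `CKI_total_dyn`, `Emi1_total`.
#' @export
g0_observables <- function(state, params = default_parameters()) {
  params <- as_g0_parameters(params)
  s <- as_state(state)
  cd_tot <- unname(params["Cdh1_total"])
  rb_tot <- unname(params["Rb_total"])
  c(
    E2F_total = unname(s["E2F"] + s["RbE2F"] + s["RbPE2F"]),
    E2F_free = unname(s["E2F"]),
    CycE_Cdk2_activity = unname(params["e_cdk2"] * s["CycE"]),
    CycA_Cdk2_activity = unname(params["e_cdk2"] * s["CycA"]),
    Cdh1_active_fraction = unname(s["Cdh1"]) / cd_tot,
    Rb_hyper_fraction = unname(s["RbPP"]) / rb_tot,
    CycE_total = unname(s["CycE"] + s["CycECKI"]),
    CycD_total = unname(s["CycD"] + s["CycDCKI"]),
    CKI_total_dyn = unname(s["CKI"] + s["CycDCKI"] + s["CycECKI"] + s["CycACKI"]),
    Emi1_total = unname(s["Emi1"] + s["Emi1Cdh1"])
  )
}

#' Names of the derived observables
#' @return character vector.
#' @export
observable_names <- function() {
  c("E2F_total", "E2F_free", "CycE_Cdk2_activity", "CycA_Cdk2_activity",
    "Cdh1_active_fraction", "Rb_hyper_fraction", "CycE_total", "CycD_total",
    "CKI_total_dyn", "Emi1_total")
}
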