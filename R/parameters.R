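#' Model parameter set
#'
#' A `g0_parameters` object is a named numeric vector holding every rate
#' constant, Michaelis constant and total concentration of the
#' quiescence-proliferation model, plus the mitogen level `S`.
#'
#' Units: concentrations and totals in arbitrary units (a.u.), first-order
#' rate constants in 1/h, bimolecular (association) constants in 1/(a.u. h),
#' Michaelis constants in a.u., `S` and `e_cdk2` dimensionless. E2F-dependent
#' synthesis terms use a Hill function with coefficient n = 1 throughout.
#'
#' @section Parameter groups:
#' \describe{
#'   \item{Myc}{`k_smyc` (mitogen-driven synthesis), `k_dmyc` (turnover).}
#'   \item{Cyclin D:Cdk4/6}{`k_scycds` (mitogen-dependent synthesis),
#'     `k_scycdm` (Myc-dependent synthesis), `k_dcycd` (degradation).}
#'   \item{Cyclin E:Cdk2}{`k_scyceb` (basal), `k_scyce` (E2F-dependent),
#'     `k_scycem` (Myc-dependent, 0 by default), `k_dcyce` (basal
#'     degradation), `k_dcycea` (Cyclin A:Cdk2-promoted degradation).}
#'   \item{Cyclin A:Cdk2}{`k_scyca` (E2F-dependent synthesis), `k_dcyca`
#'     (basal degradation), `k_dcycac` (APC/C-Cdh1-mediated degradation).}
#'   \item{E2F}{`k_se2fb` (basal), `k_se2f` (autoregulatory), `k_se2fm`
#'     (Myc-dependent, 0 by default), `k_de2f` (basal degradation),
#'     `k_de2fa` (Cyclin A-promoted degradation), `J_e2f` (half-saturation
#'     of all E2F-dependent synthesis terms).}
#'   \item{CKI}{`k_scki` (synthesis; raised by stress), `k_dcki` (basal
#'     degradation), `k_dckiu` (Ubl- and Cdk2-dependent degradation).}
#'   \item{Emi1}{`k_semi1` (E2F-dependent synthesis), `k_demi1` (basal
#'     degradation), `k_demi1c` (degradation by free active Cdh1, acting on
#'     both free and Cdh1-bound Emi1).}
#'   \item{Ubl}{`k_subl`, `k_dubl`, `k_dublc` (Cdh1-mediated degradation)
#'     for the lumped SCF-Skp2/CRL4-Cdt2 ubiquitin-ligase activity.}
#'   \item{APC/C-Cdh1}{`k_acdh1` (activation), `k_icdh1e`
#'     (Cyclin E:Cdk2-mediated inactivation), `k_icdh1a` (Cyclin A:Cdk2
#'     weight), `J_acdh1`, `J_icdh1` (Michaelis constants).}
#'   \item{Rb phosphorylation}{`k_pprbd` (Cyclin D-mediated
#'     mono-phosphorylation), `k_pprbe` (Cdk2-mediated mono-to-hyper
#'     conversion), `k_pprbue` (direct hyper-phosphorylation of
#'     un-phosphorylated Rb), `k_dprbp` (dephosphorylation), `J_prb`,
#'     `J_dprb` (Michaelis constants).}
#'   \item{Complex formation}{`k_asre`/`k_dsre` (Rb:E2F), `k_ascd`/`k_dscd`,
#'     `k_asce`/`k_dsce`, `k_asca`/`k_dsca` (CKI with the three cyclin:Cdk
#'     complexes), `k_asec`/`k_dsec` (Emi1:Cdh1).}
#'   \item{Totals and inputs}{`Rb_total`, `CKI_total`, `Cdh1_total`, mitogen
#'     level `S`, Cdk2 activity multiplier `e_cdk2` (1 = full activity; the
#'     Cdk2-inhibition preset sets it to 0).}
#' }
#'
#' @param values named numeric vector; must contain exactly the model's
#'   parameter names (see [default_parameters()]).
#' @return object of class `g0_parameters`.
#' @seealso [default_parameters()], [load_parameters()]
#' @export
g0_parameters <- function(values) {
  if (is.list(values)) values <- unlist(values)
  if (!is.numeric(values) || is.null(names(values))) {
    stop("parameters must be a named numeric vector")
  }
  ref <- names(.g0_default_values())
  missing <- setdiff(ref, names(values))
  extra <- setdiff(names(values), ref)
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  }
  values <- values[ref]
  validate_parameters(values)
  structure(values, class = "g0_parameters")
}

# Single source of the default table. Calibrated so that the default model
# reproduces the canonical behaviours: stable quiescence at S = 0, the
# wild-type stimulation event order at S = 1, commitment at Cdh1
# inactivation, and the hysteresis structure of the two switches.
.g0_default_values <- function() {
  c(
    ## mitogen input and Myc
    S        = 1,
    k_smyc   = 25,    k_dmyc  = 0.5,
    ## Cyclin D:Cdk4/6
    k_scycds = 0.04,  k_scycdm = 0.002, k_dcycd = 0.05,
    ## Cyclin E:Cdk2
    k_scyceb = 0.013, k_scyce = 0.15,  k_scycem = 0,
    k_dcyce  = 0.2,   k_dcycea = 0.5,
    ## Cyclin A:Cdk2
    k_scyca  = 0.15,  k_dcyca = 0.1,   k_dcycac = 1.5,
    ## E2F
    k_se2fb  = 0.08,  k_se2f = 0.05,   k_se2fm = 0,
    k_de2f   = 0.1,   k_de2fa = 0.1,   J_e2f = 0.1,
    ## CKI (p21/p27 lumped)
    k_scki   = 0.075, k_dcki = 0.15,   k_dckiu = 3,
    ## Emi1
    k_semi1  = 0.9,   k_demi1 = 0.26,  k_demi1c = 3.4,
    ## Ubl (SCF-Skp2 / CRL4-Cdt2 lumped)
    k_subl   = 2,     k_dubl = 2,      k_dublc = 50,
    ## APC/C-Cdh1
    k_acdh1  = 0.6,   J_acdh1 = 0.3,
    k_icdh1e = 1.3,   k_icdh1a = 0.3,  J_icdh1 = 0.3,
    ## Rb phosphorylation
    k_pprbd  = 2,     k_pprbe = 2,     k_pprbue = 0.35,
    k_dprbp  = 0.2,   J_prb = 0.5,     J_dprb = 0.5,
    ## complex formation / dissociation
    k_asre   = 100,   k_dsre = 0.1,
    k_ascd   = 50,    k_dscd = 0.5,
    k_asce   = 50,    k_dsce = 0.5,
    k_asca   = 50,    k_dsca = 0.5,
    k_asec   = 50,    k_dsec = 0.5,
    ## Cdk2 activity multiplier (inhibition handle)
    e_cdk2   = 1,
    ## conserved totals
    Rb_total = 1.5,   CKI_total = 0.5, Cdh1_total = 1
  )
}

#' Default parameter set
#'
#' Returns the model's default parameter table. Values printed in the model's
#' perturbation presets (for example the stress value `k_scki = 0.6`, Cyclin D
#' clearance `k_dcycd = 0.1`, or the Myc-dependent synthesis rates
#' `k_se2fm = 0.0015`, `k_scycem = 0.0005`) are applied as overrides on top of
#' these defaults by the scenario machinery, not stored here.
#'
#' @param overrides optional named numeric vector of parameter overrides.
#' @return a [g0_parameters] object.
#' @examples
#' p <- default_parameters()
#' p["S"]
#' p_stress <- default_parameters(c(k_scki = 0.6))
#' @export
default_parameters <- function(overrides = NULL) {
  v <- .g0_default_values()
  if (!is.null(overrides)) {
    if (is.list(overrides)) overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), names(v))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    v[names(overrides)] <- overrides
  }
  g0_parameters(v)
}

# Invariants: non-negative rates and totals, strictly positive Michaelis
# constants. Hill coefficient is structurally 1 (no parameter).
validate_parameters <- function(v) {
  if (any(!is.finite(v))) {
    stop("non-finite parameter value(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  }
  if (any(v < 0)) {
    stop("negative parameter value(s): ",
         paste(names(v)[v < 0], collapse = ", "))
  }
  km <- c("J_e2f", "J_acdh1", "J_icdh1", "J_prb", "J_dprb")
  if (any(v[km] <= 0)) {
    stop("Michaelis constant(s) must be > 0: ",
         paste(km[v[km] <= 0], collapse = ", "))
  }
  invisible(v)
}

#' Apply named overrides to a parameter set
#'
#' @param params a [g0_parameters] object.
#' @param overrides named numeric vector; every name must be a known
#'   parameter (unknown keys are rejected).
#' @return a new [g0_parameters] object.
#' @export
set_parameters <- function(params, overrides) {
  params <- as_g0_parameters(params)
  if (is.list(overrides)) overrides <- unlist(overrides)
  if (length(overrides) == 0) return(params)
  bad <- setdiff(names(overrides), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  v <- unclass(params)
  v[names(overrides)] <- overrides
  g0_parameters(v)
}

as_g0_parameters <- function(x) {
  if (inherits(x, "g0_parameters")) return(x)
  g0_parameters(x)
}

#' @export
print.g0_parameters <- function(x, ...) {
  cat("<g0_parameters> ", length(x), " parameters (a.u., 1/h)\n", sep = "")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}
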