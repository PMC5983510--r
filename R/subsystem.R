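#' Clamped / reduced dynamical systems
#'
#' Equilibrium and continuation work is carried out on a *reduced* system in
#' which (i) an arbitrary set of species can be clamped to constant values
#' and treated as parameters, and (ii) one member of each structurally
#' conserved family (`RbPP` for the Rb moiety, `Cdh1P` for the Cdh1 moiety,
#' and `CKI` when CKI turnover is frozen) is eliminated through its
#' conservation law. Elimination removes the zero eigenvalues the
#' conservation laws would otherwise contribute, so that stability can be
#' read off the reduced Jacobian.
#'
#' @param params a [g0_parameters] object.
#' @param clamp named numeric vector of species held constant (a
#'   "ClampSpec"), or NULL.
#' @param conserve_cki freeze CKI synthesis/degradation and treat the CKI
#'   moiety as conserved at `CKI_total` (used by the Rb-E2F subsystem
#'   analysis, where total CKI is a bifurcation axis).
#' @return an object of class `g0_system` with elements `free` (free species
#'   names), `clamp`, `eliminated`, `params`, and function members
#'   `reconstruct(x)`, `f(x)`, `with_param(name)`.
#' @export
make_system <- function(params, clamp = NULL, conserve_cki = FALSE) {
  params <- as_g0_parameters(params)
  sp <- species_names()
  if (!is.null(clamp)) {
    if (is.list(clamp)) clamp <- unlist(clamp)
    bad <- setdiff(names(clamp), sp)
    if (length(bad)) stop("unknown clamped species: ", paste(bad, collapse = ", "))
  } else {
    clamp <- stats::setNames(numeric(0), character(0))
  }
  if (conserve_cki) {
    params <- set_parameters(params, c(k_scki = 0, k_dcki = 0, k_dckiu = 0))
  }

  rb_family <- c("Rb", "RbP", "RbPP", "RbE2F", "RbPE2F")
  cdh1_family <- c("Cdh1", "Cdh1P", "Emi1Cdh1")
  cki_family <- c("CKI", "CycDCKI", "CycECKI", "CycACKI")

  eliminated <- character(0)
  if (!any(rb_family %in% names(clamp))) eliminated <- c(eliminated, "RbPP")
  if (!any(cdh1_family %in% names(clamp))) eliminated <- c(eliminated, "Cdh1P")
  if (conserve_cki && !any(cki_family %in% names(clamp))) {
    eliminated <- c(eliminated, "CKI")
  }

  free <- setdiff(sp, c(names(clamp), eliminated))

  reconstruct <- function(x, clamp_values = clamp, pset = params) {
    st <- stats::setNames(numeric(length(sp)), sp)
    st[free] <- x
    if (length(clamp_values)) st[names(clamp_values)] <- clamp_values
    if ("RbPP" %in% eliminated) {
      st["RbPP"] <- pset[["Rb_total"]] -
        (st["Rb"] + st["RbP"] + st["RbE2F"] + st["RbPE2F"])
    }
    if ("Cdh1P" %in% eliminated) {
      st["Cdh1P"] <- pset[["Cdh1_total"]] - st["Cdh1"] - st["Emi1Cdh1"]
    }
    if ("CKI" %in% eliminated) {
      st["CKI"] <- pset[["CKI_total"]] -
        (st["CycDCKI"] + st["CycECKI"] + st["CycACKI"])
    }
    st
  }

  f <- function(x, clamp_values = clamp, pset = params) {
    st <- reconstruct(x, clamp_values, pset)
    d <- .g0_rhs_raw(st, pset)
    unname(d[free])
  }

  # Returns f(x, v) with parameter `name` (a ParameterSet key or a clamped
  # species) set to v. Used by continuation; skips re-validation so that
  # branches may be continued through (unphysical) negative parameter
  # values, e.g. to show that a deactivation fold lies at S < 0.
  with_param <- function(name) {
    if (name %in% names(params)) {
      function(x, v) {
        pset <- unclass(params)
        pset[[name]] <- v
        f(x, clamp, pset)
      }
    } else if (name %in% names(clamp)) {
      function(x, v) {
        cl <- clamp
        cl[[name]] <- v
        f(x, cl, params)
      }
    } else {
      stop("free parameter '", name,
           "' is neither a model parameter nor a clamped species")
    }
  }

  structure(list(free = free, clamp = clamp, eliminated = eliminated,
                 params = params, conserve_cki = conserve_cki,
                 reconstruct = reconstruct, f = f, with_param = with_param),
            class = "g0_system")
}

#' @export
print.g0_system <- function(x, ...) {
  cat("<g0_system> ", length(x$free), " free species\n", sep = "")
  if (length(x$clamp)) {
    cat("clamped:", paste(names(x$clamp), collapse = ", "), "\n")
  }
  if (length(x$eliminated)) {
    cat("eliminated by conservation:", paste(x$eliminated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rb-E2F subsystem
#'
#' The mitogen-response subsystem used for the one- and two-parameter
#' bifurcation analysis of Rb hyper-phosphorylation/E2F activation: the
#' APC/C-Cdh1 block (`Cdh1`, `Cdh1P`, `Emi1`, `Emi1Cdh1`, `Ubl`) is clamped
#' at its G1 configuration (Cdh1 fully active, Emi1 absent, Ubl at its
#' Cdh1-suppressed steady state), and CKI turnover is frozen so that total
#' CKI becomes a conserved quantity set by the `CKI_total` parameter.
#'
#' @param params a [g0_parameters] object.
#' @return a `g0_system`.
#' @export
rb_e2f_subsystem <- function(params = default_parameters()) {
  params <- as_g0_parameters(params)
  ubl_g1 <- unname(params["k_subl"] /
                     (params["k_dubl"] + params["k_dublc"] * params["Cdh1_total"]))
  clamp <- c(Cdh1 = unname(params["Cdh1_total"]), Cdh1P = 0,
             Emi1 = 0, Emi1Cdh1 = 0, Ubl = ubl_g1)
  make_system(params, clamp = clamp, conserve_cki = TRUE)
}

#' Cdh1-Emi1 subsystem
#'
#' The G1/S subsystem used for the bifurcation analysis of APC/C-Cdh1
#' inactivation: only `Cdh1`, `Emi1` and the `Emi1Cdh1` complex remain
#' dynamic (`Cdh1P` is eliminated through the Cdh1 conservation law); free
#' Cyclin E:Cdk2 is clamped and used as the bifurcation parameter, E2F is
#' clamped at a proliferative level driving Emi1 synthesis, and Cyclin A and
#' the CKI block are clamped to zero.
#'
#' @param params a [g0_parameters] object.
#' @param cyce clamped Cyclin E:Cdk2 activity (a.u.).
#' @param e2f clamped free-E2F level driving Emi1 synthesis (a.u.).
#' @return a `g0_system`.
#' @export
cdh1_emi1_subsystem <- function(params = default_parameters(), cyce = 0,
                                e2f = 0.5) {
  params <- as_g0_parameters(params)
  clamp <- c(Myc = 0, CycD = 0, CycDCKI = 0, CycE = cyce, CycECKI = 0,
             CycA = 0, CycACKI = 0, CKI = 0, E2F = e2f,
             Rb = 0, RbP = 0, RbPP = unname(params["Rb_total"]),
             RbE2F = 0, RbPE2F = 0, Ubl = 0)
  make_system(params, clamp = clamp)
}
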