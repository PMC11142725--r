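#' Model parameters for the polarization network
#'
#' Constructs the full parameter set of the twelve-field reaction-diffusion
#' model: total concentrations, baseline activation input rates, decay rates,
#' crosstalk activation/inhibition constants, the shared Hill coefficient, and
#' the diffusion coefficients of every species class. Defaults are the
#' published parameterization for renal epithelial (MDCK) cells; any subset can
#' be overridden by name.
#'
#' Units: concentrations and inhibition half-points in uM, first-order rates in
#' 1/s, input and association rates in uM/s, diffusion coefficients in um^2/s.
#'
#' @param ... named overrides of individual parameters, e.g. `I_tot = 20`.
#' @return An object of class `polar_params`: a named list of 29 numeric
#'   parameters.
#'
#' @details
#' The parameter slots are:
#' * `C_tot`, `R_tot`, `rho_tot` — total Cdc42 / Rac / Rho (4.4, 2.4, 4.0 uM).
#' * `I_C`, `I_R`, `I_rho` — baseline activation inputs (0.5, 0.5, 3.3 uM/s).
#' * `delta_C`, `delta_R`, `delta_rho` — active-form decay rates (1 /s).
#' * `beta_R`, `beta_rho`, `beta_PR` — Hill half-points for Rac-on-Rho,
#'   Rho-on-Rac and Par-on-Rac inhibition (1.5, 0.7, 2.0 uM).
#' * `alpha_C`, `alpha_rho` — Cdc42-dependent Par association and
#'   Rho-dependent Cdc42 activation gains (2.5 /s each).
#' * `n_hill` — Hill coefficient of every inhibition term (4).
#' * `D_act`, `D_inact` — membrane / cytosolic GTPase diffusion (0.1, 10).
#' * `P_tot`, `S_tot` — effective total Par and Scribble (1.6 uM each).
#' * `k_on_P`, `k_on_S` — complex association rates (0.5, 4.0 uM/s).
#' * `k_off_P`, `k_off_S` — complex dissociation rates (2.0 /s each).
#' * `beta_SP`, `beta_PS` — Scribble-on-Par / Par-on-Scribble half-points
#'   (0.2 uM each).
#' * `D_PC`, `D_SC`, `D_Pun`, `D_Sun` — complex membrane (0.2) and unbound
#'   cytosolic (2.0) diffusion of the polarity proteins.
#' * `I_tot`, `I_I`, `delta_I`, `alpha_I`, `D_Ii` — integrin total (30 uM),
#'   activation input (10 uM/s), active-integrin decay (1 /s),
#'   integrin-dependent Rac activation (1.5 /s), inactive-integrin diffusion
#'   (10). Active integrin is ECM-bound and does not diffuse.
#' @examples
#' p <- polar_params()
#' p$beta_rho
#' polar_params(I_tot = 18)$I_tot
#' @export
polar_params <- function(...) {
  defaults <- list(
    C_tot = 4.4, R_tot = 2.4, rho_tot = 4.0,
    I_C = 0.5, I_R = 0.5, I_rho = 3.3,
    delta_C = 1.0, delta_R = 1.0, delta_rho = 1.0,
    beta_R = 1.5, beta_rho = 0.7, beta_PR = 2.0,
    alpha_C = 2.5, alpha_rho = 2.5,
    n_hill = 4,
    D_act = 0.1, D_inact = 10,
    P_tot = 1.6, S_tot = 1.6,
    k_on_P = 0.5, k_on_S = 4.0,
    k_off_P = 2.0, k_off_S = 2.0,
    beta_SP = 0.2, beta_PS = 0.2,
    D_PC = 0.2, D_SC = 0.2, D_Pun = 2.0, D_Sun = 2.0,
    I_tot = 30, I_I = 10, delta_I = 1.0, alpha_I = 1.5, D_Ii = 10
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("all parameter overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown) > 0L) {
      abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  validate_polar_params(structure(defaults, class = "polar_params"))
}

validate_polar_params <- function(p) {
  vals <- unlist(p, use.names = TRUE)
  if (!is.numeric(vals) || anyNA(vals)) {
    abort("all parameters must be finite numbers")
  }
  if (p$n_hill < 1 || p$n_hill != round(p$n_hill)) {
    abort("n_hill must be a positive integer")
  }
  nonneg_ok <- c("D_act", "D_inact", "D_PC", "D_SC", "D_Pun", "D_Sun", "D_Ii")
  strict <- vals[setdiff(names(vals), nonneg_ok)]
  if (any(strict <= 0)) {
    abort(paste0(
      "parameters must be strictly positive; offending: ",
      paste(names(strict)[strict <= 0], collapse = ", ")
    ))
  }
  if (any(vals[nonneg_ok] < 0)) {
    abort("diffusion coefficients must be non-negative")
  }
  p
}

#' @export
print.polar_params <- function(x, ...) {
  cat("<polar_params> ", length(x), " parameters\n", sep = "")
  print(tibble::enframe(unlist(x), name = "parameter", value = "value"), n = Inf)
  invisible(x)
}

#' @export
tidy.polar_params <- function(x, ...) {
  tibble::enframe(unlist(x), name = "parameter", value = "value")
}

#' Names of the parameters varied by the sensitivity analysis
#'
#' The 21 interaction parameters subjected to the multiparametric sensitivity
#' analysis: every rate or half-point governing a protein-protein interaction
#' that cannot be measured directly (total GTPase concentrations, Hill
#' coefficient and diffusion coefficients are held fixed).
#'
#' @return Character vector of length 21, a subset of [polar_params()] names.
#' @export
mpsa_parameter_names <- function() {
  c(
    "I_C", "delta_C", "alpha_C",
    "I_R", "delta_R", "beta_R",
    "I_rho", "delta_rho", "alpha_rho", "beta_rho",
    "k_on_P", "k_off_P", "beta_PR", "beta_PS",
    "k_on_S", "k_off_S", "beta_SP",
    "I_I", "delta_I", "I_tot", "alpha_I"
  )
}

## Fixed-order numeric vector handed to the compiled integrator.
params_as_vector <- function(p) {
  unlist(p[c(
    "I_tot", "I_I", "delta_I", "alpha_I", "D_Ii",
    "C_tot", "I_C", "delta_C", "alpha_rho",
    "R_tot", "I_R", "delta_R", "beta_rho", "beta_PR",
    "rho_tot", "I_rho", "delta_rho", "beta_R",
    "n_hill",
    "D_act", "D_inact",
    "P_tot", "k_on_P", "k_off_P", "alpha_C", "beta_SP",
    "S_tot", "k_on_S", "k_off_S", "beta_PS",
    "D_PC", "D_SC", "D_Pun", "D_Sun"
  )])
}

## Per-species diffusion coefficients in SPECIES column order.
## Active integrin is immobilized by its ECM attachment (D = 0).
species_diffusion <- function(p) {
  c(
    I_a = 0, I_i = p$D_Ii,
    C_a = p$D_act, C_i = p$D_inact,
    R_a = p$D_act, R_i = p$D_inact,
    rho_a = p$D_act, rho_i = p$D_inact,
    P_C = p$D_PC, P_un = p$D_Pun,
    S_C = p$D_SC, S_un = p$D_Sun
  )
}
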