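#' Hill inhibition factor
#'
#' Saturating repression term `1 / (1 + (value/beta)^n)` used by every
#' inhibitory interaction in the network (Rac-on-Rho, Rho-on-Rac, Par-on-Rac,
#' and the mutual Par/Scribble inhibition). Equals 1 with no inhibitor, 1/2 at
#' the half-point `beta`, and decreases monotonically with steepness `n`.
#'
#' @param value inhibitor concentration, uM (vectorized; must be >= 0).
#' @param beta half-point concentration, uM (> 0).
#' @param n Hill coefficient, a positive integer.
#' @return Dimensionless factor(s) in (0, 1].
#' @examples
#' hill_inhibition(0.7, 0.7, 4)   # 0.5
#' hill_inhibition(1.4, 0.7, 4)   # 1/17
#' @export
hill_inhibition <- function(value, beta, n) {
  if (!is.numeric(beta) || beta <= 0) abort("beta must be positive")
  if (!is.numeric(n) || n < 1 || n != round(n)) abort("n must be a positive integer")
  if (any(value < 0)) abort("inhibitor concentration must be non-negative")
  1 / (1 + (value / beta)^n)
}

#' Combined Rho- and Par-mediated inhibition of Rac activation
#'
#' The Rac activation prefactor is divided by
#' `1 + (rho_a/beta_rho)^n + (P_C/beta_PR)^n`: active Rho and the bound Par
#' complex inhibit Rac jointly through a single shared denominator rather than
#' as a product of two Hill terms.
#'
#' @param rho_a active Rho concentration, uM.
#' @param P_C bound Par complex concentration, uM.
#' @param params a [polar_params()] object (uses `beta_rho`, `beta_PR`,
#'   `n_hill`).
#' @return Dimensionless factor(s) in (0, 1].
#' @examples
#' p <- polar_params()
#' combined_rac_inhibition(p$beta_rho, 0, p)  # 0.5
#' combined_rac_inhibition(0.7, 2.0, p)       # 1/3 at defaults
#' @export
combined_rac_inhibition <- function(rho_a, P_C, params) {
  if (any(rho_a < 0) || any(P_C < 0)) abort("concentrations must be non-negative")
  n <- params$n_hill
  1 / (1 + (rho_a / params$beta_rho)^n + (P_C / params$beta_PR)^n)
}

#' Local reaction rates of all twelve fields
#'
#' Evaluates the non-diffusive part of the governing equations at every node:
#' integrin activation (on the masked ECM-adjacent nodes only) and decay,
#' GTPase activation/inactivation with Hill-type crosstalk, and polarity
#' complex association/dissociation. Each conjugate pair (active/inactive,
#' bound/unbound) has exactly opposite rates at every node, so reactions
#' conserve each protein family pointwise.
#'
#' Negative round-off in the inhibitor fields is clipped at zero before
#' exponentiation.
#'
#' @param state a `polar_state` matrix (see [initial_state()]).
#' @param params a [polar_params()] object.
#' @param mask logical vector, one entry per node, marking nodes where the
#'   integrin activation input applies (see [activation_mask()]).
#' @param totals optional named list overriding the per-species total used in
#'   a rate law with a per-node vector (used internally by the perturbation
#'   protocol, where the targeted GTPase's total is no longer conserved).
#' @return A matrix of the same shape as `state`, in uM/s.
#' @export
reaction_rates <- function(state, params, mask, totals = NULL) {
  if (length(mask) != nrow(state)) {
    abort("mask length must equal the number of grid nodes")
  }
  p <- params
  n <- p$n_hill
  cl <- function(v) pmax(v, 0)    # guard tiny negative round-off
  tot <- function(name, default) {
    if (!is.null(totals) && !is.null(totals[[name]])) totals[[name]] else default
  }

  I_a <- state[, "I_a"]; I_i <- state[, "I_i"]
  C_a <- state[, "C_a"]; C_i <- state[, "C_i"]
  R_a <- state[, "R_a"]; R_i <- state[, "R_i"]
  rho_a <- state[, "rho_a"]; rho_i <- state[, "rho_i"]
  P_C <- state[, "P_C"]; P_un <- state[, "P_un"]
  S_C <- state[, "S_C"]; S_un <- state[, "S_un"]

  r <- matrix(0, nrow(state), ncol(state), dimnames = dimnames(state))

  # integrins: activation only at the ECM contact, decay everywhere
  act_I <- ifelse(mask, p$I_I * I_i / tot("I", p$I_tot), 0) - p$delta_I * I_a
  r[, "I_a"] <- act_I
  r[, "I_i"] <- -act_I

  # Cdc42: activated by Rho plus a baseline input
  act_C <- (p$alpha_rho * rho_a + p$I_C) * (C_i / tot("C", p$C_tot)) -
    p$delta_C * C_a
  r[, "C_a"] <- act_C
  r[, "C_i"] <- -act_C

  # Rac: activated by integrins, jointly inhibited by Rho and Par
  inhib_R <- 1 + (cl(rho_a) / p$beta_rho)^n + (cl(P_C) / p$beta_PR)^n
  act_R <- (p$alpha_I * I_a + p$I_R) / inhib_R * (R_i / tot("R", p$R_tot)) -
    p$delta_R * R_a
  r[, "R_a"] <- act_R
  r[, "R_i"] <- -act_R

  # Rho: inhibited by Rac
  act_rho <- p$I_rho / (1 + (cl(R_a) / p$beta_R)^n) *
    (rho_i / tot("rho", p$rho_tot)) - p$delta_rho * rho_a
  r[, "rho_a"] <- act_rho
  r[, "rho_i"] <- -act_rho

  # Par complex: association boosted by Cdc42, inhibited by Scribble
  act_P <- (p$alpha_C * C_a + p$k_on_P) / (1 + (cl(S_C) / p$beta_SP)^n) *
    (P_un / p$P_tot) - p$k_off_P * P_C
  r[, "P_C"] <- act_P
  r[, "P_un"] <- -act_P

  # Scribble complex: association inhibited by Par
  act_S <- p$k_on_S / (1 + (cl(P_C) / p$beta_PS)^n) *
    (S_un / p$S_tot) - p$k_off_S * S_C
  r[, "S_C"] <- act_S
  r[, "S_un"] <- -act_S

  r
}
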