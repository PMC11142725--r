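#' Temporal degradation/upregulation profile
#'
#' The percentage of the targeted active GTPase prescribed over the 300-s
#' protocol: 100% during the 100-s pre-phase, an exponential ramp
#' `100 + a (1 - exp(-rate (t - 100)))` during the second 100 s, and a hold at
#' the t = 200 s value for the final 100 s. Negative `a` degrades, positive
#' `a` upregulates.
#'
#' @param t time(s) in seconds, within `[0, t_pre + t_ramp + t_hold]`.
#' @param a perturbation level, percent, in `{-100, -80, ..., 80, 100}`.
#' @param rate exponential rate of the ramp, 1/s (default 0.043).
#' @param t_pre,t_ramp,t_hold phase durations, s (default 100 each).
#' @return Percent of the baseline active amount at each `t`.
#' @examples
#' perturbation_profile(200, a = -100)  # 100 * exp(-4.3), about 1.36
#' @export
perturbation_profile <- function(t, a, rate = 0.043,
                                 t_pre = 100, t_ramp = 100, t_hold = 100) {
  total <- t_pre + t_ramp + t_hold
  if (any(t < 0 | t > total)) {
    abort(sprintf("t must lie in [0, %g] s", total))
  }
  ramp <- function(tt) 100 + a * (1 - exp(-rate * (tt - t_pre)))
  dplyr::case_when(
    t <= t_pre ~ 100,
    t <= t_pre + t_ramp ~ ramp(t),
    .default = ramp(t_pre + t_ramp)
  )
}

perturbable <- c(Cdc42 = 1L, Rac = 2L, Rho = 3L)
active_col <- c(Cdc42 = "C_a", Rac = "R_a", Rho = "rho_a")
inactive_col <- c(Cdc42 = "C_i", Rac = "R_i", Rho = "rho_i")

#' Run the GTPase degradation/upregulation protocol
#'
#' Three-phase in-silico experiment on one Rho-GTPase. Phase 1 (0-100 s):
#' unperturbed dynamics reach the polarized steady state. Phase 2
#' (100-200 s): after every Euler step the targeted active field is rescaled
#' so its node-summed amount follows [perturbation_profile()] (shape
#' preserved, total pinned); degraded protein is removed from the system and
#' upregulated protein is added in active form, and the targeted species'
#' rate law uses its per-node active + inactive total, since its conservation
#' is intentionally broken. Phase 3 (200-300 s): both fields of the targeted
#' species are frozen at their t = 200 s values while all other species
#' evolve freely around them.
#'
#' @inheritParams simulate_polarity
#' @param species which GTPase to perturb: `"Rho"`, `"Rac"` or `"Cdc42"`.
#' @param a perturbation level, percent: negative degrades, positive
#'   upregulates (the protocol grid is -100 to 100 in steps of 20).
#' @param rate ramp rate, 1/s.
#' @param t_pre,t_ramp,t_hold phase durations, s.
#' @param reference optional reference `polar_state` for delta-P; defaults to
#'   the final state of an unperturbed run of the same total duration.
#' @return A list of class `polar_perturbation`: `trajectory` (all three
#'   phases), `polarization` (tibble vs the unperturbed reference),
#'   `species`, `a`, `profile_end` (prescribed percent at the end of the
#'   ramp).
#' @export
run_perturbation <- function(params, grid, species = c("Rho", "Rac", "Cdc42"),
                             a = -100, rate = 0.043,
                             t_pre = 100, t_ramp = 100, t_hold = 100,
                             snapshot_every = 1, reference = NULL) {
  species <- match.arg(species)
  if (abs(a) > 100) abort("a must lie in [-100, 100]")
  check_stability(grid, params)
  mask <- activation_mask(grid, "basal")
  pvec <- params_as_vector(params)
  sp_id <- perturbable[[species]]
  snap_stride <- max(1L, as.integer(round(snapshot_every / grid$dt)))
  state0 <- initial_state(params, grid, "basal")

  steps <- function(tt) ceiling(round(tt / grid$dt, 6))

  # phase 1: free dynamics to the polarized steady state
  ph1 <- rd_integrate(unclass(state0), pvec, grid$dx, grid$dt, steps(t_pre),
                      mask, snap_stride, 0, 0L, 0L, 0, 0, 0, 0)
  s100 <- ph1$final_state
  colnames(s100) <- SPECIES
  ref_sum <- sum(s100[, active_col[[species]]])

  # phase 2: ramp with node-sum pinned to the temporal profile
  ph2 <- rd_integrate(s100, pvec, grid$dx, grid$dt, steps(t_ramp), mask,
                      snap_stride, t_pre, sp_id, 1L, a, rate, t_pre, ref_sum)
  s200 <- ph2$final_state

  # phase 3: targeted species clamped, everything else free
  ph3 <- rd_integrate(s200, pvec, grid$dx, grid$dt, steps(t_hold), mask,
                      snap_stride, t_pre + t_ramp, sp_id, 2L, a, rate, t_pre,
                      ref_sum)

  times <- c(0, ph1$snap_times, ph2$snap_times, ph3$snap_times)
  states <- c(list(state0),
              lapply(c(ph1$snapshots, ph2$snapshots, ph3$snapshots),
                     function(m) { colnames(m) <- SPECIES; as_polar_state(m) }))
  t_total <- t_pre + t_ramp + t_hold
  if (abs(times[length(times)] - t_total) > grid$dt / 2) {
    times <- c(times, t_total)
    fs <- ph3$final_state; colnames(fs) <- SPECIES
    states <- c(states, list(as_polar_state(fs)))
  }
  fs <- ph3$final_state; colnames(fs) <- SPECIES
  traj <- new_trajectory(times, states, as_polar_state(fs), grid, params,
                         "basal", max(ph1$max_clip, ph2$max_clip, ph3$max_clip))

  if (is.null(reference)) {
    reference <- simulate_polarity(params, grid, t_end = t_total,
                                   snapshot_every = t_total)$final_state
  }
  structure(
    list(
      trajectory = traj,
      polarization = polarization(traj$final_state, reference),
      species = species, a = a,
      profile_end = perturbation_profile(t_pre + t_ramp, a, rate,
                                         t_pre, t_ramp, t_hold)
    ),
    class = "polar_perturbation"
  )
}

#' @export
print.polar_perturbation <- function(x, ...) {
  cat(sprintf("<polar_perturbation> %s at a = %+g%% (ramp ends at %.1f%%)\n",
              x$species, x$a, x$profile_end))
  print(x$polarization)
  invisible(x)
}

#' Integrin dose sweep
#'
#' Runs the 100-s baseline simulation over a grid of integrin amplitudes,
#' replacing the total integrin concentration (which jointly scales the
#' initial active-integrin profile and the conserved integrin pool) by each
#' amplitude, and classifies every run against the default-parameter
#' reference. The reported threshold is the smallest tested amplitude whose
#' Par and Scribble outputs are both polarized.
#'
#' @inheritParams simulate_polarity
#' @param amplitudes increasing vector of integrin totals to test, uM
#'   (default `10:30`, resolving the dose threshold at 1-uM steps).
#' @param t_end run length per amplitude, s.
#' @return A list of class `polar_sweep`: `results` (tibble with one row per
#'   amplitude and output), `threshold_uM` (smallest polarized amplitude, NA
#'   if none), `amplitudes`.
#' @export
integrin_sweep <- function(params, grid, amplitudes = 10:30, t_end = 100) {
  if (length(amplitudes) == 0L) abort("amplitudes must be non-empty")
  if (any(amplitudes <= 0) || is.unsorted(amplitudes)) {
    abort("amplitudes must be positive and sorted increasingly")
  }
  reference <- simulate_polarity(params, grid, t_end = t_end,
                                 snapshot_every = t_end)$final_state

  results <- purrr::map(amplitudes, function(A) {
    p_A <- params
    p_A$I_tot <- A
    traj <- simulate_polarity(p_A, grid, t_end = t_end, snapshot_every = t_end)
    polarization(traj$final_state, reference) |>
      dplyr::mutate(amplitude_uM = A, .before = 1)
  }) |>
    purrr::list_rbind()

  complexes <- results |>
    dplyr::filter(.data$output %in% c("P_C", "S_C")) |>
    dplyr::summarise(polarized = all(.data$polarized),
                     .by = "amplitude_uM")
  ok <- complexes$amplitude_uM[complexes$polarized]
  structure(
    list(results = results,
         threshold_uM = if (length(ok)) min(ok) else NA_real_,
         amplitudes = amplitudes),
    class = "polar_sweep"
  )
}

#' @export
print.polar_sweep <- function(x, ...) {
  cat(sprintf("<polar_sweep> %d amplitudes, polarization threshold = %s uM\n",
              length(x$amplitudes),
              ifelse(is.na(x$threshold_uM), "not reached", x$threshold_uM)))
  invisible(x)
}

#' @export
tidy.polar_sweep <- function(x, ...) x$results

#' Directional-cue experiment
#'
#' Runs the baseline simulation twice, with the integrin cue at the basal and
#' at the apical boundary, and verifies that the final states are node-wise
#' mirror images: the Par complex always accumulates at the membrane opposite
#' the active integrins, Scribble at the same membrane.
#'
#' @inheritParams simulate_polarity
#' @return A list with elements `basal` and `apical` (the two trajectories),
#'   `mirror_error` (largest node-wise absolute discrepancy between the
#'   apical run and the flipped basal run, uM), and `par_peak` (named vector
#'   of the node index of the Par maximum in each run).
#' @export
directional_cue <- function(params, grid, t_end = 100) {
  b <- simulate_polarity(params, grid, t_end = t_end, cue_side = "basal",
                         snapshot_every = t_end)
  a <- simulate_polarity(params, grid, t_end = t_end, cue_side = "apical",
                         snapshot_every = t_end)
  flipped <- b$final_state[rev(seq_len(nrow(b$final_state))), , drop = FALSE]
  list(
    basal = b, apical = a,
    mirror_error = max(abs(a$final_state - flipped)),
    par_peak = c(basal = which.max(b$final_state[, "P_C"]),
                 apical = which.max(a$final_state[, "P_C"]))
  )
}
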