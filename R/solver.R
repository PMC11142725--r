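#' Discrete Laplacian with conservative no-flux boundaries
#'
#' Second-order central difference in the interior; at the two boundary nodes
#' a first-order zero-flux closure is used (`(f[2]-f[1])/dx^2` and its mirror)
#' so that the node sum of the returned field is exactly zero and diffusion
#' conserves total material on the grid.
#'
#' @param field numeric vector of nodal concentrations (length >= 3).
#' @param dx node spacing, um.
#' @return Numeric vector of the same length, uM/um^2.
#' @examples
#' laplacian_noflux(c(0, 0, 1, 0, 0), 1)  # c(0, 1, -2, 1, 0)
#' @export
laplacian_noflux <- function(field, dx) {
  n <- length(field)
  if (n < 3L) abort("field must have at least 3 nodes")
  out <- numeric(n)
  out[1] <- (field[2] - field[1]) / dx^2
  out[n] <- (field[n - 1] - field[n]) / dx^2
  i <- 2:(n - 1)
  out[i] <- (field[i - 1] - 2 * field[i] + field[i + 1]) / dx^2
  out
}

#' One explicit Euler step of the full system
#'
#' Reference R implementation of a single forward-Euler update:
#' `state + dt * (reaction_rates + D * laplacian)` per species, with the
#' species-specific diffusion coefficients (active integrin does not diffuse).
#' Negative round-off is clipped at zero. The production time loop runs in
#' compiled code ([simulate_polarity()]); this function defines the update it
#' must reproduce and is convenient for inspecting single transitions.
#'
#' @inheritParams reaction_rates
#' @param grid a [polar_grid()] object.
#' @return The updated `polar_state` matrix.
#' @export
euler_step <- function(state, params, grid, mask) {
  rates <- reaction_rates(state, params, mask)
  D <- species_diffusion(params)
  new <- state
  for (sp in SPECIES) {
    lap <- if (D[[sp]] > 0) laplacian_noflux(state[, sp], grid$dx) else 0
    new[, sp] <- state[, sp] + grid$dt * (rates[, sp] + D[[sp]] * lap)
  }
  if (any(!is.finite(new))) {
    bad <- which(!is.finite(new), arr.ind = TRUE)[1, ]
    abort(sprintf("integration failure: non-finite %s at node %d",
                  colnames(state)[bad[2]], bad[1]))
  }
  new[new < 0] <- 0
  as_polar_state(new)
}

#' Simulate the polarization model
#'
#' Integrates the twelve-field reaction-diffusion system with explicit Euler
#' time stepping from the standard initial condition ([initial_state()]) for
#' `t_end` seconds of model time. The run is fully deterministic. Snapshots of
#' the state are stored every `snapshot_every` seconds of model time (plus the
#' initial and final states).
#'
#' @inheritParams initial_state
#' @param t_end total simulated time, s (default 100, which is past the
#'   steady state of the default parameterization).
#' @param snapshot_every snapshot stride in model seconds (default 1).
#' @param state optional starting `polar_state`; defaults to
#'   [initial_state()].
#' @param t_start model time of the starting state (default 0); snapshot
#'   times are offset accordingly.
#' @return A `polar_trajectory`: list with `times`, `states` (list of
#'   `polar_state`), `final_state`, `grid`, `params`, `cue_side`, `max_clip`
#'   (largest negative excursion clipped to zero, uM).
#' @examples
#' traj <- simulate_polarity(polar_params(), polar_grid(), t_end = 1)
#' traj$final_state[1, "R_a"]
#' @export
simulate_polarity <- function(params, grid, t_end = 100,
                              cue_side = c("basal", "apical"),
                              snapshot_every = 1,
                              state = NULL, t_start = 0) {
  cue_side <- match.arg(cue_side)
  if (t_end < 0) abort("t_end must be non-negative")
  check_stability(grid, params)
  mask <- activation_mask(grid, cue_side)
  if (is.null(state)) state <- initial_state(params, grid, cue_side)

  n_steps <- ceiling(round(t_end / grid$dt, 6))
  if (n_steps == 0L) {
    return(new_trajectory(times = t_start, states = list(state),
                          final_state = state, grid = grid, params = params,
                          cue_side = cue_side, max_clip = 0))
  }
  snap_stride <- max(1L, as.integer(round(snapshot_every / grid$dt)))
  res <- rd_integrate(unclass(state), params_as_vector(params), grid$dx,
                      grid$dt, n_steps, mask, snap_stride, t_start,
                      0L, 0L, 0, 0, 0, 0)
  assemble_trajectory(res, state, t_start, n_steps, grid, params, cue_side)
}

## Shared plumbing: prepend the initial state, append the final state if the
## stride missed it, wrap as polar_trajectory.
assemble_trajectory <- function(res, state0, t_start, n_steps, grid, params,
                                cue_side, include_initial = TRUE) {
  times <- res$snap_times
  label <- function(m) {
    colnames(m) <- SPECIES
    as_polar_state(m)
  }
  states <- lapply(res$snapshots, label)
  res$final_state <- label(res$final_state)
  t_final <- t_start + n_steps * grid$dt
  if (length(times) == 0L || abs(times[length(times)] - t_final) > grid$dt / 2) {
    times <- c(times, t_final)
    states <- c(states, list(res$final_state))
  }
  if (include_initial) {
    times <- c(t_start, times)
    states <- c(list(state0), states)
  }
  new_trajectory(times = times, states = states,
                 final_state = res$final_state,
                 grid = grid, params = params, cue_side = cue_side,
                 max_clip = res$max_clip)
}

new_trajectory <- function(times, states, final_state, grid, params, cue_side,
                           max_clip) {
  structure(
    list(times = times, states = states, final_state = final_state,
         grid = grid, params = params, cue_side = cue_side,
         max_clip = max_clip),
    class = "polar_trajectory"
  )
}

#' @export
print.polar_trajectory <- function(x, ...) {
  cat(sprintf(
    "<polar_trajectory> %d snapshots over t = [%g, %g] s, %d nodes, cue at %s side\n",
    length(x$times), min(x$times), max(x$times), nrow(x$final_state), x$cue_side
  ))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x a `polar_trajectory`.
#' @param species optional character vector restricting the output to a
#'   subset of the twelve fields.
#' @param ... unused.
#' @return A tibble with columns `time_s`, `node`, `x_um`, `species`,
#'   `conc_uM`, suitable for ggplot2 or CSV export.
#' @export
tidy.polar_trajectory <- function(x, species = NULL, ...) {
  out <- purrr::map2(x$states, x$times, function(st, tt) {
    tidy.polar_state(st, grid = x$grid) |>
      dplyr::mutate(time_s = tt, .before = 1)
  }) |>
    purrr::list_rbind()
  if (!is.null(species)) {
    bad <- setdiff(species, SPECIES)
    if (length(bad)) abort(paste0("unknown species: ", paste(bad, collapse = ", ")))
    out <- dplyr::filter(out, .data$species %in% !!species)
  }
  out
}

#' @export
glance.polar_trajectory <- function(x, ...) {
  fam <- family_totals(x$final_state)
  tibble::tibble(
    t_end = max(x$times),
    n_nodes = nrow(x$final_state),
    n_snapshots = length(x$times),
    max_clip_uM = x$max_clip,
    total_integrin_uM = fam[["integrin"]],
    total_par_uM = fam[["par"]]
  )
}

## Node-summed amount of each of the six conserved protein families.
family_totals <- function(state) {
  c(
    integrin = sum(state[, "I_a"]) + sum(state[, "I_i"]),
    cdc42 = sum(state[, "C_a"]) + sum(state[, "C_i"]),
    rac = sum(state[, "R_a"]) + sum(state[, "R_i"]),
    rho = sum(state[, "rho_a"]) + sum(state[, "rho_i"]),
    par = sum(state[, "P_C"]) + sum(state[, "P_un"]),
    scribble = sum(state[, "S_C"]) + sum(state[, "S_un"])
  )
}

#' Export a trajectory as tidy CSV
#'
#' @param x a `polar_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(tidy.polar_trajectory(x), path, row.names = FALSE)
  invisible(path)
}
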