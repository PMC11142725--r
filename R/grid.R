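#' Spatial grid and time-stepping settings
#'
#' The 1D domain spans the apical-basal axis of the cell, from the basal
#' membrane at x = 0 to the apical membrane at x = L. The default 30
#' subdomains (31 nodes) and dt = 0.005 s reproduce the mesh- and
#' time-step-converged discretization of the model; with the default
#' diffusion coefficients the explicit-Euler stability bound
#' dt <= dx^2 / (2 D_max) is satisfied (bound 0.00556 s at dx = 1/3 um,
#' D_max = 10 um^2/s).
#'
#' @param L domain length in um (default 10, a typical cell diameter).
#' @param n_sub number of subdomains; the grid has `n_sub + 1` nodes.
#' @param dt explicit Euler time step in seconds.
#' @return A `polar_grid` object with fields `L`, `n_sub`, `dt`, `dx`,
#'   `n_nodes` and node coordinates `x`.
#' @examples
#' g <- polar_grid()
#' g$dx
#' @export
polar_grid <- function(L = 10, n_sub = 30, dt = 0.005) {
  if (!is.numeric(L) || L <= 0) abort("L must be positive")
  if (!is.numeric(n_sub) || n_sub < 2 || n_sub != round(n_sub)) {
    abort("n_sub must be an integer >= 2")
  }
  if (!is.numeric(dt) || dt <= 0) abort("dt must be positive")
  dx <- L / n_sub
  structure(
    list(
      L = L, n_sub = as.integer(n_sub), dt = dt, dx = dx,
      n_nodes = as.integer(n_sub + 1),
      x = seq(0, L, length.out = n_sub + 1)
    ),
    class = "polar_grid"
  )
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf(
    "<polar_grid> L = %g um, %d nodes (dx = %.4g um), dt = %g s\n",
    x$L, x$n_nodes, x$dx, x$dt
  ))
  invisible(x)
}

## Stop if dt violates the diffusive stability bound for these parameters.
check_stability <- function(grid, params) {
  d_max <- max(species_diffusion(params))
  if (d_max > 0) {
    bound <- grid$dx^2 / (2 * d_max)
    if (grid$dt > bound + 1e-12) {
      abort(sprintf(
        "dt = %g exceeds the explicit stability bound dx^2/(2 D_max) = %.4g s",
        grid$dt, bound
      ))
    }
  }
  invisible(TRUE)
}
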