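#' Design of the multiparametric sensitivity analysis
#'
#' Specifies the Latin hypercube design: the 21 varied interaction parameters
#' ([mpsa_parameter_names()]), the sample count, the multiplier range applied
#' to each baseline value (default 0.2x to 5x, i.e. 20-500%), and the number
#' of inert dummy variables (baseline value 1, same range) whose maximum K-S
#' distance per output sets the significance threshold.
#'
#' @param n_samples number of parameter combinations (>= 2; the full study
#'   design uses 3000).
#' @param range_lo,range_hi multiplier bounds, `0 < range_lo < 1 < range_hi`.
#' @param n_dummies number of dummy variables (default 21).
#' @param seed RNG seed making the design reproducible.
#' @return An `mpsa_design` object.
#' @export
mpsa_design <- function(n_samples = 3000, range_lo = 0.2, range_hi = 5,
                        n_dummies = 21, seed = 1L) {
  if (n_samples < 2) abort("n_samples must be at least 2")
  if (!(range_lo > 0 && range_lo < 1 && range_hi > 1)) {
    abort("need 0 < range_lo < 1 < range_hi")
  }
  structure(
    list(parameter_names = mpsa_parameter_names(),
         n_samples = as.integer(n_samples),
         range_lo = range_lo, range_hi = range_hi,
         n_dummies = as.integer(n_dummies), seed = as.integer(seed)),
    class = "mpsa_design"
  )
}

#' Latin hypercube sample of the varied parameters
#'
#' Draws one stratified sample per parameter: for a parameter with baseline
#' value v, the `n_samples` values are uniformly stratified over
#' `[range_lo * v, range_hi * v]` with exactly one value per equiprobable
#' stratum, shuffled independently per column. Dummies are sampled the same
#' way around baseline 1. Reproducible under the design's seed.
#'
#' @param design an [mpsa_design()].
#' @param baseline a [polar_params()] object supplying the baseline values.
#' @return A list with `samples` (`n_samples x 21` matrix of absolute
#'   parameter values, named columns) and `dummy_samples`
#'   (`n_samples x n_dummies`).
#' @export
lhs_sample <- function(design, baseline = polar_params()) {
  set.seed(design$seed)
  k <- length(design$parameter_names) + design$n_dummies
  unit <- lhs::randomLHS(design$n_samples, k)
  base_vals <- c(unlist(baseline[design$parameter_names]),
                 rep(1, design$n_dummies))
  lo <- design$range_lo * base_vals
  hi <- design$range_hi * base_vals
  scaled <- sweep(sweep(unit, 2, hi - lo, `*`), 2, lo, `+`)
  samples <- scaled[, seq_along(design$parameter_names), drop = FALSE]
  colnames(samples) <- design$parameter_names
  dummies <- scaled[, -seq_along(design$parameter_names), drop = FALSE]
  colnames(dummies) <- paste0("dummy_", seq_len(design$n_dummies))
  list(samples = samples, dummy_samples = dummies)
}

#' Simulate the ensemble and label acceptance
#'
#' Runs the 100-s model once per sampled parameter combination, computes the
#' delta-P statistic of every output against the baseline reference run, and
#' labels each (sample, output) pair accepted when delta-P > 20%. A run that
#' fails to integrate (non-finite fields) is labeled unaccepted for all
#' outputs and flagged.
#'
#' @param samples parameter matrix from [lhs_sample()].
#' @param baseline baseline [polar_params()] (also defines the reference
#'   run).
#' @param grid a [polar_grid()].
#' @param t_end run length, s (default 100).
#' @return A list with `delta_p` and `accepted` (`n_samples x 6` matrices,
#'   outputs as columns), and `failed` (logical per sample).
#' @export
run_ensemble <- function(samples, baseline = polar_params(),
                         grid = polar_grid(), t_end = 100) {
  reference <- simulate_polarity(baseline, grid, t_end = t_end,
                                 snapshot_every = t_end)$final_state
  ref_diff <- vapply(OUTPUTS, apical_basal_difference, numeric(1),
                     state = reference)
  if (any(ref_diff <= 0)) {
    abort("reference run is degenerate: zero apical-basal difference")
  }

  n <- nrow(samples)
  dp <- matrix(NA_real_, n, length(OUTPUTS),
               dimnames = list(NULL, OUTPUTS))
  failed <- logical(n)
  for (m in seq_len(n)) {
    p_m <- baseline
    p_m[colnames(samples)] <- as.list(samples[m, ])
    res <- tryCatch(
      simulate_polarity(p_m, grid, t_end = t_end, snapshot_every = t_end),
      error = function(e) NULL
    )
    if (is.null(res)) {
      failed[m] <- TRUE
      dp[m, ] <- 0
    } else {
      td <- vapply(OUTPUTS, apical_basal_difference, numeric(1),
                   state = res$final_state)
      dp[m, ] <- 100 * td / ref_diff
    }
  }
  if (any(failed)) {
    warn(sprintf("%d of %d ensemble runs failed to integrate; labeled unaccepted",
                 sum(failed), n))
  }
  list(delta_p = dp, accepted = dp > 20, failed = failed)
}

#' Kolmogorov-Smirnov distance between accepted and unaccepted values
#'
#' Sorts a parameter's sampled values, builds the empirical cumulative
#' distributions of the accepted and unaccepted subsets (each normalized by
#' its own count), and returns the maximum absolute difference between them
#' over the pooled values. Distances lie in `[0, 1]`; larger means the
#' parameter separates accepted from unaccepted runs more strongly.
#'
#' If one class is empty the separation is undefined; 0 is returned with a
#' warning so ensemble post-processing never aborts.
#'
#' @param values numeric vector of a parameter's sampled values.
#' @param accepted logical vector of the same length.
#' @return Distance in `[0, 1]`.
#' @examples
#' ks_distance(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE))  # 0.5
#' @export
ks_distance <- function(values, accepted) {
  if (length(values) != length(accepted)) {
    abort("values and accepted must have the same length")
  }
  n_a <- sum(accepted)
  n_u <- sum(!accepted)
  if (n_a == 0L || n_u == 0L) {
    warn("single-class input: K-S distance undefined, returning 0")
    return(0)
  }
  xs <- sort(values)
  fa <- stats::ecdf(values[accepted])
  fu <- stats::ecdf(values[!accepted])
  max(abs(fa(xs) - fu(xs)))
}

#' Dummy-derived significance threshold
#'
#' Per output, the threshold is the maximum K-S distance attained by the
#' inert dummy variables; a model parameter counts as influential for that
#' output iff its own K-S distance exceeds the threshold.
#'
#' @param dummy_ks matrix of dummy K-S distances (dummies x outputs).
#' @return Named numeric vector, one threshold per output column.
#' @export
significance_threshold <- function(dummy_ks) {
  apply(dummy_ks, 2, max)
}

#' Full multiparametric sensitivity analysis
#'
#' Chains [lhs_sample()], [run_ensemble()], [ks_distance()] and
#' [significance_threshold()] into the complete analysis: sample the 21
#' interaction parameters plus the dummies, simulate the ensemble, label
#' acceptance per output, and score every parameter's influence by its K-S
#' separation against the dummy-derived threshold.
#'
#' @inheritParams run_ensemble
#' @param design an [mpsa_design()].
#' @return An object of class `polar_mpsa`: list with `design`, `samples`,
#'   `dummy_samples`, `delta_p`, `accepted`, `failed`, `ks` (21 x 6),
#'   `dummy_ks`, `threshold` (per output), `influential` (21 x 6 logical).
#' @export
run_mpsa <- function(design = mpsa_design(), baseline = polar_params(),
                     grid = polar_grid(), t_end = 100) {
  draws <- lhs_sample(design, baseline)
  ens <- run_ensemble(draws$samples, baseline, grid, t_end)

  ks_for <- function(mat) {
    out <- matrix(NA_real_, ncol(mat), length(OUTPUTS),
                  dimnames = list(colnames(mat), OUTPUTS))
    for (j in seq_along(OUTPUTS)) {
      acc <- ens$accepted[, j]
      for (i in seq_len(ncol(mat))) {
        out[i, j] <- ks_distance(mat[, i], acc)
      }
    }
    out
  }
  ks <- ks_for(draws$samples)
  dummy_ks <- ks_for(draws$dummy_samples)
  threshold <- significance_threshold(dummy_ks)

  structure(
    list(design = design, samples = draws$samples,
         dummy_samples = draws$dummy_samples,
         delta_p = ens$delta_p, accepted = ens$accepted, failed = ens$failed,
         ks = ks, dummy_ks = dummy_ks, threshold = threshold,
         influential = sweep(ks, 2, threshold, `>`)),
    class = "polar_mpsa"
  )
}

#' @export
print.polar_mpsa <- function(x, ...) {
  cat(sprintf("<polar_mpsa> %d samples x %d parameters (+%d dummies)\n",
              nrow(x$samples), ncol(x$samples), ncol(x$dummy_samples)))
  cat("influential parameters per output:\n")
  for (out in colnames(x$ks)) {
    infl <- rownames(x$ks)[x$influential[, out]]
    cat(sprintf("  %-6s: %s\n", out,
                if (length(infl)) paste(infl, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

#' Tidy MPSA results
#'
#' @param x a `polar_mpsa` object.
#' @param ... unused.
#' @return Tibble with one row per (parameter, output): `parameter`,
#'   `output`, `ks`, `threshold`, `influential`, `ks_normalized` (K-S
#'   distance scaled to the per-output maximum).
#' @export
tidy.polar_mpsa <- function(x, ...) {
  tibble::as_tibble(x$ks, rownames = "parameter") |>
    tidyr::pivot_longer(-"parameter", names_to = "output", values_to = "ks") |>
    dplyr::mutate(
      threshold = x$threshold[.data$output],
      influential = .data$ks > .data$threshold
    ) |>
    dplyr::mutate(ks_normalized = .data$ks / max(.data$ks), .by = "output")
}

#' @export
glance.polar_mpsa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_parameters = ncol(x$samples),
    n_dummies = ncol(x$dummy_samples),
    n_failed = sum(x$failed),
    acceptance_rate = mean(x$accepted),
    most_robust_output = OUTPUTS[which.min(colSums(!x$accepted))],
    most_sensitive_output = OUTPUTS[which.max(colSums(!x$accepted))]
  )
}

#' Export MPSA results as CSV and JSON
#'
#' Writes long-format CSVs of the sampled parameters and the per-output
#' delta-P/acceptance, plus a JSON summary with the K-S matrix, dummy
#' thresholds and influential flags.
#'
#' @param x a `polar_mpsa` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mpsa <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples_long <- tibble::as_tibble(x$samples) |>
    dplyr::mutate(sample = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"sample", names_to = "parameter", values_to = "value")
  utils::write.csv(samples_long, file.path(dir, "mpsa_samples.csv"),
                   row.names = FALSE)
  dp_long <- tibble::as_tibble(x$delta_p) |>
    dplyr::mutate(sample = dplyr::row_number(),
                  failed = x$failed, .before = 1) |>
    tidyr::pivot_longer(-c("sample", "failed"), names_to = "output",
                        values_to = "delta_p") |>
    dplyr::mutate(accepted = .data$delta_p > 20)
  utils::write.csv(dp_long, file.path(dir, "mpsa_delta_p.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(ks = x$ks, dummy_ks = x$dummy_ks, threshold = x$threshold,
         influential = x$influential),
    file.path(dir, "mpsa_summary.json"),
    matrix = "rowmajor", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
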