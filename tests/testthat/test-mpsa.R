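test_that("Latin hypercube draws are stratified, in range, and reproducible", {
  des <- mpsa_design(n_samples = 4, seed = 99)
  draws <- lhs_sample(des)
  expect_equal(dim(draws$samples), c(4, 21))
  expect_equal(dim(draws$dummy_samples), c(4, 21))

  # every sampled value lies in [0.2 v, 5 v] of its baseline
  base <- unlist(polar_params()[colnames(draws$samples)])
  for (j in seq_len(ncol(draws$samples))) {
    expect_true(all(draws$samples[, j] >= 0.2 * base[j]))
    expect_true(all(draws$samples[, j] <= 5 * base[j]))
  }
  # beta_R specifically in [0.3, 7.5]
  expect_true(all(draws$samples[, "beta_R"] >= 0.3 &
                    draws$samples[, "beta_R"] <= 7.5))

  # one draw per quartile stratum, per column
  for (j in seq_len(ncol(draws$samples))) {
    u <- (draws$samples[, j] - 0.2 * base[j]) / (4.8 * base[j])
    expect_setequal(findInterval(u, c(0, 0.25, 0.5, 0.75, 1),
                                 rightmost.closed = TRUE), 1:4)
  }
  # dummies centered on baseline 1
  expect_true(all(draws$dummy_samples >= 0.2 & draws$dummy_samples <= 5))

  # reproducibility under the seed
  draws2 <- lhs_sample(des)
  expect_identical(draws$samples, draws2$samples)
  expect_identical(draws$dummy_samples, draws2$dummy_samples)
})

test_that("K-S distance agrees with a brute-force ECDF oracle", {
  expect_equal(ks_distance(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  # identical multisets in both classes separate nothing
  expect_equal(ks_distance(c(1, 2, 3, 1, 2, 3),
                           rep(c(TRUE, FALSE), each = 3)), 0)
  # fully separated supports reach the maximum
  expect_equal(ks_distance(c(1, 2, 3, 10, 11), c(T, T, T, F, F)), 1)

  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    vals <- round(runif(n, 0, 5), 2)
    acc <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(acc) || all(!acc)) next
    expect_equal(ks_distance(vals, acc),
                 ks_bruteforce(vals[acc], vals[!acc]))
    # cross-check against the standard two-sample statistic
    expect_equal(ks_distance(vals, acc),
                 unname(suppressWarnings(
                   stats::ks.test(vals[acc], vals[!acc])$statistic)))
  }
})

test_that("K-S distance is invariant under strictly monotone transforms", {
  set.seed(21)
  vals <- runif(40, 0.5, 4)
  acc <- vals + rnorm(40, sd = 0.8) > 2
  if (all(acc) || all(!acc)) acc[1:2] <- c(TRUE, FALSE)
  d0 <- ks_distance(vals, acc)
  expect_equal(ks_distance(log(vals), acc), d0)
  expect_equal(ks_distance(vals^3, acc), d0)
  expect_equal(ks_distance(exp(vals / 2), acc), d0)
})

test_that("single-class input yields zero with a warning instead of aborting", {
  expect_warning(d <- ks_distance(1:5, rep(TRUE, 5)), "single-class")
  expect_equal(d, 0)
})

test_that("random label permutation drives a real effect toward the null", {
  set.seed(13)
  vals <- runif(200, 1, 5)
  acc <- vals > 3          # strong separation
  d_real <- ks_distance(vals, acc)
  d_perm <- replicate(30, ks_distance(vals, sample(acc)))
  expect_gt(d_real, 0.9)
  expect_lt(mean(d_perm), 0.3)
})

test_that("the dummy threshold is the per-output maximum and gates influence", {
  dummy_ks <- matrix(c(0.1, 0.3, 0.2, 0.05, 0.15, 0.25), nrow = 3,
                     dimnames = list(NULL, c("R_a", "rho_a")))
  thr <- significance_threshold(dummy_ks)
  expect_equal(thr, c(R_a = 0.3, rho_a = 0.25))
  expect_equal(significance_threshold(dummy_ks * 0), c(R_a = 0, rho_a = 0))
})

test_that("the baseline parameter vector itself is accepted with delta-P 100", {
  base <- unlist(polar_params()[mpsa_parameter_names()])
  samples <- matrix(base, nrow = 1, dimnames = list(NULL, names(base)))
  ens <- run_ensemble(samples, polar_params(), polar_grid())
  expect_equal(dim(ens$accepted), c(1, 6))
  expect_equal(unname(ens$delta_p[1, ]), rep(100, 6), tolerance = 1e-9)
  expect_true(all(ens$accepted))
  expect_false(any(ens$failed))
})

test_that("a small end-to-end analysis is reproducible and well-shaped", {
  des <- mpsa_design(n_samples = 8, seed = 5)
  # some outputs may be single-class at this tiny scale; that is the
  # documented degenerate path (distance 0 + warning)
  mp1 <- suppressWarnings(run_mpsa(des))
  mp2 <- suppressWarnings(run_mpsa(des))
  expect_identical(mp1$ks, mp2$ks)
  expect_identical(mp1$accepted, mp2$accepted)
  expect_equal(dim(mp1$ks), c(21, 6))
  expect_equal(dim(mp1$dummy_ks), c(21, 6))
  expect_true(all(mp1$ks >= 0 & mp1$ks <= 1))
  expect_identical(mp1$influential,
                   sweep(mp1$ks, 2, mp1$threshold, `>`))
  td <- tidy(mp1)
  expect_equal(nrow(td), 21 * 6)
  expect_true(all(c("parameter", "output", "ks", "threshold",
                    "influential", "ks_normalized") %in% names(td)))
})
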