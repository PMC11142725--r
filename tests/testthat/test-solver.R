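test_that("the no-flux Laplacian matches the stencil and conserves mass", {
  expect_equal(laplacian_noflux(rep(2.5, 7), 0.5), rep(0, 7))
  expect_equal(laplacian_noflux(c(0, 1, 2, 3), 1), c(1, 0, 0, -1))
  expect_equal(laplacian_noflux(c(0, 0, 1, 0, 0), 1), c(0, 1, -2, 1, 0))
  # node sum is exactly zero for arbitrary fields (discrete conservation)
  set.seed(4)
  for (rep in 1:10) {
    f <- runif(17, 0, 5)
    expect_equal(sum(laplacian_noflux(f, 1 / 3)), 0, tolerance = 1e-12)
  }
  expect_error(laplacian_noflux(c(1, 2), 1), "at least 3")
})

test_that("the compiled integrator reproduces the R reference step", {
  p <- polar_params()
  g <- polar_grid()
  mask <- activation_mask(g)
  s <- initial_state(p, g)

  s_r <- s
  for (i in 1:20) s_r <- euler_step(s_r, p, g, mask)

  res <- polarsim:::rd_integrate(unclass(s), polarsim:::params_as_vector(p),
                                 g$dx, g$dt, 20L, mask, 0L, 0, 0L, 0L,
                                 0, 0, 0, 0)
  expect_equal(unname(res$final_state), unname(unclass(s_r)),
               tolerance = 1e-12)
})

test_that("a uniform reaction fixed point with flat profiles is preserved", {
  # decouple from integrins (no mask effect: I_a = 0 everywhere) and place
  # every pair at its uniform steady state solved from the rate balance
  p <- polar_params()
  g <- polar_grid(n_sub = 30)
  s <- initial_state(p, g)
  s[, "I_a"] <- 0; s[, "I_i"] <- p$I_tot
  # solve the flat two-field fixed point for each pair numerically
  flat_fp <- function(act_fun, tot) {
    f <- stats::uniroot(function(a) act_fun(a, tot - a), c(0, tot),
                        tol = 1e-14)
    f$root
  }
  rho_a <- NULL; R_a <- NULL  # solved iteratively below
  # Rac and Rho are mutually coupled: iterate to a joint fixed point
  R_a <- 0.3; rho_a <- 1.5
  for (i in 1:200) {
    R_a <- flat_fp(function(a, i_) (p$I_R) /
                     (1 + (rho_a / p$beta_rho)^4) * (i_ / p$R_tot) - a, p$R_tot)
    rho_a <- flat_fp(function(a, i_) p$I_rho /
                       (1 + (R_a / p$beta_R)^4) * (i_ / p$rho_tot) - a,
                     p$rho_tot)
  }
  C_a <- flat_fp(function(a, i_) (p$alpha_rho * rho_a + p$I_C) *
                   (i_ / p$C_tot) - a, p$C_tot)
  s[, "R_a"] <- R_a; s[, "R_i"] <- p$R_tot - R_a
  s[, "rho_a"] <- rho_a; s[, "rho_i"] <- p$rho_tot - rho_a
  s[, "C_a"] <- C_a; s[, "C_i"] <- p$C_tot - C_a
  # Par/Scribble joint flat fixed point
  P_C <- 0.5; S_C <- 0.5
  for (i in 1:500) {
    P_C <- flat_fp(function(a, u) (p$alpha_C * C_a + p$k_on_P) /
                     (1 + (S_C / p$beta_SP)^4) * (u / p$P_tot) -
                     p$k_off_P * a, p$P_tot)
    S_C <- flat_fp(function(a, u) p$k_on_S /
                     (1 + (P_C / p$beta_PS)^4) * (u / p$S_tot) -
                     p$k_off_S * a, p$S_tot)
  }
  s[, "P_C"] <- P_C; s[, "P_un"] <- p$P_tot - P_C
  s[, "S_C"] <- S_C; s[, "S_un"] <- p$S_tot - S_C

  mask <- rep(FALSE, g$n_nodes)  # no integrin input
  s1 <- s
  for (i in 1:10) s1 <- euler_step(s1, p, g, mask)
  expect_equal(unclass(s1), unclass(s), tolerance = 1e-9)
})

test_that("one step from the initial state raises Rac at the cue node", {
  p <- polar_params()
  g <- polar_grid()
  s <- initial_state(p, g)
  s1 <- euler_step(s, p, g, activation_mask(g))
  expect_gt(s1[1, "R_a"], s[1, "R_a"])
})

test_that("unperturbed runs conserve every protein family", {
  traj <- baseline_run()
  tot0 <- polarsim:::family_totals(traj$states[[1]])
  tot1 <- polarsim:::family_totals(traj$final_state)
  expect_true(all(abs(tot1 - tot0) / tot0 < 1e-8))
  # no appreciable negative round-off was clipped
  expect_lt(traj$max_clip, 1e-10)
})

test_that("t_end = 0 returns only the initial state and runs are deterministic", {
  p <- polar_params()
  g <- polar_grid()
  tr0 <- simulate_polarity(p, g, t_end = 0)
  expect_length(tr0$times, 1)
  expect_equal(unclass(tr0$final_state), unclass(initial_state(p, g)))

  a <- simulate_polarity(p, g, t_end = 2)
  b <- simulate_polarity(p, g, t_end = 2)
  expect_identical(a$final_state, b$final_state)
})

test_that("the stability bound on dt is enforced", {
  expect_error(
    simulate_polarity(polar_params(), polar_grid(n_sub = 100, dt = 0.005),
                      t_end = 1),
    "stability"
  )
})

test_that("trajectory tidier is long-format with coordinates", {
  tr <- simulate_polarity(polar_params(), polar_grid(), t_end = 2)
  td <- tidy(tr)
  expect_named(td, c("time_s", "node", "x_um", "species", "conc_uM"))
  expect_equal(sort(unique(td$time_s)), c(0, 1, 2))
  expect_equal(nrow(td), 3 * 31 * 12)
  td_sub <- tidy(tr, species = c("P_C", "S_C"))
  expect_setequal(unique(td_sub$species), c("P_C", "S_C"))
  expect_error(tidy(tr, species = "X_a"), "unknown species")
})
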