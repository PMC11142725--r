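test_that("Hill inhibition matches its closed form", {
  expect_equal(hill_inhibition(0, 0.7, 4), 1)
  # value at the half-point is 1/2 for any exponent
  for (n in c(1, 2, 4, 7)) expect_equal(hill_inhibition(0.7, 0.7, n), 0.5)
  expect_equal(hill_inhibition(1.4, 0.7, 4), 1 / 17)
  # monotone non-increasing
  v <- seq(0, 5, by = 0.1)
  expect_true(all(diff(hill_inhibition(v, 1.5, 4)) <= 0))
  expect_error(hill_inhibition(-0.1, 0.7, 4), "non-negative")
  expect_error(hill_inhibition(1, 0, 4), "positive")
})

test_that("Rho and Par inhibit Rac through one shared denominator", {
  p <- polar_params()
  expect_equal(combined_rac_inhibition(0, 0, p), 1)
  expect_equal(combined_rac_inhibition(p$beta_rho, 0, p), 0.5)
  expect_equal(combined_rac_inhibition(0, p$beta_PR, p), 0.5)
  # both ratios at 1 with the defaults beta_rho = 0.7, beta_PR = 2.0
  expect_equal(combined_rac_inhibition(0.7, 2.0, p), 1 / 3)
})

test_that("reaction rates reproduce hand-computed node values", {
  p <- polar_params()
  g <- polar_grid()
  s <- initial_state(p, g)
  mask <- activation_mask(g)

  # interior node with no inhibitors and a full inactive Rac pool
  s2 <- s
  s2[10, "rho_a"] <- 0; s2[10, "P_C"] <- 0; s2[10, "I_a"] <- 0
  s2[10, "R_a"] <- 0; s2[10, "R_i"] <- p$R_tot
  r <- reaction_rates(s2, p, mask)
  expect_equal(unname(r[10, "R_a"]), p$I_R)  # 0.5 uM/s

  # Cdc42 activation with rho_a = 1 and an entirely inactive pool
  s3 <- s
  s3[10, "rho_a"] <- 1; s3[10, "C_a"] <- 0; s3[10, "C_i"] <- p$C_tot
  r <- reaction_rates(s3, p, mask)
  expect_equal(unname(r[10, "C_a"]), (p$alpha_rho * 1 + p$I_C) * 1)  # 3.0 uM/s

  expect_error(reaction_rates(s, p, mask[-1]), "mask length")
})

test_that("conjugate pairs have exactly opposite reaction rates everywhere", {
  p <- polar_params()
  g <- polar_grid()
  mask <- activation_mask(g)
  set.seed(11)
  for (rep in 1:5) {
    s <- initial_state(p, g)
    # random admissible perturbation of the active fractions
    for (pair in list(c("I_a", "I_i"), c("C_a", "C_i"), c("R_a", "R_i"),
                      c("rho_a", "rho_i"), c("P_C", "P_un"),
                      c("S_C", "S_un"))) {
      tot <- s[, pair[1]] + s[, pair[2]]
      frac <- runif(nrow(s))
      s[, pair[1]] <- frac * tot
      s[, pair[2]] <- (1 - frac) * tot
    }
    r <- reaction_rates(s, p, mask)
    expect_identical(r[, "I_a"], -r[, "I_i"])
    expect_identical(r[, "C_a"], -r[, "C_i"])
    expect_identical(r[, "R_a"], -r[, "R_i"])
    expect_identical(r[, "rho_a"], -r[, "rho_i"])
    expect_identical(r[, "P_C"], -r[, "P_un"])
    expect_identical(r[, "S_C"], -r[, "S_un"])
  }
})

test_that("raising active Rho slows Rac activation and speeds Cdc42 activation", {
  p <- polar_params()
  g <- polar_grid()
  mask <- activation_mask(g)
  s <- initial_state(p, g)
  rho_levels <- seq(0, 3, by = 0.5)
  dRa <- vapply(rho_levels, function(rho) {
    s[10, "rho_a"] <- rho
    reaction_rates(s, p, mask)[10, "R_a"]
  }, numeric(1))
  dCa <- vapply(rho_levels, function(rho) {
    s[10, "rho_a"] <- rho
    reaction_rates(s, p, mask)[10, "C_a"]
  }, numeric(1))
  expect_true(all(diff(dRa) <= 0))
  expect_true(all(diff(dCa) >= 0))
})
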