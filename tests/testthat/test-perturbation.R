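test_that("the temporal profile matches its closed form in all three phases", {
  expect_equal(perturbation_profile(0, a = -100), 100)
  expect_equal(perturbation_profile(50, a = 60), 100)
  expect_equal(perturbation_profile(100, a = -100), 100)
  # end of a full-degradation ramp: 100 exp(-4.3)
  expect_equal(perturbation_profile(200, a = -100), 100 * exp(-4.3))
  expect_equal(perturbation_profile(200, a = -100), 1.357, tolerance = 1e-3)
  # the hold phase carries the t = 200 value
  expect_equal(perturbation_profile(250, a = 60),
               100 + 60 * (1 - exp(-4.3)))
  expect_equal(perturbation_profile(250, a = 60),
               perturbation_profile(200, a = 60))
  # mid-ramp value
  expect_equal(perturbation_profile(150, a = -40),
               100 - 40 * (1 - exp(-0.043 * 50)))
  expect_error(perturbation_profile(301, a = 0), "lie in")
  expect_error(perturbation_profile(-1, a = 0), "lie in")
})

test_that("a zero-level protocol reproduces the unperturbed run", {
  p <- polar_params()
  g <- polar_grid()
  ref <- simulate_polarity(p, g, t_end = 300, snapshot_every = 300)$final_state
  pe <- run_perturbation(p, g, species = "Rho", a = 0, snapshot_every = 300,
                         reference = ref)
  expect_equal(unclass(pe$trajectory$final_state), unclass(ref),
               tolerance = 1e-7)
  expect_equal(pe$polarization$delta_p_percent, rep(100, 6), tolerance = 1e-4)
})

test_that("the ramp pins the targeted active amount to the profile", {
  p <- polar_params()
  g <- polar_grid()
  pe <- run_perturbation(p, g, species = "Rac", a = -60, snapshot_every = 5)
  tr <- pe$trajectory
  ref_sum <- sum(tr$states[[which(tr$times == 100)]][, "R_a"])
  in_ramp <- which(tr$times > 100 & tr$times <= 200)
  for (j in in_ramp) {
    target <- perturbation_profile(tr$times[j], a = -60) / 100 * ref_sum
    expect_equal(sum(tr$states[[j]][, "R_a"]), target, tolerance = 0.01)
  }
})

test_that("non-targeted families conserve their totals through all phases", {
  p <- polar_params()
  g <- polar_grid()
  pe <- run_perturbation(p, g, species = "Cdc42", a = -60,
                         snapshot_every = 300)
  tot0 <- polarsim:::family_totals(pe$trajectory$states[[1]])
  tot1 <- polarsim:::family_totals(pe$trajectory$final_state)
  for (fam in c("integrin", "rac", "rho", "par", "scribble")) {
    expect_lt(abs(tot1[[fam]] - tot0[[fam]]) / tot0[[fam]], 1e-8)
  }
  # the targeted family did lose mass
  expect_lt(tot1[["cdc42"]], tot0[["cdc42"]])
})

test_that("the targeted pair is frozen during the hold phase", {
  p <- polar_params()
  g <- polar_grid()
  pe <- run_perturbation(p, g, species = "Rho", a = -40, snapshot_every = 10)
  tr <- pe$trajectory
  s200 <- tr$states[[which(tr$times == 200)]]
  s300 <- tr$states[[which(tr$times == 300)]]
  expect_identical(s300[, "rho_a"], s200[, "rho_a"])
  expect_identical(s300[, "rho_i"], s200[, "rho_i"])
  # other fields kept evolving
  expect_false(isTRUE(all.equal(s300[, "P_C"], s200[, "P_C"],
                                tolerance = 1e-12)))
})

test_that("the cue side sets the orientation and mirrors the final state", {
  p <- polar_params()
  g <- polar_grid()
  dc <- directional_cue(p, g, t_end = 50)
  # Par accumulates opposite the cue, Scribble at the cue
  expect_gt(dc$basal$final_state[31, "P_C"], dc$basal$final_state[1, "P_C"])
  expect_gt(dc$apical$final_state[1, "P_C"], dc$apical$final_state[31, "P_C"])
  expect_gt(dc$basal$final_state[1, "S_C"], dc$basal$final_state[31, "S_C"])
  # node-wise mirror to numerical round-off
  expect_lt(dc$mirror_error, 1e-10)
})

test_that("the integrin sweep validates its amplitude grid", {
  p <- polar_params()
  g <- polar_grid()
  expect_error(integrin_sweep(p, g, amplitudes = numeric(0)), "non-empty")
  expect_error(integrin_sweep(p, g, amplitudes = c(3, 2, 1)), "sorted")
  sw <- integrin_sweep(p, g, amplitudes = c(30), t_end = 20)
  # the default amplitude is its own reference: delta-P 100 throughout
  expect_equal(sw$results$delta_p_percent, rep(100, 6), tolerance = 1e-9)
  expect_equal(sw$threshold_uM, 30)
})
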