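test_that("unfolding work vanishes with the jump and matches the area oracle", {
  expect_equal(unfolding_work(20, 0, 0), 0)
  # oracle: the work equals the area between the released and folded
  # branches, integrated over force with plain trapezoids on wlc_extension
  dl <- nt_to_delta_l(18, conv)
  f_r <- 22
  fg <- seq(1e-4, f_r, length.out = 4000)
  gap <- wlc_extension(fg, wlc_params(0.8, dl), pc)
  area <- sum((gap[-1] + gap[-length(gap)]) / 2 * diff(fg))
  w <- unfolding_work(f_r, dl * wlc_extension(f_r, wlc_params(0.8, 1), pc),
                      dl)
  expect_equal(w, area / pc$kcal_per_mol_pn_nm, tolerance = 0.02)
  # dissipation grows with rupture force for the same species
  fs <- c(12, 18, 25, 35)
  ws <- unfolding_work(fs, dl * wlc_extension(fs, wlc_params(0.8, 1), pc),
                       dl)
  expect_true(all(diff(ws) > 0))
  expect_warning(unfolding_work(5, 0.01, 30), "misdetected")
})

test_that("the Jarzynski estimator is exact for constant work and matches the Gaussian closed form", {
  est <- jarzynski_estimate(rep(10, 50), pc, n_boot = 100)
  expect_equal(est$delta_g, 10, tolerance = 1e-9)
  kT <- pn_nm_to_kcal(pc$kT, pc)
  set.seed(42)
  w <- rnorm(1e5, 12, 1.2)
  est2 <- jarzynski_estimate(w, pc, n_boot = 100)
  expect_equal(est2$delta_g, 12 - 1.2^2 / (2 * kT), tolerance = 0.02)
  expect_error(jarzynski_estimate(rnorm(5)), "at least 10")
})

test_that("Jensen's inequality holds on arbitrary work samples", {
  set.seed(43)
  for (i in 1:20) {
    w <- switch(1 + i %% 4,
                rnorm(50, 8, 2),
                rlnorm(50, 1.5, 0.6),
                runif(50, 0, 15),
                rexp(50, 0.2) + 2)
    est <- jarzynski_estimate(w, pc, n_boot = 50)
    expect_lte(est$delta_g, mean(w) + 1e-9)
  }
})

test_that("finite-sample Jarzynski bias is positive and shrinks with more pulls", {
  kT <- pn_nm_to_kcal(pc$kT, pc)
  mu <- 10; s <- 1
  truth <- mu - s^2 / (2 * kT)
  set.seed(44)
  bias <- vapply(c(25, 100, 400), function(n) {
    est <- replicate(300, {
      w <- rnorm(n, mu, s)
      m <- min(w)
      m - kT * log(mean(exp(-(w - m) / kT)))
    })
    mean(est) - truth
  }, numeric(1))
  expect_true(all(bias > 0))
  expect_true(all(diff(bias) < 0))
})

test_that("tertiary energy is antisymmetric and zero for identical populations", {
  set.seed(45)
  w <- rnorm(60, 9, 1)
  same <- tertiary_energy(w, w, pc, n_boot = 100)
  expect_equal(same$delta_g_tertiary, 0, tolerance = 1e-12)
  w2 <- rnorm(60, 11, 1)
  ab <- tertiary_energy(w2, w, pc, n_boot = 100)
  ba <- tertiary_energy(w, w2, pc, n_boot = 100)
  expect_equal(ab$delta_g_tertiary, -ba$delta_g_tertiary, tolerance = 1e-12)
})

test_that("the stacking energy of the NMS1-4 twin is recovered as a state function", {
  sc <- builtin_scenarios("NMS1-4")
  sim <- simulate_events(sc, n_cycles = 900, seed = 46)
  te <- tertiary_energy(first_rank_works(sim$events, "QQI3+G4_18"),
                        first_rank_works(sim$events, "G4_18"),
                        pc, n_boot = 200)
  expect_lt(abs(te$delta_g_tertiary - 2.0), 0.4)
  # independence of the loading rate: the estimate is an equilibrium
  # quantity, recovered equally from a twice-faster ramp
  sc11 <- builtin_scenarios("NMS1-4", loading_rate = 11)
  sim11 <- simulate_events(sc11, n_cycles = 900, seed = 47)
  te11 <- tertiary_energy(first_rank_works(sim11$events, "QQI3+G4_18"),
                          first_rank_works(sim11$events, "G4_18"),
                          pc, n_boot = 200)
  expect_lt(abs(te11$delta_g_tertiary - 2.0), 0.4)
  expect_lt(abs(te11$delta_g_tertiary - te$delta_g_tertiary),
            3 * sqrt(te$se^2 + te11$se^2))
})
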