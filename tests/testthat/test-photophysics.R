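test_that("excitation rate follows cos^2 photoselection", {
  ph <- photophysics_params()
  pr <- quick_protocol()
  # perpendicular orientation: zero
  expect_equal(excitation_rate(ph, pr, c(0, 1, 0), "primary"), 0)
  expect_equal(excitation_rate(ph, pr, c(0, 0, 1), "secondary"), 0)
  # parallel orientation: sigma * intensity (primary clipped at 1)
  expect_equal(excitation_rate(ph, pr, c(1, 0, 0), "secondary"),
               ph$sigma_T1 * pr$secondary_intensity)
  expect_equal(excitation_rate(ph, pr, c(1, 0, 0), "primary"),
               min(ph$sigma_S0 * pr$primary_fluence, 1))
  # oblique: cos^2 of the angle to the axis
  u <- c(1, 1, 0) / sqrt(2)
  expect_equal(excitation_rate(ph, pr, u, "secondary"),
               ph$sigma_T1 * pr$secondary_intensity * 0.5)
  expect_error(excitation_rate(ph, pr, c(1, 1, 0), "primary"), "unit")
})

test_that("isotropic average of the secondary rate is sigma*I/3", {
  ph <- photophysics_params()
  pr <- quick_protocol()
  ens <- sample_isotropic(2e4, seed = 3)
  rates <- apply(ens$orientations, 1, function(u) {
    excitation_rate(ph, pr, u, "secondary")
  })
  expect_equal(mean(rates) / (ph$sigma_T1 * pr$secondary_intensity), 1 / 3,
               tolerance = 0.02)
})

test_that("polarization leakage mixes the lab axes with unit total weight", {
  ph <- photophysics_params()
  pr <- excitation_protocol(leakage_in_plane = 0.1,
                            leakage_out_of_plane = 0.05,
                            window = 1e-6, bin_width = 50e-9)
  k <- ph$sigma_T1 * pr$secondary_intensity
  expect_equal(excitation_rate(ph, pr, c(1, 0, 0), "secondary"), 0.85 * k)
  expect_equal(excitation_rate(ph, pr, c(0, 1, 0), "secondary"), 0.10 * k)
  expect_equal(excitation_rate(ph, pr, c(0, 0, 1), "secondary"), 0.05 * k)
})

test_that("populations conserve probability and decay as expected", {
  ph <- photophysics_params(k_T = 2e5)
  pr <- quick_protocol(window = 5e-6)
  pop <- integrate_populations(ph, pr, c(1, 0, 0), horizon = 5e-6)
  expect_true(all(abs(pop$S0 + pop$S1 + pop$T1 - 1) < 1e-6))
  expect_true(all(pop$T1 >= 0 & pop$T1 <= 1))

  # secondary off: pure unimolecular decay of the shelf
  pr0 <- quick_protocol(secondary_intensity = 0, window = 5e-6)
  pop0 <- integrate_populations(ph, pr0, c(1, 0, 0), horizon = 5e-6)
  expect_equal(pop0$T1, pop0$T1[1] * exp(-ph$k_T * pop0$time),
               tolerance = 1e-6)
  expect_true(all(pop0$oadf_rate == 0))

  # no intersystem crossing: no shelf, no delayed emission
  ph_no <- photophysics_params(phi_ISC = 0)
  popn <- integrate_populations(ph_no, pr, c(1, 0, 0))
  expect_true(all(popn$T1 == 0))
  expect_true(all(popn$oadf_rate == 0))
})

test_that("aligned molecule with k_T = 0 decays at the pump-depletion rate", {
  ph <- photophysics_params(k_T = 0)
  pr <- quick_protocol(primary_fluence = 1e16, window = 5e-6)
  pop <- integrate_populations(ph, pr, c(1, 0, 0), horizon = 5e-6)
  k_dep <- ph$sigma_T1 * pr$secondary_intensity * ph$phi_RISC *
    (1 - ph$phi_ISC)
  expect_equal(pop$T1 / pop$T1[1], exp(-k_dep * pop$time), tolerance = 1e-6)
  # cross-check against a fine-step explicit Euler integrator
  dt <- 5e-10
  tt <- seq(0, 5e-6, by = dt)
  t1 <- ph$phi_ISC
  euler <- numeric(length(tt))
  for (i in seq_along(tt)) {
    euler[i] <- t1
    t1 <- t1 * (1 - k_dep * dt)
  }
  idx <- round(pop$time / dt) + 1
  expect_equal(pop$T1, euler[idx], tolerance = 1e-3)
})

test_that("OADF emission integral matches the pump-attributable T1 loss", {
  ph <- photophysics_params(k_T = 1e5)
  pr <- quick_protocol(window = 6e-6)
  pop <- integrate_populations(ph, pr, c(1, 0, 0), horizon = 6e-6,
                               n_out = 1201)
  dt <- diff(pop$time[1:2])
  emitted <- sum(pop$oadf_rate) * dt
  k_pump <- excitation_rate(ph, pr, c(1, 0, 0), "secondary")
  pump_loss <- sum(pop$T1 * k_pump * ph$phi_RISC * (1 - ph$phi_ISC)) * dt
  # photons = pump-driven exits * phi_f / (1 - phi_ISC)
  expect_equal(emitted, pump_loss * ph$phi_f / (1 - ph$phi_ISC),
               tolerance = 1e-6)
})

test_that("stronger pumping never increases the T1 population", {
  ph <- photophysics_params(k_T = 1e5)
  u <- c(1, 1, 1) / sqrt(3)
  pops <- lapply(c(0, 1e24, 4e24), function(I) {
    integrate_populations(ph, quick_protocol(secondary_intensity = I,
                                             window = 4e-6), u)
  })
  expect_true(all(pops[[1]]$T1 >= pops[[2]]$T1 - 1e-12))
  expect_true(all(pops[[2]]$T1 >= pops[[3]]$T1 - 1e-12))
})

test_that("orientation averaging slows the ensemble OADF decay", {
  ph <- photophysics_params(k_T = 0)
  pr <- quick_protocol(window = 4e-6)
  horizon <- 4e-6
  aligned <- integrate_populations(ph, pr, c(1, 0, 0), horizon = horizon)
  ens <- sample_isotropic(300, seed = 9)
  t1_sum <- 0
  for (i in seq_len(nrow(ens$orientations))) {
    t1_sum <- t1_sum +
      integrate_populations(ph, pr, ens$orientations[i, ],
                            horizon = horizon, n_out = 41)$T1
  }
  t1_ens <- t1_sum / nrow(ens$orientations)
  idx <- round(seq(1, 201, length.out = 41))
  frac_aligned <- aligned$T1[idx] / aligned$T1[1]
  frac_ens <- t1_ens / t1_ens[1]
  expect_true(all(frac_ens >= frac_aligned - 1e-9))
  expect_gt(frac_ens[41], frac_aligned[41])
})

test_that("delayed secondary turn-on is honored by the integrator", {
  ph <- photophysics_params(k_T = 1e5)
  pr <- excitation_protocol(secondary_on_delay = 2e-6, window = 6e-6,
                            bin_width = 100e-9)
  pop <- integrate_populations(ph, pr, c(1, 0, 0))
  expect_true(all(pop$oadf_rate[pop$time < 2e-6] == 0))
  before <- pop$T1[pop$time <= 2e-6]
  expect_equal(before, pop$T1[1] * exp(-ph$k_T * pop$time[pop$time <= 2e-6]),
               tolerance = 1e-6)
  expect_gt(max(pop$oadf_rate), 0)
})
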