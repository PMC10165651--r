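test_that("no intersystem crossing means no delayed photons", {
  tr <- simulate_oadfa(photophysics_params(phi_ISC = 0), quick_protocol(),
                       diffusion_params(theta_rot = 200e-9), 1e4, seed = 1)
  expect_true(all(tr$counts_par == 0))
  expect_true(all(tr$counts_perp == 0))
  expect_gt(sum(tr$prompt_counts), 0)
})

test_that("same seed reproduces the trace exactly; photon bookkeeping holds", {
  ph <- photophysics_params()
  pr <- quick_protocol(secondary_intensity = 2.4e24)
  di <- diffusion_params(theta_rot = 200e-9)
  a <- simulate_oadfa(ph, pr, di, 5e4, seed = 11)
  b <- simulate_oadfa(ph, pr, di, 5e4, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  for (chan in attr(a, "counters")) {
    expect_lte(chan$n_delayed, chan$n_pump_events)
    expect_lte(chan$n_delayed, chan$n_isc)  # one exit photon max per shelf
    expect_lte(chan$n_isc, chan$n_excited)
  }
  expect_equal(sum(a$counts_par), attr(a, "counters")$par$n_delayed)
  expect_error(simulate_oadfa(ph, pr, di, 0), ">= 1")
})

test_that("rotation much faster than the bin width depolarizes fully", {
  tr <- simulate_oadfa(photophysics_params(),
                       quick_protocol(secondary_intensity = 2.4e24),
                       diffusion_params(theta_rot = 5e-9), 4e5, seed = 3)
  p <- sum(tr$counts_par[-(1:2)])
  q <- sum(tr$counts_perp[-(1:2)])
  r <- (p - q) / (p + 2 * q)
  expect_lt(abs(r), 3 * 0.5 / sqrt(p + q))
})

test_that("weak-depletion traces match the closed-form anisotropy decay", {
  ph <- photophysics_params(k_T = 3e5)
  pr <- quick_protocol(secondary_intensity = 2.4e24)
  di <- diffusion_params(theta_rot = 200e-9)
  tr <- simulate_oadfa(ph, pr, di, 2e6, seed = 5, n_cycles = 4)
  an <- compute_anisotropy(tr, include_prompt = FALSE, blind_bins = 0)
  sel <- an$time < 0.6e-6 & !an$mask & an$r_err > 0
  z <- (an$r[sel] - closed_form_anisotropy(an$time[sel], 200e-9)) /
    an$r_err[sel]
  expect_lt(mean(abs(z)), 2)
  expect_lt(max(abs(z)), 5)
  fit <- fit_decay(compute_anisotropy(tr))
  expect_true(fit$success)
  expect_lt(abs(fit$theta - 200e-9),
            max(3 * fit$theta_err, 0.1 * 200e-9))
})

test_that("prompt fluorescence forces near-zero anisotropy in the blind bin", {
  tr <- simulate_oadfa(photophysics_params(phi_f = 0.3, phi_ISC = 0.7),
                       quick_protocol(secondary_intensity = 2.4e24),
                       diffusion_params(theta_rot = 200e-9), 4e5, seed = 6)
  an_prompt <- compute_anisotropy(tr, blind_bins = 0, include_prompt = TRUE)
  an_pure <- compute_anisotropy(tr, blind_bins = 0, include_prompt = FALSE)
  expect_lt(abs(an_prompt$r[1]), 0.05)
  expect_gt(an_pure$r[3], an_prompt$r[1] + 0.1)
})

test_that("the lab frame can be rotated without changing the statistics", {
  ph <- photophysics_params()
  di <- diffusion_params(theta_rot = 200e-9)
  pr_x <- quick_protocol(secondary_intensity = 2.4e24)
  pr_y <- quick_protocol(secondary_intensity = 2.4e24,
                         primary_pol_axis = c(0, 1, 0))
  a <- simulate_oadfa(ph, pr_x, di, 4e5, seed = 21)
  b <- simulate_oadfa(ph, pr_y, di, 4e5, seed = 22)
  # total counts agree within Poisson error
  for (col in c("counts_par", "counts_perp")) {
    na <- sum(a[[col]]); nb <- sum(b[[col]])
    expect_lt(abs(na - nb) / sqrt(na + nb), 4)
  }
  fa <- fit_decay(compute_anisotropy(a))
  fb <- fit_decay(compute_anisotropy(b))
  expect_lt(abs(fa$theta - fb$theta),
            4 * sqrt(fa$theta_err^2 + fb$theta_err^2))
})

test_that("frozen classic FA reproduces the photoselection limit r = 2/5", {
  ph <- photophysics_params(phi_f = 0.9, phi_ISC = 0)
  pr <- excitation_protocol(window = 30e-9, bin_width = 1e-9)
  tr <- simulate_classic_fa(ph, pr, diffusion_params(D_rot = 0), 2e5,
                            seed = 8, tau_f = 3e-9)
  p <- sum(tr$counts_par); q <- sum(tr$counts_perp)
  r <- (p - q) / (p + 2 * q)
  expect_lt(abs(r - 0.4), 3 * 0.5 / sqrt(p + q))
})

test_that("classic FA recovers a 16.8 ns correlation time with a 3 ns dye", {
  ph <- photophysics_params(phi_f = 0.9, phi_ISC = 0)
  pr <- excitation_protocol(window = 40e-9, bin_width = 1e-9)
  di <- diffusion_params(theta_rot = 16.8e-9)
  tr <- simulate_classic_fa(ph, pr, di, 3e6, seed = 9, tau_f = 3e-9)
  an <- compute_anisotropy(tr, blind_bins = 0)
  fit <- fit_decay(an)
  expect_true(fit$success)
  expect_lt(abs(fit$theta / 16.8e-9 - 1), 0.05)
})

test_that("depletion diagnostics distinguish the three regimes", {
  # weak pump, fast rotation: no crossover, tail anisotropy ~ 0
  weak <- simulate_oadfa(photophysics_params(k_T = 3e5),
                         quick_protocol(secondary_intensity = 1.2e24),
                         diffusion_params(theta_rot = 20e-9), 4e5, seed = 31)
  dw <- differential_depletion_summary(weak)
  expect_true(is.na(dw$crossover_bin))
  expect_false(dw$tail_negative)

  # strong pump, slow rotor: crossover and a negative tail
  cfg <- preset_config("strong_pump_2500ns")
  objs <- config_objects(cfg)
  strong <- simulate_oadfa(objs$photo, objs$protocol, objs$diffusion,
                           5e5, seed = 32, n_cycles = 4)
  ds <- differential_depletion_summary(strong)
  expect_false(is.na(ds$crossover_bin))
  expect_true(ds$tail_negative)

  # delayed secondary: tail anisotropy nonnegative within error
  cfgd <- preset_config("delayed_secondary_2500ns")
  od <- config_objects(cfgd)
  delayed <- simulate_oadfa(od$photo, od$protocol, od$diffusion,
                            5e5, seed = 33, n_cycles = 20)
  dd <- differential_depletion_summary(delayed)
  expect_false(dd$tail_negative)

  expect_error(differential_depletion_summary(weak[1:2, ]), "too short")
})
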