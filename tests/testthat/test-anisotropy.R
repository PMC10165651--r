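test_that("per-bin anisotropy handles the degenerate count patterns", {
  df <- tibble::tibble(
    bin_start = (0:3) * 50e-9,
    counts_par = c(100L, 100L, 80L, 0L),
    counts_perp = c(100L, 0L, 80L, 0L),
    prompt_counts = 0L
  )
  class(df) <- c("oadfa_trace", class(df))
  for (conv in c("standard", "total")) {
    an <- compute_anisotropy(df, convention = conv, blind_bins = 0)
    expect_equal(an$r[1], 0)            # I_par = I_perp
    expect_equal(an$r[2], 1)            # I_perp = 0: degenerate bound
    expect_equal(an$r[3], 0)
    expect_true(an$mask[4])             # zero denominator is masked
  }
  an2 <- compute_anisotropy(df, blind_bins = 2)
  expect_true(all(an2$mask[1:2]))
})

test_that("convention identity holds bin-wise on any trace pair", {
  tr <- synthetic_closed_form_trace(300e-9, 2e5, seed = 4)
  rs <- compute_anisotropy(tr, convention = "standard", blind_bins = 0)
  rp <- compute_anisotropy(tr, convention = "total", blind_bins = 0)
  p <- as.numeric(tr$counts_par)
  q <- as.numeric(tr$counts_perp)
  ratio <- (p + q) / (p + 2 * q)
  ok <- !rs$mask & !rp$mask
  expect_equal(rs$r[ok], (rp$r * ratio)[ok], tolerance = 1e-12)
})

test_that("analytic weak-depletion traces reproduce both closed forms", {
  theta <- 250e-9
  tr <- synthetic_closed_form_trace(theta, 5e6, seed = 8)
  mid <- tr$bin_start + 25e-9
  for (conv in c("standard", "total")) {
    an <- compute_anisotropy(tr, convention = conv, blind_bins = 0)
    ref <- closed_form_anisotropy(mid, theta, convention = conv)
    ok <- !an$mask & an$r_err > 0 & mid < 4 * theta
    z <- (an$r[ok] - ref[ok]) / an$r_err[ok]
    expect_lt(mean(abs(z)), 2)
    expect_lt(max(abs(z)), 5)
  }
})

test_that("mismatched binning between channel traces is an input error", {
  tr <- synthetic_closed_form_trace(300e-9, 1e4, seed = 2)
  tr2 <- tr
  tr2$bin_start <- tr2$bin_start + 1e-9
  expect_error(compute_anisotropy(tr, tr2), "mismatched binning")
})

test_that("noiseless single exponentials are recovered exactly", {
  times <- seq(25e-9, 2e-6, by = 50e-9)
  fit <- fit_decay(exact_aniso(0.4, 200e-9, times))
  expect_true(fit$success)
  expect_equal(fit$r0, 0.4, tolerance = 1e-6)
  expect_equal(fit$theta, 200e-9, tolerance = 1e-6)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("r0", "theta"))
  expect_equal(td$estimate[2], fit$theta)
  gl <- generics::glance(fit)
  expect_true(gl$success)
})

test_that("a constant trace yields a reported failure, never a finite theta", {
  times <- seq(25e-9, 2e-6, by = 50e-9)
  an <- tibble::tibble(time = times, r = 0.25, r_err = 1e-3, mask = FALSE)
  class(an) <- c("oadfa_anisotropy", class(an))
  fit <- fit_decay(an)
  expect_false(fit$success)
  expect_match(fit$reason, "unbounded|non-positive")
  expect_true(is.na(fit$theta))
  expect_error(theta_to_size(fit, solution_conditions(1, 293, unit = "cP")),
               "failed")
})

test_that("fit window contracts are enforced", {
  times <- seq(25e-9, 2e-6, by = 50e-9)
  an <- exact_aniso(0.4, 200e-9, times)
  expect_error(fit_decay(an, window = c(1.9e-6, 2e-6)), "fewer than 4")
  an$mask <- TRUE
  expect_error(fit_decay(an), "no unmasked bins")
})

test_that("fit is unbiased with calibrated uncertainties on Poisson data", {
  theta <- 200e-9
  n_rep <- 200
  stats <- purrr::map_dfr(seq_len(n_rep), function(i) {
    tr <- synthetic_closed_form_trace(theta, 3e5, survival_rate = 4e5,
                                      seed = 1000 + i)
    an <- compute_anisotropy(tr, blind_bins = 0)
    f <- fit_decay(an, window = c(0, 2e-6))
    tibble::tibble(theta_hat = f$theta,
                   covered = abs(f$theta - theta) <= f$theta_err,
                   ok = f$success)
  })
  expect_true(all(stats$ok))
  expect_lt(abs(mean(stats$theta_hat) / theta - 1), 0.01)
  cov <- mean(stats$covered)
  expect_gte(cov, 0.60)
  expect_lte(cov, 0.76)
})

test_that("Stokes-Einstein-Debye inversion reproduces the nanoparticle size", {
  cond <- solution_conditions(1.0005, 293, unit = "cP")
  sz <- theta_to_size(1.5e-6, cond)
  expect_equal(signif(sz$diameter, 2), 23)
  expect_equal(sz$volume, pi * (sz$diameter * 1e-9)^3 / 6, tolerance = 1e-12)
  # independent dimensional pathway: kB in Pa nm^3 / K, volume in nm^3
  v_nm3 <- 1.5e-6 * (1.380649e-23 * 1e27) * 293 / 1.0005e-3
  d_nm <- (6 * v_nm3 / pi)^(1 / 3)
  expect_equal(sz$diameter, d_nm, tolerance = 1e-6)
})

test_that("size/theta round trip and scaling laws hold", {
  cond <- solution_conditions(1.0005, 293, unit = "cP")
  th <- size_to_theta(theta_to_size(1.5e-6, cond)$diameter, cond)
  expect_equal(th, 1.5e-6, tolerance = 1e-12)
  # doubling the diameter multiplies theta by 8
  expect_equal(size_to_theta(46, cond) / size_to_theta(23, cond), 8,
               tolerance = 1e-12)
  # viscosity scaling at fixed volume and temperature
  c1 <- solution_conditions(1.0005, 293, unit = "cP")
  c2 <- solution_conditions(56.76, 293, unit = "cP")
  d <- 10
  expect_equal(size_to_theta(d, c2) / size_to_theta(d, c1),
               56.76 / 1.0005, tolerance = 1e-12)
  expect_equal(56.76 / 1.0005, 56.73, tolerance = 1e-4)
  # vanishing size gives vanishing correlation time
  expect_lt(size_to_theta(1e-3, c1), 1e-15)
  # error propagation: relative error divided by 3
  sz <- theta_to_size(1.5e-6, cond, theta_err = 0.6e-6)
  expect_equal(sz$diameter_err / sz$diameter, 0.6 / 1.5 / 3,
               tolerance = 1e-12)
})
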