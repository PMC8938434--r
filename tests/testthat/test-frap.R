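test_that("normalization maps prebleach to 1 and corrects acquisition decay", {
  t <- 0:8 * 2
  roi <- seq(20, 100, by = 10)
  norm <- suppressWarnings(frap_normalize(t, roi, 100))
  expect_equal(norm$c_norm[1], 0.2)
  expect_equal(norm$c_norm[length(t)], 1.0)

  # identical decay on ROI and reference cancels exactly
  decay <- 1 - 0.1 * seq(0, 1, length.out = length(t))
  withdecay <- frap_normalize(t, roi * decay, 100, reference = 100 * decay)
  expect_equal(withdecay$c_norm, norm$c_norm, tolerance = 1e-9)

  expect_warning(frap_normalize(t, roi, 100), "correction skipped")
  expect_error(frap_normalize(t, roi, 100, reference = c(rep(1, 8), 0)),
               "zero")
  expect_error(frap_normalize(t, roi, 0), "> 0")

  # idempotence: normalizing an already-normalized trace changes nothing
  twice <- suppressWarnings(frap_normalize(norm$time_s, norm$c_norm, 1))
  expect_equal(twice$c_norm, norm$c_norm, tolerance = 1e-12)
})

test_that("recovery fits are exact on noiseless curves and flag immobile
           traces", {
  t <- seq(0, 300, by = 2)
  c_norm <- 0.2 + 0.8 * 0.9 * (1 - exp(-t / 30))
  fit <- fit_recovery(t, c_norm)
  expect_equal(fit$A, 0.9, tolerance = 1e-8)
  expect_equal(fit$tau, 30, tolerance = 1e-8)
  expect_false(fit$immobile)

  flat <- fit_recovery(t, rep(0.05, length(t)))
  expect_true(flat$immobile)
  expect_true(is.na(flat$tau))

  expect_error(fit_recovery(0:3, c(0.2, 0.3, 0.4, 0.5)), "5 time points")
})

test_that("noisy recovery fits have small mean bias in tau", {
  # 3% additive noise, 2 s sampling over 300 s, 100 replicates
  set.seed(31)
  t <- seq(0, 300, by = 2)
  taus <- replicate(100, {
    c_true <- 0.2 + 0.8 * 0.95 * (1 - exp(-t / 23))
    fit_recovery(t, c_true + rnorm(length(t), 0, 0.03))$tau
  })
  expect_lt(abs(mean(taus) / 23 - 1), 0.05)
})

test_that("half-time and diffusion formulas are exact identities", {
  expect_equal(half_time(1), log(2), tolerance = 1e-12)
  expect_equal(half_time(30), 20.79, tolerance = 1e-3)
  expect_error(half_time(0), "> 0")

  expect_equal(diffusion_coefficient(23.3, 2.5), 0.0601, tolerance = 1e-3)
  expect_equal(diffusion_coefficient(10, 2), 4 * diffusion_coefficient(10, 1),
               tolerance = 1e-12)
  expect_equal(diffusion_coefficient(0.224, 1), 1, tolerance = 1e-12)
  expect_error(diffusion_coefficient(-1, 1), "> 0")
})

test_that("bleach radius matches the analytic half-width of known dips", {
  # rectangular dip of half-width 2 um
  x <- seq(-6, 6, by = 0.05)
  rect <- ifelse(abs(x) < 2, 0.2, 1.0)
  expect_lt(abs(bleach_radius(x, rect) - 2.0), 0.06)

  # Gaussian dip: closed form sigma * sqrt(2 ln(1/0.14))
  xg <- seq(-8, 8, by = 0.001)
  sigma <- 1.2
  gauss <- 1 - 0.8 * exp(-xg^2 / (2 * sigma^2))
  expect_equal(bleach_radius(xg, gauss), sigma * sqrt(2 * log(1 / 0.14)),
               tolerance = 1e-6)

  # generator truth agrees
  bp <- gen_bleach_profile(sigma_um = 1.2, depth = 0.8)
  expect_lt(rel_err(bleach_radius(bp$distance_um, bp$intensity),
                    attr(bp, "truth")$radius_um), 1e-3)
  # a nominal ~1.5 um spot blurs to an effective 2-3 um radius
  r_eff <- bleach_radius(bp$distance_um, bp$intensity)
  expect_gt(r_eff, 2)
  expect_lt(r_eff, 3)

  expect_error(bleach_radius(x, rep(1, length(x))), "no bleached dip")
})

test_that("the noiseless pipeline returns the generator's diffusion
           coefficient exactly", {
  for (d_in in c(0.02, 0.06, 0.5)) {
    fr <- gen_frap(d_in, 2.5, noise = 0)
    norm <- frap_normalize(fr$time_s, fr$roi, 100, reference = fr$reference)
    fit <- fit_recovery(norm$time_s, norm$c_norm)
    expect_equal(diffusion_coefficient(fit$t_half, 2.5), d_in,
                 tolerance = 1e-6)
  }
})

test_that("acquisition-bleaching correction removes the downward bias in D", {
  fr <- gen_frap(0.06, 2.5, acq_bleach_rate = 0.003, noise = 0)
  corr <- frap_normalize(fr$time_s, fr$roi, 100, reference = fr$reference)
  d_corr <- diffusion_coefficient(
    fit_recovery(corr$time_s, corr$c_norm)$t_half, 2.5)
  uncorr <- suppressWarnings(frap_normalize(fr$time_s, fr$roi, 100))
  d_uncorr <- diffusion_coefficient(
    fit_recovery(uncorr$time_s, uncorr$c_norm)$t_half, 2.5)
  expect_lt(rel_err(d_corr, 0.06), 0.05)
  expect_gt(rel_err(d_uncorr, 0.06), rel_err(d_corr, 0.06))  # uncorrected is biased
})

test_that("replicate summaries report mean and SD over mobile curves", {
  curves <- lapply(1:5, function(i) {
    gen_frap(0.06, 2.5, noise = 0.01, seed = 100 + i)
  })
  out <- run_frap(curves, prebleach_level = 100, radius_um = 2.5)
  expect_equal(nrow(out$per_replicate), 5)
  expect_equal(out$summary$n_mobile, 5)
  expect_lt(rel_err(out$summary$d_mean_um2_s, 0.06), 0.1)
  expect_gt(out$summary$d_sd_um2_s, 0)

  # a fully immobile replicate is excluded from the summary
  curves[[3]] <- gen_frap(0.06, 2.5, immobile_frac = 1, noise = 0)
  out2 <- run_frap(curves, prebleach_level = 100, radius_um = 2.5)
  expect_true(out2$per_replicate$immobile[3])
  expect_equal(out2$summary$n_mobile, 4)
})
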