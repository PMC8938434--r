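test_that("the cross-correlated rate model is zero at tau = 0, matches the
           frozen oracle value and is strictly monotone", {
  expect_equal(eta_forward(0, sp600), 0)
  # frozen before the build from an independent direct evaluation of the
  # rate formula with CODATA constants (600 MHz, r_NH = 1.02 A,
  # d_sigma_N = 160 ppm, theta = 17 deg)
  expect_equal(eta_forward(5e-9, sp600), 11.906234, tolerance = 1e-6)
  taus <- 10^seq(log10(1e-12), log10(1e-6), length.out = 200)
  expect_true(all(diff(eta_forward(taus, sp600)) > 0))
})

test_that("rate inversion is the exact inverse of the forward model", {
  for (tau_ns in c(0.5, 2, 5, 11)) {
    eta <- eta_forward(tau_ns * 1e-9, sp600)
    expect_equal(tau_c_from_eta(eta, sp600), tau_ns, tolerance = 1e-6)
  }
  # across four decades
  taus_ns <- 10^seq(-2, 2, length.out = 25)
  back <- tau_c_from_eta(eta_forward(taus_ns * 1e-9, sp600), sp600)
  expect_true(all(rel_err(back, taus_ns) < 1e-6))
  # small eta maps to small tau
  expect_lt(tau_c_from_eta(1e-4, sp600), 1e-3)
  # non-physical rates are indeterminate, not errors
  expect_true(is.na(tau_c_from_eta(0, sp600)))
  expect_true(is.na(tau_c_from_eta(-3, sp600)))
  expect_error(tau_c_from_eta(1e9, sp600), "bracket")
})

test_that("eta_xy is half the rate difference with sign preserved", {
  expect_equal(eta_xy(10, 20), 5)
  expect_equal(eta_xy(7, 7), 0)
  expect_equal(eta_xy(20, 10), -5)
})

test_that("exponential decay fits recover exact and noisy rates", {
  delays <- seq(0, 0.24, length.out = 7)
  exact <- fit_decay(delays, 100 * exp(-5 * delays))
  expect_equal(exact$rate, 5, tolerance = 1e-8)
  expect_lt(exact$sd, 1e-6)
  expect_false(exact$flagged)

  flat <- fit_decay(delays, rep(40, 7))
  expect_lt(abs(flat$rate), 1e-3)
  expect_true(flat$flagged)

  expect_error(fit_decay(c(0, 0.1), c(10, 5)), "3 distinct")

  # Monte-Carlo oracle: R = 12/s, 2% multiplicative noise, 7 delays to
  # ~30% residual signal; mean recovery within 1%, reported sd
  # consistent with the empirical scatter
  set.seed(21)
  r_true <- 12
  d7 <- seq(0, log(1 / 0.3) / r_true, length.out = 7)
  fits <- replicate(200, {
    y <- 100 * exp(-r_true * d7) * (1 + rnorm(7, 0, 0.02))
    f <- fit_decay(d7, y)
    c(f$rate, f$sd)
  })
  expect_lt(abs(mean(fits[1, ]) / r_true - 1), 0.01)
  expect_lt(abs(mean(fits[2, ]) / sd(fits[1, ]) - 1), 0.3)
})

test_that("Monte Carlo error propagation is seeded, vanishes with the
           rate errors and scales linearly with them", {
  mc0 <- monte_carlo_sd(10, 0, 30, 0, sp600, n_iter = 500, seed = 1)
  expect_equal(mc0$tau_c_sd_ns, 0)

  a <- monte_carlo_sd(10, 0.3, 30, 0.3, sp600, n_iter = 4000, seed = 9)
  b <- monte_carlo_sd(10, 0.3, 30, 0.3, sp600, n_iter = 4000, seed = 9)
  expect_identical(a$tau_c_sd_ns, b$tau_c_sd_ns)

  # first-order propagation oracle: sd(tau) ~ |dtau/deta| * sd(eta)
  eta0 <- eta_xy(10, 30)
  h <- 1e-5
  dtau_deta <- (tau_c_from_eta(eta0 * (1 + h), sp600) -
                  tau_c_from_eta(eta0 * (1 - h), sp600)) / (2 * eta0 * h)
  for (s in c(0.1, 0.2, 0.4)) {
    mc <- monte_carlo_sd(10, s, 30, s, sp600, n_iter = 20000, seed = 33)
    lin <- abs(dtau_deta) * sqrt(2 * s^2) / 2
    expect_lt(abs(mc$tau_c_sd_ns / lin - 1), 0.1)
  }

  # overwhelming discard fraction flags the result
  bad <- monte_carlo_sd(20, 0.1, 19.9, 0.1, sp600, n_iter = 2000, seed = 3)
  expect_true(bad$indeterminate)
})

test_that("the per-residue pipeline reproduces a noiseless profile exactly", {
  truth <- preset_tau_profile("phase")
  d <- gen_tract(truth, sp600, noise = 0, seed = 1)
  res <- run_tract(d, sp600, n_mc = 200, seed = 5)
  expect_equal(res$residue, names(truth))
  expect_true(all(rel_err(res$tau_c_ns, unname(truth)) < 1e-6))
  expect_false(any(res$indeterminate))
})

test_that("a flat soluble-state profile comes back flat", {
  truth <- preset_tau_profile("soluble")
  d <- gen_tract(truth, sp600, noise = 0.01, seed = 2)
  res <- run_tract(d, sp600, n_mc = 500, seed = 6)
  expect_lt(abs(mean(res$tau_c_ns) - 2), 0.1)
  expect_lt(diff(range(res$tau_c_ns)), 0.5)
})

test_that("residues with overlapping alpha/beta rates are flagged, not dropped", {
  truth <- c(G1 = 4, G5 = 5, N7 = 6, T8 = 7)
  d <- gen_tract(truth, sp600, noise = 0, seed = 3)
  # overwrite three residues with identical alpha and beta decays
  for (res in c("G1", "G5", "N7")) {
    sel_b <- d$residue == res & d$state == "beta"
    sel_a <- d$residue == res & d$state == "alpha"
    d$delay_s[sel_b] <- d$delay_s[sel_a]
    d$intensity[sel_b] <- d$intensity[sel_a]
  }
  out <- run_tract(d, sp600, n_mc = 200, seed = 8)
  expect_equal(out$residue[out$indeterminate], c("G1", "G5", "N7"))
  expect_true(all(is.na(out$tau_c_ns[out$indeterminate])))
  expect_false(out$indeterminate[out$residue == "T8"])
})

test_that("structural errors in the decay table are rejected by name", {
  d <- gen_tract(c(G1 = 3, G2 = 4), sp600, noise = 0, seed = 4)
  expect_error(run_tract(d[d$residue != "G2" | d$state != "beta", ], sp600),
               "G2")
  expect_error(run_tract(d[, c("residue", "state", "intensity")], sp600),
               "delay_s")
  empty <- d[0, ]
  expect_equal(nrow(run_tract(empty, sp600)), 0)
})
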