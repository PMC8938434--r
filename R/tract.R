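#' Spin parameters for TRACT analysis
#'
#' Bundles the spectrometer field and the spin-interaction constants that
#' enter the cross-correlated relaxation rate of the amide 15N: the
#' dipole-CSA prefactor p, the CSA term, and the 15N Larmor frequency.
#' Values not measurable from the data (N-H distance, CSA breadth, the
#' dipole/CSA angle) default to the values standard in the TRACT
#' literature and are configurable.
#'
#' @param field_mhz Proton Larmor frequency in MHz (sets B0).
#' @param r_nh_a Amide N-H distance in Angstrom (default 1.02).
#' @param delta_sigma_n_ppm 15N CSA breadth in ppm (default 160).
#' @param theta_deg Angle between the dipolar and CSA tensors in degrees
#'   (default 17).
#' @param gamma_h,gamma_n Gyromagnetic ratios in rad/s/T (magnitudes).
#' @return An object of class `spin_parameters`.
#' @examples
#' sp <- spin_parameters(600)
#' sp$b0  # ~14.09 T
#' @export
spin_parameters <- function(field_mhz = 600, r_nh_a = 1.02,
                            delta_sigma_n_ppm = 160, theta_deg = 17,
                            gamma_h = .GAMMA_H, gamma_n = .GAMMA_N15) {
  stopifnot(field_mhz > 0, r_nh_a > 0, theta_deg >= 0, theta_deg <= 90)
  b0 <- 2 * pi * field_mhz * 1e6 / gamma_h
  structure(
    list(field_mhz = field_mhz,
         b0 = b0,
         gamma_h = gamma_h,
         gamma_n = gamma_n,
         r_nh_a = r_nh_a,
         delta_sigma_n_ppm = delta_sigma_n_ppm,
         theta_deg = theta_deg,
         omega_n = gamma_n * b0),
    class = "spin_parameters"
  )
}

#' @export
print.spin_parameters <- function(x, ...) {
  cat(sprintf(
    "Spin parameters: %.0f MHz (B0 = %.3f T), r_NH = %.2f A, d_sigma_N = %.0f ppm, theta = %.0f deg\n",
    x$field_mhz, x$b0, x$r_nh_a, x$delta_sigma_n_ppm, x$theta_deg))
  invisible(x)
}

#' Cross-correlated relaxation rate from the rotational correlation time
#'
#' Forward model for the transverse 15N dipole-CSA cross-correlated rate:
#' \deqn{\eta_{xy} = 2 p \delta_N (3\cos^2\theta - 1)(4J(0) + 3J(\omega_N))}
#' with \eqn{p = \mu_0\gamma_H\gamma_N h / (16\pi^2\sqrt{2}\, r_{NH}^3)},
#' \eqn{\delta_N = \gamma_N B_0 \Delta\delta_N / (3\sqrt{2})} and the
#' rigid-tumbling spectral density
#' \eqn{J(\omega) = 0.4\,\tau_c/(1 + \omega^2\tau_c^2)}. Strictly
#' increasing in \eqn{\tau_c}, which makes the inversion well posed.
#'
#' @param tau_c_s Rotational correlation time(s) in seconds (vectorised).
#' @param sp A [spin_parameters()] object.
#' @return Rate(s) in 1/s.
#' @export
eta_forward <- function(tau_c_s, sp) {
  stopifnot(inherits(sp, "spin_parameters"))
  if (any(tau_c_s < 0)) stop("tau_c must be >= 0", call. = FALSE)
  r_m <- sp$r_nh_a * 1e-10
  p <- .MU0 * sp$gamma_h * sp$gamma_n * .PLANCK_H /
    (16 * pi^2 * sqrt(2) * r_m^3)
  delta_n <- sp$gamma_n * sp$b0 * sp$delta_sigma_n_ppm * 1e-6 / (3 * sqrt(2))
  ang <- 3 * cos(sp$theta_deg * pi / 180)^2 - 1
  j0 <- 0.4 * tau_c_s
  jwn <- 0.4 * tau_c_s / (1 + sp$omega_n^2 * tau_c_s^2)
  2 * p * delta_n * ang * (4 * j0 + 3 * jwn)
}

#' Invert the cross-correlated rate to a rotational correlation time
#'
#' Solves \eqn{\eta_{xy}(\tau_c) = \eta} for \eqn{\tau_c} by bisection in
#' \eqn{\log\tau_c} on the bracket \[1 ps, 10 us\], to a relative
#' tolerance of 1e-9 in \eqn{\eta}. Vectorised over `eta`. Non-positive
#' rates are indeterminate and return `NA` (no error): they arise when the
#' fitted alpha-state rate exceeds the beta-state rate within noise.
#'
#' @param eta Cross-correlated rate(s) in 1/s.
#' @param sp A [spin_parameters()] object.
#' @param lower,upper Bracket for the root, in seconds.
#' @return Correlation time(s) in ns (`NA` where `eta <= 0`).
#' @export
tau_c_from_eta <- function(eta, sp, lower = 1e-12, upper = 1e-5) {
  stopifnot(inherits(sp, "spin_parameters"))
  out <- rep(NA_real_, length(eta))
  ok <- is.finite(eta) & eta > 0
  if (!any(ok)) return(out)
  eta_hi <- eta_forward(upper, sp)
  if (any(eta[ok] > eta_hi)) {
    stop(sprintf(
      "eta = %.4g 1/s exceeds the value at the upper bracket (%.4g 1/s at tau_c = %g s)",
      max(eta[ok]), eta_hi, upper), call. = FALSE)
  }
  # eta is linear in tau below the bracket floor; extend the floor so the
  # root stays bracketed for arbitrarily small positive rates
  while (min(eta[ok]) < eta_forward(lower, sp) && lower > 1e-24) {
    lower <- lower / 100
  }
  lo <- rep(log(lower), sum(ok))
  hi <- rep(log(upper), sum(ok))
  target <- eta[ok]
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    f <- eta_forward(exp(mid), sp)
    below <- f < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  root <- exp((lo + hi) / 2)
  # monotone bisection to 2^-80 of the log-bracket leaves residuals far
  # below the 1e-9 relative tolerance; assert anyway
  resid <- abs(eta_forward(root, sp) - target) / target
  if (any(resid > 1e-9)) {
    stop("bisection failed to reach the 1e-9 relative tolerance",
         call. = FALSE)
  }
  out[ok] <- root * 1e9
  out
}

#' Cross-correlated rate from the two 15N doublet relaxation rates
#'
#' The TRACT observable: half the difference between the relaxation rates
#' of the broad (anti-TROSY, beta) and narrow (TROSY, alpha) 15N doublet
#' components. May be non-positive for noisy data; such residues are
#' handled as indeterminate downstream.
#'
#' @param r_alpha,r_beta Relaxation rates in 1/s.
#' @return Rate in 1/s.
#' @export
eta_xy <- function(r_alpha, r_beta) {
  (r_beta - r_alpha) / 2
}

#' Fit a monoexponential decay to a relaxation series
#'
#' Unweighted nonlinear least squares of \eqn{I(t) = I_0 e^{-Rt}} (no
#' offset) with starting values from a log-linear regression. Rate
#' uncertainty is taken from the fit covariance. Non-decaying or constant
#' series are not an error: they yield a rate near zero with a `flagged`
#' marker.
#'
#' @param delays Delay times in s, at least 3 distinct values.
#' @param intensities Signal intensities, same length.
#' @return A list with `rate` (1/s), `sd`, `amplitude`, `rss` and
#'   `flagged`.
#' @export
fit_decay <- function(delays, intensities) {
  if (length(delays) != length(intensities)) {
    stop("delays and intensities must have the same length", call. = FALSE)
  }
  if (length(unique(delays)) < 3L) {
    stop("at least 3 distinct delays are required", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (is.unsorted(delays, strictly = TRUE)) {
    o <- order(delays)
    delays <- delays[o]
    intensities <- intensities[o]
  }
  # log-linear start (guard non-positive intensities)
  pos <- intensities > 0
  if (sum(pos) >= 2L) {
    cf <- stats::coef(stats::lm(log(intensities[pos]) ~ delays[pos]))
    start <- list(i0 = exp(cf[[1L]]), r = max(-cf[[2L]], 1e-9))
  } else {
    start <- list(i0 = max(abs(intensities)), r = 1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(intensities ~ i0 * exp(-r * delays),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(rate = 0, sd = Inf, amplitude = mean(intensities),
                rss = NA_real_, flagged = TRUE))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(i0 = NA_real_, r = NA_real_))
  sd_r <- unname(se[["r"]])
  if (!is.finite(sd_r)) sd_r <- 0
  rate <- unname(est[["r"]])
  flagged <- rate <= 1e-6 || (is.finite(sd_r) && sd_r >= abs(rate))
  list(rate = rate,
       sd = sd_r,
       amplitude = unname(est[["i0"]]),
       rss = sum(stats::resid(fit)^2),
       flagged = flagged)
}

#' Monte Carlo uncertainty of a rotational correlation time
#'
#' Resamples the two doublet relaxation rates from normal distributions
#' centred on their fitted values, recomputes \eqn{\tau_c} for each draw
#' and reports the standard deviation of the sample. Draws in which the
#' beta rate does not exceed the alpha rate have no physical solution and
#' are discarded (and counted); if more than half the draws are discarded
#' the result is flagged indeterminate.
#'
#' @param r_alpha,r_beta Fitted relaxation rates, 1/s.
#' @param r_alpha_sd,r_beta_sd Their standard deviations, >= 0.
#' @param sp A [spin_parameters()] object.
#' @param n_iter Number of Monte Carlo draws (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `tau_c_sd_ns`, `frac_discarded` and
#'   `indeterminate`.
#' @export
monte_carlo_sd <- function(r_alpha, r_alpha_sd, r_beta, r_beta_sd, sp,
                           n_iter = 10000L, seed = NULL) {
  stopifnot(n_iter >= 1, r_alpha_sd >= 0, r_beta_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  ra <- stats::rnorm(n_iter, r_alpha, r_alpha_sd)
  rb <- stats::rnorm(n_iter, r_beta, r_beta_sd)
  eta <- eta_xy(ra, rb)
  keep <- eta > 0
  frac_discarded <- 1 - mean(keep)
  if (frac_discarded > 0.5) {
    return(list(tau_c_sd_ns = NA_real_, frac_discarded = frac_discarded,
                indeterminate = TRUE))
  }
  tau <- tau_c_from_eta(eta[keep], sp)
  sd_ns <- if (sum(keep) > 1L) stats::sd(tau) else 0
  list(tau_c_sd_ns = sd_ns, frac_discarded = frac_discarded,
       indeterminate = FALSE)
}

#' Residue-specific rotational correlation times from TRACT data
#'
#' Full per-residue pipeline: exponential fits of the alpha- and
#' beta-state decays, cross-correlated rate, inversion to \eqn{\tau_c},
#' and Monte Carlo propagation of the fit uncertainties. Residues whose
#' two rates are equal within error (or inverted) are marked
#' indeterminate and carry `NA` correlation times; plotting code
#' conventionally renders these as zero.
#'
#' @param decays Data frame with columns `residue`, `state` (`"alpha"` or
#'   `"beta"`), `delay_s`, `intensity`. Every residue must appear in both
#'   states.
#' @param sp A [spin_parameters()] object.
#' @param n_mc Monte Carlo draws per residue (default 10000).
#' @param seed Optional integer seed; per-residue streams are derived from
#'   it.
#' @return A data frame with one row per residue: `residue`, `r_alpha`,
#'   `r_alpha_sd`, `r_beta`, `r_beta_sd`, `eta_xy`, `tau_c_ns`,
#'   `tau_c_sd_ns`, `indeterminate`.
#' @export
run_tract <- function(decays, sp, n_mc = 10000L, seed = NULL) {
  stopifnot(inherits(sp, "spin_parameters"))
  required <- c("residue", "state", "delay_s", "intensity")
  missing_cols <- setdiff(required, names(decays))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(decays) == 0L) {
    return(data.frame(residue = character(), r_alpha = numeric(),
                      r_alpha_sd = numeric(), r_beta = numeric(),
                      r_beta_sd = numeric(), eta_xy = numeric(),
                      tau_c_ns = numeric(), tau_c_sd_ns = numeric(),
                      indeterminate = logical()))
  }
  if (!all(decays$state %in% c("alpha", "beta"))) {
    stop("state must be 'alpha' or 'beta'", call. = FALSE)
  }
  res_a <- unique(decays$residue[decays$state == "alpha"])
  res_b <- unique(decays$residue[decays$state == "beta"])
  only_one <- c(setdiff(res_a, res_b), setdiff(res_b, res_a))
  if (length(only_one) > 0L) {
    stop(sprintf("residue(s) present in only one state: %s",
                 paste(only_one, collapse = ", ")), call. = FALSE)
  }
  residues <- unique(decays$residue)
  rows <- lapply(seq_along(residues), function(i) {
    res <- residues[[i]]
    sub_a <- decays[decays$residue == res & decays$state == "alpha", ]
    sub_b <- decays[decays$residue == res & decays$state == "beta", ]
    fa <- fit_decay(sub_a$delay_s, sub_a$intensity)
    fb <- fit_decay(sub_b$delay_s, sub_b$intensity)
    eta <- eta_xy(fa$rate, fb$rate)
    eta_sd <- sqrt(fa$sd^2 + fb$sd^2) / 2
    indet <- !is.finite(eta) || eta <= 0 || eta <= eta_sd
    tau <- NA_real_
    tau_sd <- NA_real_
    if (!indet) {
      tau <- tau_c_from_eta(eta, sp)
      mc <- monte_carlo_sd(fa$rate, fa$sd, fb$rate, fb$sd, sp,
                           n_iter = n_mc,
                           seed = if (is.null(seed)) NULL else seed + i)
      if (mc$indeterminate) {
        indet <- TRUE
        tau <- NA_real_
      } else {
        tau_sd <- mc$tau_c_sd_ns
      }
    }
    data.frame(residue = res, r_alpha = fa$rate, r_alpha_sd = fa$sd,
               r_beta = fb$rate, r_beta_sd = fb$sd, eta_xy = eta,
               tau_c_ns = tau, tau_c_sd_ns = tau_sd,
               indeterminate = indet)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
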