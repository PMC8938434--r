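# Seeded generators for every input the analyzers consume. Each generator
# is the exact inverse image of its analyzer at zero noise, so round-trip
# identity tests pin the pipeline down end to end.

#' Simulate a TRACT relaxation dataset
#'
#' Forward-simulates per-residue alpha/beta relaxation decays from a
#' ground-truth correlation-time profile: the cross-correlated rate of
#' each residue is computed with [eta_forward()] and split symmetrically
#' about a base relaxation rate (`R_alpha = base - eta`,
#' `R_beta = base + eta`). For each residue and state, `n_delays` points
#' are sampled with the delay range auto-scaled so that the last point
#' of each state decays to `last_fraction` (~30%) of its own first
#' increment, the acquisition design used for pseudo-3D relaxation
#' series.
#' Multiplicative Gaussian noise is applied to the intensities.
#'
#' @param tau_profile_ns Named numeric vector of ground-truth correlation
#'   times in ns (names are residue labels, e.g. `"F4"`).
#' @param sp A [spin_parameters()] object.
#' @param base_rate Base transverse relaxation rate in 1/s about which
#'   the two doublet components split (default 30; must exceed the
#'   largest eta in the profile).
#' @param noise Relative (multiplicative) Gaussian noise level (default
#'   0.02).
#' @param n_delays Delays per decay (default 7).
#' @param last_fraction Target residual signal at the last delay of each
#'   state (default 0.3).
#' @param i0 First-point intensity (default 100).
#' @param seed Optional integer seed.
#' @return Data frame with columns `residue`, `state`, `delay_s`,
#'   `intensity`; the ground-truth rates are attached as attribute
#'   `"truth"`.
#' @export
gen_tract <- function(tau_profile_ns, sp, base_rate = 30, noise = 0.02,
                      n_delays = 7L, last_fraction = 0.3, i0 = 100,
                      seed = NULL) {
  stopifnot(inherits(sp, "spin_parameters"))
  if (any(tau_profile_ns <= 0)) stop("tau values must be > 0", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labels <- names(tau_profile_ns)
  if (is.null(labels)) labels <- paste0("res", seq_along(tau_profile_ns))
  eta <- eta_forward(tau_profile_ns * 1e-9, sp)
  if (any(eta >= base_rate)) {
    stop("base_rate must exceed the largest eta in the profile",
         call. = FALSE)
  }
  r_alpha <- base_rate - eta
  r_beta <- base_rate + eta
  rows <- lapply(seq_along(labels), function(i) {
    do.call(rbind, lapply(c("alpha", "beta"), function(st) {
      r <- if (st == "alpha") r_alpha[i] else r_beta[i]
      # each state is sampled to ~`last_fraction` residual signal of its
      # own first increment
      delays <- seq(0, log(1 / last_fraction) / r, length.out = n_delays)
      ideal <- i0 * exp(-r * delays)
      obs <- ideal * (1 + stats::rnorm(n_delays, 0, noise))
      data.frame(residue = labels[i], state = st, delay_s = delays,
                 intensity = obs)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(residue = labels,
                                   tau_c_ns = unname(tau_profile_ns),
                                   eta_xy = eta, r_alpha = r_alpha,
                                   r_beta = r_beta)
  out
}

#' Ground-truth correlation-time profile of a condensed-phase repeat
#'
#' An 11-residue profile over the non-proline positions of the 12-mer
#' GGLFGGNTQPAT with maxima at the hydrophobic patch (L3/F4) and around
#' the proline (Q9/A11), spanning roughly 6-11 ns, the range and shape
#' characteristic of an FG condensed phase at 36 degC. With
#' `state = "soluble"` a flat ~2 ns profile is returned instead
#' (aqueous-phase behaviour at 24 degC).
#'
#' @param state `"phase"` (default) or `"soluble"`.
#' @return Named numeric vector of correlation times in ns.
#' @export
preset_tau_profile <- function(state = c("phase", "soluble")) {
  state <- match.arg(state)
  labels <- c("G1", "G2", "L3", "F4", "G5", "G6", "N7", "T8", "Q9",
              "A11", "T12")
  if (state == "phase") {
    stats::setNames(c(6.0, 6.5, 9.0, 11.0, 6.5, 6.0, 6.5, 7.0, 9.0,
                      10.0, 7.0), labels)
  } else {
    stats::setNames(rep(2.0, length(labels)), labels)
  }
}

#' Simulate a FRAP time course
#'
#' Inverts the exponential recovery model: the normalized bleached-ROI
#' signal is \eqn{C(t) = c_0 + (1 - c_0)\,A(1 - e^{-t/\tau})} with
#' bleach floor \eqn{c_0 = 1 - } `bleach_depth`, mobile fraction
#' \eqn{A = 1 - } `immobile_frac`, and
#' \eqn{\tau = 0.224 R^2 / (\ln 2\, D)}. Both the ROI and an unbleached
#' reference trace decay exponentially at the acquisition-photobleaching
#' rate; additive Gaussian noise is applied to the normalized signal.
#'
#' @param d_um2_s Ground-truth diffusion coefficient in um^2/s.
#' @param radius_um Effective bleach radius in um.
#' @param bleach_depth Fraction of signal removed by the bleach (0-1,
#'   default 0.8).
#' @param immobile_frac Immobile protein fraction (0-1, default 0.05).
#' @param acq_bleach_rate Acquisition photobleaching rate in 1/s
#'   (default 0).
#' @param dt Frame interval in s (default 2, the standard acquisition
#'   interval).
#' @param t_end Last frame time in s (default 300).
#' @param prebleach_level Prebleach ROI signal (default 100).
#' @param noise Additive Gaussian noise on the normalized signal
#'   (default 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns `time_s`, `roi`, `reference`;
#'   ground-truth parameters attached as attribute `"truth"`.
#' @export
gen_frap <- function(d_um2_s, radius_um, bleach_depth = 0.8,
                     immobile_frac = 0.05, acq_bleach_rate = 0, dt = 2,
                     t_end = 300, prebleach_level = 100, noise = 0,
                     seed = NULL) {
  stopifnot(d_um2_s > 0, radius_um > 0,
            bleach_depth > 0, bleach_depth <= 1,
            immobile_frac >= 0, immobile_frac <= 1)
  if (!is.null(seed)) set.seed(seed)
  tau <- 0.224 * radius_um^2 / (-log(0.5) * d_um2_s)
  times <- seq(0, t_end, by = dt)
  a <- 1 - immobile_frac
  floor0 <- 1 - bleach_depth
  c_true <- floor0 + bleach_depth * a * (1 - exp(-times / tau))
  decay <- exp(-acq_bleach_rate * times)
  c_obs <- c_true + stats::rnorm(length(times), 0, noise)
  out <- data.frame(time_s = times,
                    roi = prebleach_level * c_obs * decay,
                    reference = prebleach_level * decay)
  attr(out, "truth") <- list(d_um2_s = d_um2_s, tau_s = tau,
                             t_half_s = half_time(tau), A = a,
                             bleach_floor = floor0)
  out
}

#' Simulate a postbleach radial intensity profile
#'
#' Gaussian bleached dip \eqn{I(x) = 1 - d\,e^{-x^2/2\sigma^2}},
#' emulating a nominally small bleach spot blurred by diffusion during
#' bleaching and by the laser profile. The half-width at 86% of bleach
#' depth of this profile is \eqn{\sigma\sqrt{2\ln(1/0.14)}}.
#'
#' @param sigma_um Gaussian width of the dip in um (default 1.2, which
#'   blurs a nominal ~1.5 um spot to an effective ~2.4 um radius).
#' @param depth Bleach depth (default 0.8).
#' @param extent_um Half-range of the profile in um (default 8).
#' @param step_um Sampling step in um (default 0.05).
#' @param noise Additive Gaussian noise (default 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns `distance_um`, `intensity`; the
#'   analytic effective radius is attached as attribute `"truth"`.
#' @export
gen_bleach_profile <- function(sigma_um = 1.2, depth = 0.8,
                               extent_um = 8, step_um = 0.05, noise = 0,
                               seed = NULL) {
  stopifnot(sigma_um > 0, depth > 0, depth <= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(-extent_um, extent_um, by = step_um)
  i_true <- 1 - depth * exp(-x^2 / (2 * sigma_um^2))
  out <- data.frame(distance_um = x,
                    intensity = i_true + stats::rnorm(length(x), 0, noise))
  attr(out, "truth") <- list(radius_um = sigma_um * sqrt(2 * log(1 / 0.14)))
  out
}

#' Simulate a DLS temperature ramp across a phase transition
#'
#' Logistic jump of the apparent hydrodynamic radius centred at the
#' programmed transition temperature, from the monomer radius (~5 nm) to
#' the condensate-particle radius (~1000 nm), sampled on a uniform
#' temperature grid (1 degC/min ramp with continuous acquisition).
#' Optionally generates the matched cooling ramp with a programmable
#' hysteresis shift. Multiplicative Gaussian noise on the radii.
#'
#' @param t_star_c Programmed transition temperature in degC.
#' @param r_low_nm Monomer radius in nm (default 5).
#' @param r_high_nm Condensate radius in nm (default 1000).
#' @param width_c Logistic width (scale) of the transition in degC
#'   (default 0.1: a sharp jump).
#' @param t_min_c,t_max_c Ramp range in degC (defaults 2 and 40).
#' @param step_c Sampling step in degC (default 0.5).
#' @param direction `"heating"` (default) or `"cooling"`.
#' @param hysteresis_c Shift of the cooling-ramp transition to lower
#'   temperature (default 0).
#' @param noise Relative Gaussian noise on radii (default 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns `temperature_c`, `radius_nm`,
#'   `direction`.
#' @export
gen_dls_ramp <- function(t_star_c, r_low_nm = 5, r_high_nm = 1000,
                         width_c = 0.1, t_min_c = 2, t_max_c = 40,
                         step_c = 0.5,
                         direction = c("heating", "cooling"),
                         hysteresis_c = 0, noise = 0, seed = NULL) {
  direction <- match.arg(direction)
  if (t_star_c <= t_min_c || t_star_c >= t_max_c) {
    stop("t_star must lie inside the ramp range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  temps <- seq(t_min_c, t_max_c, by = step_c)
  centre <- t_star_c
  if (direction == "cooling") {
    temps <- rev(temps)
    centre <- t_star_c - hysteresis_c
  }
  r <- r_low_nm + (r_high_nm - r_low_nm) /
    (1 + exp(-(temps - centre) / max(width_c, 1e-6)))
  r <- r * (1 + stats::rnorm(length(r), 0, noise))
  data.frame(temperature_c = temps, radius_nm = pmax(r, 1e-3),
             direction = direction)
}

#' Simulate a DLS correlogram for a monodisperse particle
#'
#' Single-exponential intensity autocorrelation
#' \eqn{g_2 - 1 = \beta e^{-2\Gamma\tau}} with
#' \eqn{\Gamma = D q^2} and D from Stokes-Einstein at the given radius,
#' sampled on a logarithmic lag grid covering the decay.
#'
#' @param radius_nm Particle hydrodynamic radius in nm.
#' @param temp_c Temperature in degC.
#' @param q Scattering vector in 1/m (default [scattering_vector()]).
#' @param beta Coherence factor (default 0.9).
#' @param n_lags Number of lag points (default 80).
#' @param noise Additive Gaussian noise on g2-1 (default 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns `lag_s`, `g2m1`.
#' @export
gen_correlogram <- function(radius_nm, temp_c, q = scattering_vector(),
                            beta = 0.9, n_lags = 80L, noise = 0,
                            seed = NULL) {
  stopifnot(radius_nm > 0, q > 0)
  if (!is.null(seed)) set.seed(seed)
  d_m2_s <- stokes_einstein_d(radius_nm, temp_c) * 1e-12
  gamma <- d_m2_s * q^2
  lag <- exp(seq(log(0.005 / gamma), log(4 / gamma),
                 length.out = n_lags))
  g <- beta * exp(-2 * gamma * lag)
  data.frame(lag_s = lag,
             g2m1 = g + stats::rnorm(n_lags, 0, noise))
}

#' Simulate a pair of shift tables with condition-dependent
#' perturbations
#'
#' Condition B equals condition A plus the supplied perturbations;
#' unperturbed resonances are identical in both tables.
#'
#' @param perturbations Data frame with columns `label` (atom labels
#'   matching the base table) and `d_ppm`.
#' @param base Base shift table (default [synthetic_shift_table()]).
#' @return A list with shift tables `a` and `b`.
#' @export
gen_shift_tables <- function(perturbations = NULL,
                             base = synthetic_shift_table()) {
  b <- base
  if (!is.null(perturbations)) {
    unknown <- setdiff(perturbations$label, base$label)
    if (length(unknown) > 0L) {
      stop(sprintf("perturbation names unknown atom(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    idx <- match(perturbations$label, b$label)
    b$shift_ppm[idx] <- b$shift_ppm[idx] + perturbations$d_ppm
  }
  list(a = base, b = b)
}

#' Simulate a NOESY peak list from a contact list
#'
#' Places one cross peak at the shift coordinates of each listed atom
#' pair (e.g. `"F4-HD~T8-HG"`), plus diagonal peaks for every proton
#' resonance in the table. Degenerate shifts in the table propagate to
#' ambiguous matches downstream.
#'
#' @param contacts Character vector of contacts, each `"label1~label2"`.
#' @param shifts Proton shift table with columns `label`, `shift_ppm`
#'   (default: the proton entries of [synthetic_shift_table()]).
#' @param include_diagonal Add diagonal peaks (default TRUE).
#' @param jitter Gaussian ppm jitter applied to peak coordinates
#'   (default 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns `w1`, `w2`, `intensity`,
#'   `assignment`.
#' @export
gen_noesy_peaks <- function(contacts, shifts = NULL,
                            include_diagonal = TRUE, jitter = 0,
                            seed = NULL) {
  if (is.null(shifts)) {
    shifts <- synthetic_shift_table()
    shifts <- shifts[shifts$atom != "N", ]  # proton dimension only
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ct in contacts) {
    pair <- strsplit(ct, "~", fixed = TRUE)[[1L]]
    if (length(pair) != 2L || !all(pair %in% shifts$label)) {
      stop(sprintf("contact '%s' names an unknown atom", ct),
           call. = FALSE)
    }
    w1 <- shifts$shift_ppm[match(pair[1L], shifts$label)]
    w2 <- shifts$shift_ppm[match(pair[2L], shifts$label)]
    rows[[length(rows) + 1L]] <- data.frame(
      w1 = w1, w2 = w2, intensity = 1e5,
      assignment = paste(pair, collapse = "-"))
  }
  if (include_diagonal) {
    for (i in seq_len(nrow(shifts))) {
      rows[[length(rows) + 1L]] <- data.frame(
        w1 = shifts$shift_ppm[i], w2 = shifts$shift_ppm[i],
        intensity = 1e6, assignment = paste0(shifts$label[i], "-diag"))
    }
  }
  out <- do.call(rbind, rows)
  if (jitter > 0) {
    out$w1 <- out$w1 + stats::rnorm(nrow(out), 0, jitter)
    out$w2 <- out$w2 + stats::rnorm(nrow(out), 0, jitter)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a centrifugation assay table
#'
#' Supernatant concentrations obey `sup = min(total, c_crit)` with
#' multiplicative Gaussian noise: below the critical concentration
#' nothing pellets, above it the dilute phase sits at c_crit.
#'
#' @param conditions Data frame with columns `temp_c`, `nacl_mm`,
#'   `c_crit_um` (the ground-truth critical-concentration surface).
#' @param totals_um Loaded total concentrations applied to every
#'   condition.
#' @param noise Relative Gaussian noise on supernatants (default 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns `total_um`, `supernatant_um`,
#'   `temp_c`, `nacl_mm`.
#' @export
gen_assay <- function(conditions, totals_um, noise = 0, seed = NULL) {
  stopifnot(all(c("temp_c", "nacl_mm", "c_crit_um") %in%
                  names(conditions)))
  if (any(conditions$c_crit_um <= 0)) {
    stop("c_crit must be > 0 everywhere", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    sup <- pmin(totals_um, conditions$c_crit_um[i])
    sup <- sup * (1 + stats::rnorm(length(sup), 0, noise))
    data.frame(total_um = totals_um, supernatant_um = pmax(sup, 0),
               temp_c = conditions$temp_c[i],
               nacl_mm = conditions$nacl_mm[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
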