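#' Detect the phase-transition temperature in a DLS temperature ramp
#'
#' Phase separation appears in a temperature ramp as a sharp increase of
#' the apparent hydrodynamic radius (monomers of ~5 nm giving way to
#' micrometre-scale condensate particles). The transition temperature is
#' the first temperature at which the radius exceeds a threshold
#' (`threshold_factor` times the running-baseline median, taken over the
#' first quartile of the ramp) and stays above it for `persistence`
#' consecutive points. The raw crossing temperature is refined by linear
#' interpolation between the bracketing samples and then rounded up to
#' the nearest 0.1 degC, the convention for reporting transition
#' temperatures from continuously acquired ramps.
#'
#' @param temperature_c Temperatures in degC, monotone within the ramp
#'   direction.
#' @param radius_nm Hydrodynamic radii in nm (> 0), same length.
#' @param threshold_factor Multiple of the baseline radius that counts as
#'   "sharp increase" (default 10).
#' @param persistence Number of consecutive above-threshold points
#'   required (default 3).
#' @return The transition temperature in degC (rounded up to 0.1), or
#'   `NA` if the ramp never crosses the threshold. The raw interpolated
#'   crossing is attached as attribute `"raw"`.
#' @export
detect_transition <- function(temperature_c, radius_nm,
                              threshold_factor = 10, persistence = 3) {
  n <- length(temperature_c)
  if (n != length(radius_nm)) {
    stop("temperature and radius must have the same length", call. = FALSE)
  }
  if (n < 10L) stop("at least 10 ramp points are required", call. = FALSE)
  if (any(radius_nm <= 0)) stop("radii must be > 0", call. = FALSE)
  dirs <- sign(diff(temperature_c))
  if (any(dirs > 0) && any(dirs < 0)) {
    stop("temperature must be monotone within a ramp direction",
         call. = FALSE)
  }
  if (all(dirs < 0)) {  # cooling ramp: analyse in increasing-T order
    temperature_c <- rev(temperature_c)
    radius_nm <- rev(radius_nm)
  }
  n_base <- max(3L, floor(n / 4))
  baseline <- stats::median(radius_nm[seq_len(n_base)])
  threshold <- threshold_factor * baseline
  above <- radius_nm > threshold
  idx <- NA_integer_
  for (i in seq_len(n - persistence + 1L)) {
    if (all(above[i:(i + persistence - 1L)])) {
      idx <- i
      break
    }
  }
  if (is.na(idx)) return(NA_real_)
  if (idx == 1L) {
    raw <- temperature_c[1L]
  } else {
    r0 <- radius_nm[idx - 1L]
    r1 <- radius_nm[idx]
    frac <- (threshold - r0) / (r1 - r0)
    raw <- temperature_c[idx - 1L] +
      frac * (temperature_c[idx] - temperature_c[idx - 1L])
  }
  tp <- ceiling(raw * 10 - 1e-9) / 10
  attr(tp, "raw") <- raw
  tp
}

#' Average replicate transition temperatures
#'
#' Arithmetic mean and sample standard deviation of replicate transition
#' temperatures, typically three ramps per condition. A single replicate
#' yields SD = 0 with a flag.
#'
#' @param t_p Numeric vector of transition temperatures in degC.
#' @return A list with `mean`, `sd`, `n` and `single_replicate`.
#' @export
aggregate_replicates <- function(t_p) {
  t_p <- t_p[is.finite(t_p)]
  if (length(t_p) == 0L) {
    stop("no finite transition temperatures to aggregate", call. = FALSE)
  }
  list(mean = mean(t_p),
       sd = if (length(t_p) > 1L) stats::sd(t_p) else 0,
       n = length(t_p),
       single_replicate = length(t_p) == 1L)
}

#' Assemble an LCST phase diagram from transition-temperature points
#'
#' Orders phase-boundary points by protein concentration within each salt
#' series and reports whether the boundary is consistent with
#' lower-critical-solution-temperature behaviour: the transition
#' temperature decreasing with concentration within each series, and
#' every transition temperature decreasing as the salt concentration
#' rises (salt enhancement of the hydrophobically driven separation).
#'
#' @param points Data frame with columns `protein_conc_um`, `nacl_mm`,
#'   `t_p_c` and optionally `t_p_sd_c`, `n_replicates`.
#' @return A list with `diagram` (the points sorted by salt then
#'   concentration), `lcst_consistent` (logical per salt series, named)
#'   and `salt_enhancement` (single logical, `NA` with fewer than two
#'   salt series).
#' @export
build_phase_diagram <- function(points) {
  required <- c("protein_conc_um", "nacl_mm", "t_p_c")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(points) == 0L) {
    return(list(diagram = points, lcst_consistent = logical(0),
                salt_enhancement = NA))
  }
  dup <- duplicated(points[, c("protein_conc_um", "nacl_mm")])
  if (any(dup)) {
    warning("duplicate (concentration, salt) points kept as-is")
  }
  o <- order(points$nacl_mm, points$protein_conc_um)
  diagram <- points[o, , drop = FALSE]
  rownames(diagram) <- NULL
  salts <- sort(unique(diagram$nacl_mm))
  lcst <- vapply(salts, function(s) {
    tp <- diagram$t_p_c[diagram$nacl_mm == s]
    length(tp) < 2L || all(diff(tp) <= 0)
  }, logical(1L))
  names(lcst) <- as.character(salts)
  salt_enh <- NA
  if (length(salts) >= 2L) {
    # compare series pairwise on shared concentrations
    pairs_ok <- logical(0)
    for (i in seq_len(length(salts) - 1L)) {
      lo <- diagram[diagram$nacl_mm == salts[i], ]
      hi <- diagram[diagram$nacl_mm == salts[i + 1L], ]
      shared <- intersect(lo$protein_conc_um, hi$protein_conc_um)
      if (length(shared) == 0L) next
      tp_lo <- lo$t_p_c[match(shared, lo$protein_conc_um)]
      tp_hi <- hi$t_p_c[match(shared, hi$protein_conc_um)]
      pairs_ok <- c(pairs_ok, all(tp_hi <= tp_lo))
    }
    if (length(pairs_ok) > 0L) salt_enh <- all(pairs_ok)
  }
  list(diagram = diagram, lcst_consistent = lcst,
       salt_enhancement = salt_enh)
}

#' Scattering vector of a DLS instrument
#'
#' \eqn{q = 4\pi n \sin(\theta/2)/\lambda}.
#'
#' @param wavelength_nm Laser wavelength in nm (default 658).
#' @param angle_deg Scattering angle in degrees (default 90).
#' @param refractive_index Solvent refractive index (default 1.33).
#' @return q in 1/m.
#' @export
scattering_vector <- function(wavelength_nm = 658, angle_deg = 90,
                              refractive_index = 1.33) {
  4 * pi * refractive_index * sin(angle_deg * pi / 360) /
    (wavelength_nm * 1e-9)
}

#' Hydrodynamic radius from a DLS correlogram by cumulant analysis
#'
#' First-cumulant analysis of the intensity autocorrelation function:
#' fits \eqn{g_2(\tau) - 1 = \beta e^{-2\Gamma\tau}}, converts the decay
#' rate to a diffusion coefficient \eqn{D = \Gamma/q^2} and to a radius
#' via Stokes-Einstein.
#'
#' @param lag_s Lag times in s.
#' @param g2m1 The measured \eqn{g_2 - 1} values.
#' @param temp_c Sample temperature in degC.
#' @param q Scattering vector in 1/m; defaults to [scattering_vector()]
#'   with its default optics.
#' @param viscosity Solvent viscosity in Pa s; defaults to water at
#'   `temp_c`.
#' @return Hydrodynamic radius in nm.
#' @export
cumulant_radius <- function(lag_s, g2m1, temp_c, q = scattering_vector(),
                            viscosity = NULL) {
  if (length(lag_s) != length(g2m1)) {
    stop("lag times and g2-1 must have the same length", call. = FALSE)
  }
  if (q <= 0) stop("q must be > 0", call. = FALSE)
  pos <- g2m1 > 0
  if (sum(pos) < 3L || g2m1[which.max(lag_s)] >= max(g2m1)) {
    stop("correlogram does not decay", call. = FALSE)
  }
  cf <- stats::coef(stats::lm(log(g2m1[pos]) ~ lag_s[pos]))
  if (cf[[2L]] >= 0) stop("correlogram does not decay", call. = FALSE)
  start <- list(beta = exp(cf[[1L]]), gamma = -cf[[2L]] / 2)
  fit <- minpack.lm::nlsLM(g2m1 ~ beta * exp(-2 * gamma * lag_s),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  gamma <- stats::coef(fit)[["gamma"]]
  d_m2_s <- gamma / q^2
  eta <- .viscosity_or_water(viscosity, temp_c)
  t_k <- .celsius_to_kelvin(temp_c)
  r_m <- .kB * t_k / (6 * pi * eta * d_m2_s)
  r_m * 1e9
}

#' Heating/cooling hysteresis of the phase transition
#'
#' Reversibility metric: absolute difference between the transition
#' temperatures detected on the heating and cooling ramps; zero for a
#' fully reversible transition.
#'
#' @param tp_heat,tp_cool Transition temperatures in degC.
#' @return Absolute difference in degC (`NA` if either is missing).
#' @export
transition_hysteresis <- function(tp_heat, tp_cool) {
  if (!is.finite(tp_heat) || !is.finite(tp_cool)) return(NA_real_)
  abs(tp_heat - tp_cool)
}
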