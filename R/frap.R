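#' Normalize a FRAP time course
#'
#' Corrects the bleached-ROI trace for photobleaching during acquisition
#' using an unbleached reference ROI (the ROI is divided by the reference
#' rescaled to its initial value) and normalizes so that the corrected
#' prebleach level maps to 1. The first postbleach value then reflects the
#' bleach depth. If no reference trace is supplied the correction is
#' skipped with a warning rather than inventing a decay model.
#'
#' @param times Postbleach times in s, strictly increasing, starting at
#'   the first acquired frame.
#' @param roi Bleached-ROI signal, arbitrary units.
#' @param prebleach_level Mean ROI signal before the bleach (> 0).
#' @param reference Optional unbleached reference-ROI trace, same length
#'   as `roi`.
#' @return A data frame with columns `time_s` and `c_norm` (the
#'   normalized signal C(t) on \[0, 1\]).
#' @export
frap_normalize <- function(times, roi, prebleach_level, reference = NULL) {
  if (length(times) != length(roi)) {
    stop("times and roi must have the same length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (prebleach_level <= 0) {
    stop("prebleach level must be > 0", call. = FALSE)
  }
  if (!is.null(reference)) {
    if (length(reference) != length(roi)) {
      stop("reference must have the same length as roi", call. = FALSE)
    }
    if (any(reference <= 0)) {
      stop("reference trace reaches zero; cannot correct", call. = FALSE)
    }
    roi <- roi / (reference / reference[1L])
  } else {
    warning("no reference trace supplied; acquisition-bleaching correction skipped")
  }
  data.frame(time_s = times, c_norm = roi / prebleach_level)
}

#' Fit an exponential FRAP recovery curve
#'
#' Fits the simple exponential recovery model
#' \eqn{C(t) = A(1 - e^{-t/\tau})} to the recovered fraction of the
#' bleached signal. The input trace is normalized so prebleach = 1; the
#' fit internally rescales it so that the first postbleach frame maps to
#' 0 and full recovery to 1, hence A (close to 1) measures the mobile
#' fraction and 1 - A the immobile fraction. Traces recovering less than
#' 10% of the bleach depth are classified immobile (`tau` is `NA`), as
#' for wild-type Mac98A-like condensates that show essentially no
#' recovery.
#'
#' @param times Postbleach times in s (t = 0 at bleach end), >= 5 points.
#' @param c_norm Normalized signal from [frap_normalize()].
#' @return A list with `A`, `tau` (s), `t_half` (s), `immobile`,
#'   `bleach_floor` (C at the first postbleach frame), and standard
#'   errors `A_sd`, `tau_sd`.
#' @export
fit_recovery <- function(times, c_norm) {
  if (length(times) < 5L) {
    stop("at least 5 time points are required", call. = FALSE)
  }
  t0 <- times[1L]
  tt <- times - t0
  floor0 <- c_norm[1L]
  depth <- 1 - floor0
  if (depth <= 0) {
    stop("first postbleach level must be below the prebleach level",
         call. = FALSE)
  }
  rec <- (c_norm - floor0) / depth
  if (max(rec) - rec[1L] < 0.1) {
    return(list(A = NA_real_, tau = NA_real_, t_half = NA_real_,
                immobile = TRUE, bleach_floor = floor0,
                A_sd = NA_real_, tau_sd = NA_real_))
  }
  # crude tau start: time to reach 63% of the observed plateau
  plateau <- max(rec)
  i63 <- which(rec >= 0.632 * plateau)[1L]
  tau0 <- max(tt[i63], diff(range(tt)) / 20)
  fit <- minpack.lm::nlsLM(rec ~ A * (1 - exp(-tt / tau)),
                           start = list(A = plateau, tau = tau0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA_real_, tau = NA_real_))
  se[!is.finite(se)] <- 0
  tau <- unname(est[["tau"]])
  list(A = unname(est[["A"]]), tau = tau, t_half = half_time(tau),
       immobile = FALSE, bleach_floor = floor0,
       A_sd = unname(se[["A"]]), tau_sd = unname(se[["tau"]]))
}

#' Recovery half-time from the exponential time constant
#'
#' \eqn{t_{1/2} = -\ln(0.5)\,\tau}.
#'
#' @param tau Exponential time constant in s (> 0).
#' @return Half-time in s.
#' @export
half_time <- function(tau) {
  if (any(tau <= 0)) stop("tau must be > 0", call. = FALSE)
  -log(0.5) * tau
}

#' Translational diffusion coefficient from a FRAP half-time
#'
#' \eqn{D = 0.224\,R^2 / t_{1/2}} for a circular bleach spot of radius R.
#'
#' @param t_half Recovery half-time in s (> 0).
#' @param radius_um Effective bleach-spot radius in um (> 0).
#' @return Diffusion coefficient in um^2/s.
#' @export
diffusion_coefficient <- function(t_half, radius_um) {
  if (any(t_half <= 0) || any(radius_um <= 0)) {
    stop("t_half and radius must be > 0", call. = FALSE)
  }
  0.224 * radius_um^2 / t_half
}

#' Effective bleach radius from a postbleach radial profile
#'
#' The effective radius is the half-width of the bleached dip measured at
#' 86% of the bleach depth above the dip minimum (i.e. where the profile
#' crosses the level baseline - 0.14 x depth), with linear interpolation
#' between samples. For a laser spot blurred by diffusion during
#' bleaching this is substantially larger than the nominal bleach radius.
#'
#' @param distance_um Radial (or linear) position in um, increasing, with
#'   the dip interior to the range.
#' @param intensity Postbleach intensity profile.
#' @return Effective radius in um.
#' @export
bleach_radius <- function(distance_um, intensity) {
  if (length(distance_um) != length(intensity)) {
    stop("distance and intensity must have the same length", call. = FALSE)
  }
  n <- length(intensity)
  n_edge <- max(2L, floor(n * 0.1))
  baseline <- stats::median(c(utils::head(intensity, n_edge),
                              utils::tail(intensity, n_edge)))
  i_min <- which.min(intensity)
  depth <- baseline - intensity[i_min]
  if (depth <= 0) stop("profile has no bleached dip", call. = FALSE)
  level <- baseline - 0.14 * depth
  cross <- function(idx_seq) {
    # first crossing of `level` walking outward from the minimum
    for (k in seq_len(length(idx_seq) - 1L)) {
      i <- idx_seq[k]
      j <- idx_seq[k + 1L]
      if ((intensity[i] - level) * (intensity[j] - level) <= 0 &&
          intensity[i] != intensity[j]) {
        frac <- (level - intensity[i]) / (intensity[j] - intensity[i])
        return(distance_um[i] + frac * (distance_um[j] - distance_um[i]))
      }
    }
    NA_real_
  }
  x_left <- cross(seq(i_min, 1L))
  x_right <- cross(seq(i_min, n))
  if (!is.finite(x_left) || !is.finite(x_right)) {
    stop("profile never recovers to the 86%-depth level on both sides",
         call. = FALSE)
  }
  (x_right - x_left) / 2
}

#' Fit a set of replicate FRAP curves and summarise the diffusion
#' coefficient
#'
#' Each replicate curve is normalized and fitted independently; the
#' diffusion coefficient is reported per replicate and as mean +/- SD
#' across replicates, as is standard for n = 5 bleached condensate
#' particles.
#'
#' @param curves A list of data frames with columns `time_s`, `roi` and
#'   optionally `reference`.
#' @param prebleach_level Prebleach signal level (recycled across
#'   replicates if scalar).
#' @param radius_um Effective bleach radius in um, applied to every
#'   replicate.
#' @return A list with `per_replicate` (data frame: `replicate`, `A`,
#'   `tau_s`, `t_half_s`, `d_um2_s`, `immobile`) and `summary` (mean and
#'   SD of D over the mobile replicates).
#' @export
run_frap <- function(curves, prebleach_level, radius_um) {
  stopifnot(length(curves) >= 1L)
  pre <- rep_len(prebleach_level, length(curves))
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    ref <- if ("reference" %in% names(cv)) cv$reference else NULL
    norm <- frap_normalize(cv$time_s, cv$roi, pre[i], reference = ref)
    fit <- fit_recovery(norm$time_s, norm$c_norm)
    d <- if (fit$immobile) NA_real_ else {
      diffusion_coefficient(fit$t_half, radius_um)
    }
    data.frame(replicate = i, A = fit$A, tau_s = fit$tau,
               t_half_s = fit$t_half, d_um2_s = d,
               immobile = fit$immobile)
  })
  per <- do.call(rbind, rows)
  mobile <- per$d_um2_s[!per$immobile]
  list(per_replicate = per,
       summary = data.frame(
         n_mobile = length(mobile),
         d_mean_um2_s = if (length(mobile) > 0L) mean(mobile) else NA_real_,
         d_sd_um2_s = if (length(mobile) > 1L) stats::sd(mobile) else NA_real_))
}
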