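#' Critical concentration from centrifugation supernatants
#'
#' After phase separation the dilute (aqueous) phase sits at the critical
#' (saturation) concentration, so the supernatant concentration after
#' pelleting the condensed phase estimates c_crit directly. Points where
#' the supernatant equals the loaded total (within `sep_tol` relative)
#' did not separate; if no point separated the largest total is returned
#' as a lower bound with a flag.
#'
#' @param total_um Loaded total concentrations, uM.
#' @param supernatant_um Measured supernatant concentrations, uM.
#' @param sep_tol Relative tolerance below which supernatant == total is
#'   treated as "no separation" (default 0.05).
#' @return A list with `c_crit_um`, `is_lower_bound_only`, `n_separated`.
#' @export
estimate_critical_conc <- function(total_um, supernatant_um,
                                   sep_tol = 0.05) {
  if (length(total_um) != length(supernatant_um) ||
      length(total_um) == 0L) {
    stop("need matching, non-empty total and supernatant vectors",
         call. = FALSE)
  }
  if (any(supernatant_um < 0) || any(total_um <= 0)) {
    stop("concentrations must be non-negative (totals positive)",
         call. = FALSE)
  }
  separated <- supernatant_um < (1 - sep_tol) * total_um
  if (!any(separated)) {
    return(list(c_crit_um = max(total_um), is_lower_bound_only = TRUE,
                n_separated = 0L))
  }
  list(c_crit_um = mean(supernatant_um[separated]),
       is_lower_bound_only = FALSE,
       n_separated = sum(separated))
}

#' Partition coefficient of a probe into a condensed phase
#'
#' Ratio of probe signal inside the condensed phase to the signal in the
#' surrounding buffer. A zero outside signal cannot give a finite ratio:
#' the result is then reported as a lower bound at the detection floor.
#'
#' @param signal_in Signal inside the phase (>= 0).
#' @param signal_out Signal in the buffer (>= 0).
#' @param detection_floor Fraction of `signal_in` taken as the smallest
#'   detectable outside signal when `signal_out` is zero (default 0.001).
#' @return A list with `value` and `is_lower_bound`.
#' @export
partition_coefficient <- function(signal_in, signal_out,
                                  detection_floor = 0.001) {
  if (signal_in < 0 || signal_out < 0) {
    stop("signals must be >= 0", call. = FALSE)
  }
  if (signal_out == 0) {
    return(list(value = 1 / detection_floor, is_lower_bound = TRUE))
  }
  list(value = signal_in / signal_out, is_lower_bound = FALSE)
}

#' Enrichment factor of phase separation
#'
#' Fold concentration of the protein in the condensed phase relative to
#' the starting solution, e.g. 260 mg/ml in the condensed phase from a
#' 1.2 mg/ml dilution is a >200-fold enrichment.
#'
#' @param phase_conc Concentration in the condensed phase.
#' @param starting_conc Starting (total) concentration, same units.
#' @return Fold enrichment.
#' @export
enrichment_factor <- function(phase_conc, starting_conc) {
  if (any(phase_conc <= 0) || any(starting_conc <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  phase_conc / starting_conc
}

#' Critical-concentration table across conditions
#'
#' Applies [estimate_critical_conc()] per (temperature, salt) condition
#' of a centrifugation-assay table.
#'
#' @param assay Data frame with columns `total_um`, `supernatant_um`,
#'   `temp_c`, `nacl_mm`.
#' @param sep_tol Passed to [estimate_critical_conc()].
#' @return Data frame with one row per condition: `temp_c`, `nacl_mm`,
#'   `c_crit_um`, `is_lower_bound_only`, `n_separated`.
#' @export
critical_conc_by_condition <- function(assay, sep_tol = 0.05) {
  required <- c("total_um", "supernatant_um", "temp_c", "nacl_mm")
  missing_cols <- setdiff(required, names(assay))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(assay$temp_c, assay$nacl_mm, drop = TRUE)
  rows <- lapply(split(assay, key), function(sub) {
    est <- estimate_critical_conc(sub$total_um, sub$supernatant_um,
                                  sep_tol = sep_tol)
    data.frame(temp_c = sub$temp_c[1L], nacl_mm = sub$nacl_mm[1L],
               c_crit_um = est$c_crit_um,
               is_lower_bound_only = est$is_lower_bound_only,
               n_separated = est$n_separated)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$temp_c, out$nacl_mm), ]
  rownames(out) <- NULL
  out
}
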