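#' Construct a perfectly repetitive protein sequence
#'
#' Builds an engineered repeat protein from a single repeat unit, e.g. the
#' 52-fold concatenation of the 12-mer `GGLFGGNTQPAT` that mimics a Nup98-type
#' FG domain. Only the 20 canonical one-letter codes are accepted.
#'
#' @param unit Amino-acid string of one repeat unit (one-letter codes).
#' @param n_repeats Number of times the unit is concatenated (positive integer).
#' @return An object of class `repeat_sequence` with fields `unit`,
#'   `n_repeats` and `full_sequence`.
#' @examples
#' rs <- build_repeat_sequence("GGLFGGNTQPAT", 52)
#' nchar(rs$full_sequence)  # 624
#' @export
build_repeat_sequence <- function(unit, n_repeats) {
  res <- .split_residues(unit)
  if (!is.numeric(n_repeats) || length(n_repeats) != 1L ||
      n_repeats < 1 || n_repeats != round(n_repeats)) {
    stop("n_repeats must be a positive integer", call. = FALSE)
  }
  unit <- paste(res, collapse = "")
  structure(
    list(unit = unit,
         n_repeats = as.integer(n_repeats),
         full_sequence = strrep(unit, n_repeats)),
    class = "repeat_sequence"
  )
}

#' @export
print.repeat_sequence <- function(x, ...) {
  cat(sprintf("Repeat sequence: %d x %d-mer '%s' (%d residues)\n",
              x$n_repeats, nchar(x$unit), x$unit, nchar(x$full_sequence)))
  invisible(x)
}

.as_sequence_string <- function(seq) {
  if (inherits(seq, "repeat_sequence")) seq$full_sequence else seq
}

#' Count occurrences of a sequence motif
#'
#' Counts non-overlapping occurrences of a motif (default `"FG"`) in a
#' sequence, e.g. 52 FG motifs in the 52x12 repeat protein.
#'
#' @param seq Amino-acid string or a [build_repeat_sequence()] object.
#' @param motif Motif string, default `"FG"`.
#' @return Integer count.
#' @export
count_motif <- function(seq, motif = "FG") {
  seq <- .as_sequence_string(seq)
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  if (length(hits) == 1L && hits[1L] == -1L) 0L else length(hits)
}

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water (18.015 Da). Average masses
#' are appropriate for dry-weight quantification of unlabelled protein.
#'
#' @inheritParams count_motif
#' @return Mass in Da.
#' @examples
#' molecular_weight("GGLFGGNTQPAT")  # ~1119.2
#' @export
molecular_weight <- function(seq) {
  seq <- .as_sequence_string(seq)
  res <- .split_residues(seq)
  sum(.RESIDUE_MASS[res]) + .WATER_MASS
}

#' Convert molar to mass concentration
#'
#' @param c_molar Concentration in mol/L.
#' @param mw Molecular mass in Da (g/mol).
#' @return Mass concentration in mg/ml (= g/L).
#' @examples
#' molar_to_mass_conc(1e-3, 60000)  # 60 mg/ml
#' @export
molar_to_mass_conc <- function(c_molar, mw) {
  if (any(c_molar < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(mw <= 0)) stop("molecular weight must be > 0", call. = FALSE)
  c_molar * mw
}

#' Convert mass to molar concentration
#'
#' Inverse of [molar_to_mass_conc()].
#'
#' @param c_mg_ml Mass concentration in mg/ml.
#' @param mw Molecular mass in Da.
#' @return Concentration in mol/L.
#' @export
mass_to_molar_conc <- function(c_mg_ml, mw) {
  if (any(c_mg_ml < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(mw <= 0)) stop("molecular weight must be > 0", call. = FALSE)
  c_mg_ml / mw
}

#' Motif molarity from chain molarity
#'
#' A 4.5 mM solution of a 52-motif chain corresponds to 234 mM of motifs.
#'
#' @param c_chain Chain concentration (any molar unit).
#' @param motifs_per_chain Motif count per chain.
#' @return Motif concentration in the same unit as `c_chain`.
#' @export
motif_molarity <- function(c_chain, motifs_per_chain) {
  if (any(c_chain < 0) || any(motifs_per_chain < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  c_chain * motifs_per_chain
}

#' Local concentration of copies confined to a sphere
#'
#' Effective molar concentration of `n_copies` groups confined within a
#' sphere of given radius, e.g. 52 FG motifs within a chain of ~5 nm
#' hydrodynamic radius give ~165 mM.
#'
#' @param n_copies Number of copies (>= 1).
#' @param radius_nm Sphere radius in nm (> 0).
#' @return Concentration in mol/L.
#' @export
sphere_local_concentration <- function(n_copies, radius_nm) {
  if (any(n_copies < 1)) stop("n_copies must be >= 1", call. = FALSE)
  if (any(radius_nm <= 0)) stop("radius must be > 0", call. = FALSE)
  r_dm <- radius_nm * 1e-8          # nm -> dm so the volume is in litres
  vol_l <- (4 / 3) * pi * r_dm^3
  n_copies / (.N_AVOGADRO * vol_l)
}

#' Dynamic viscosity of pure water
#'
#' Vogel-type empirical correlation
#' \eqn{\eta(T) = A \cdot 10^{B/(T - C)}} with A = 2.414e-5 Pa s,
#' B = 247.8 K, C = 140 K, accurate to well under 1% between 0 and 40 degC.
#' Buffer additives are neglected.
#'
#' @param temp_c Temperature in degrees Celsius, 0 < T < 100.
#' @return Viscosity in Pa s.
#' @examples
#' water_viscosity(20)  # ~1.002e-3
#' @export
water_viscosity <- function(temp_c) {
  t_k <- .celsius_to_kelvin(temp_c)
  if (any(t_k <= 273.15) || any(t_k >= 373.15)) {
    stop("temperature must be between 0 and 100 degC (liquid water)",
         call. = FALSE)
  }
  2.414e-5 * 10^(247.8 / (t_k - 140))
}

#' Hydrated Stokes radius of a globular protein
#'
#' Bare radius of the anhydrous sphere from the partial specific volume,
#' \eqn{r = (3 M \bar v / (4\pi N_A))^{1/3}}, plus a hydration shell.
#'
#' @param mw Molecular mass in Da.
#' @param vbar Partial specific volume in cm^3/g (default 0.73, standard
#'   for proteins).
#' @param hydration_a Hydration layer thickness in Angstrom (default 3.2).
#' @return Radius in Angstrom.
#' @export
hydrated_radius <- function(mw, vbar = 0.73, hydration_a = 3.2) {
  if (any(mw <= 0)) stop("molecular weight must be > 0", call. = FALSE)
  if (any(vbar <= 0)) stop("vbar must be > 0", call. = FALSE)
  if (any(hydration_a < 0)) stop("hydration layer must be >= 0", call. = FALSE)
  vol_cm3 <- mw * vbar / .N_AVOGADRO
  r_cm <- (3 * vol_cm3 / (4 * pi))^(1 / 3)
  r_cm * 1e8 + hydration_a
}

.viscosity_or_water <- function(viscosity, temp_c) {
  if (is.null(viscosity)) water_viscosity(temp_c) else viscosity
}

#' Stokes-law rotational correlation time of a sphere
#'
#' Stokes-Einstein-Debye prediction
#' \eqn{\tau_c = 4\pi\eta r^3/(3 k_B T)} for a rigid sphere tumbling in a
#' solvent. Used to predict the correlation time expected if a repeat
#' protein tumbled as a whole.
#'
#' @param radius_a Hydrated radius in Angstrom.
#' @param temp_c Temperature in degrees Celsius.
#' @param viscosity Solvent viscosity in Pa s; defaults to pure water at
#'   `temp_c`.
#' @return Rotational correlation time in ns.
#' @export
stokes_tau_c <- function(radius_a, temp_c, viscosity = NULL) {
  if (any(radius_a <= 0)) stop("radius must be > 0", call. = FALSE)
  eta <- .viscosity_or_water(viscosity, temp_c)
  t_k <- .celsius_to_kelvin(temp_c)
  r_m <- radius_a * 1e-10
  tau_s <- 4 * pi * eta * r_m^3 / (3 * .kB * t_k)
  tau_s * 1e9
}

#' Stokes-Einstein translational diffusion coefficient
#'
#' \eqn{D = k_B T / (6\pi\eta r)} for a sphere.
#'
#' @param radius_nm Hydrodynamic radius in nm.
#' @inheritParams stokes_tau_c
#' @return Diffusion coefficient in um^2/s.
#' @export
stokes_einstein_d <- function(radius_nm, temp_c, viscosity = NULL) {
  if (any(radius_nm <= 0)) stop("radius must be > 0", call. = FALSE)
  eta <- .viscosity_or_water(viscosity, temp_c)
  t_k <- .celsius_to_kelvin(temp_c)
  r_m <- radius_nm * 1e-9
  d_m2_s <- .kB * t_k / (6 * pi * eta * r_m)
  d_m2_s * 1e12
}

#' Hydrodynamic predictions for a repeat protein
#'
#' One-stop closed-form summary for an engineered repeat sequence: molecular
#' mass, motif count, hydrated Stokes radius and the rigid-sphere
#' predictions for the rotational correlation time and translational
#' diffusion coefficient.
#'
#' @inheritParams build_repeat_sequence
#' @param temp_c Temperature in degrees Celsius (default 24).
#' @param vbar Partial specific volume in cm^3/g.
#' @param hydration_a Hydration layer in Angstrom.
#' @param motif Motif to count (default `"FG"`).
#' @return A one-row data frame with columns `n_repeats`, `n_residues`,
#'   `mw_da`, `n_motifs`, `radius_a`, `tau_c_ns`, `d_um2_s`.
#' @examples
#' hydrodynamic_predictions("GGLFGGNTQPAT", 52, temp_c = 24)
#' @export
hydrodynamic_predictions <- function(unit, n_repeats, temp_c = 24,
                                     vbar = 0.73, hydration_a = 3.2,
                                     motif = "FG") {
  rs <- build_repeat_sequence(unit, n_repeats)
  mw <- molecular_weight(rs)
  r_a <- hydrated_radius(mw, vbar = vbar, hydration_a = hydration_a)
  data.frame(
    n_repeats = rs$n_repeats,
    n_residues = nchar(rs$full_sequence),
    mw_da = mw,
    n_motifs = count_motif(rs, motif),
    radius_a = r_a,
    tau_c_ns = stokes_tau_c(r_a, temp_c),
    d_um2_s = stokes_einstein_d(r_a / 10, temp_c)
  )
}
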