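#' Expected number of backbone amide peaks for a repeat unit
#'
#' In a 15N-1H correlation spectrum of a perfectly repetitive sequence,
#' every residue position of the repeat unit gives one peak except
#' proline, which lacks an amide proton. The 12-mer GGLFGGNTQPAT thus
#' shows 11 backbone amide peaks.
#'
#' @param unit Amino-acid string of the repeat unit.
#' @return Integer count of expected amide peaks.
#' @export
expected_amide_peaks <- function(unit) {
  res <- .split_residues(unit)
  sum(res != "P")
}

#' Aromatic CH multiplicity pattern of a residue
#'
#' Expected number of non-equivalent aromatic CH environments and their
#' relative intensities under fast ring flipping: phenylalanine shows
#' three environments at 2:2:1 (delta, epsilon, zeta), tyrosine two at
#' 2:2 (the zeta carbon bears the hydroxyl), histidine and tryptophan
#' their single-proton patterns. Non-aromatic residues give an empty
#' pattern.
#'
#' @param residue One-letter amino-acid code.
#' @return Named numeric vector of relative intensities (possibly empty).
#' @export
aromatic_multiplicity <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L)
  switch(toupper(residue),
         F = c(delta = 2, epsilon = 2, zeta = 1),
         Y = c(delta = 2, epsilon = 2),
         H = c(delta2 = 1, epsilon1 = 1),
         W = c(delta1 = 1, epsilon3 = 1, zeta2 = 1, zeta3 = 1, eta2 = 1),
         stats::setNames(numeric(0), character(0)))
}

# Parse atom labels of the form "F4-HD" / "T12-HG" / "G1-HN" into
# residue letter, position within the repeat unit, and atom name.
.parse_atom_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)-([A-Za-z0-9]+)$", label))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) {
    stop(sprintf("malformed atom label(s): %s",
                 paste(label[bad], collapse = ", ")), call. = FALSE)
  }
  data.frame(label = label,
             residue = toupper(vapply(m, `[`, character(1L), 2L)),
             position = as.integer(vapply(m, `[`, character(1L), 3L)),
             atom = toupper(vapply(m, `[`, character(1L), 4L)))
}

#' Chemical shift perturbation between two conditions
#'
#' Combined amide chemical shift perturbation per residue position,
#' \eqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (w_N\,\Delta\delta_N)^2}}
#' with the conventional nitrogen weight \eqn{w_N = 0.2}. Residues whose
#' combined perturbation exceeds the mean of the profile are flagged, the
#' usual screen for sites involved in condition-dependent interactions.
#'
#' @param a,b Shift tables: data frames with columns `position`,
#'   `residue`, `atom` (`"HN"` and `"N"` entries are used) and
#'   `shift_ppm`, for the two conditions.
#' @param w_n Weight applied to the 15N shift difference (default 0.2).
#' @return Data frame with one row per shared residue position:
#'   `position`, `residue`, `d_h_ppm`, `d_n_ppm`, `csp_ppm`,
#'   `above_average`.
#' @export
csp <- function(a, b, w_n = 0.2) {
  key <- function(tab) paste(tab$position, tab$atom, sep = "/")
  shared <- intersect(key(a), key(b))
  if (length(shared) == 0L) {
    stop("the two shift tables share no (position, atom) keys",
         call. = FALSE)
  }
  amide <- function(tab, atom) {
    sub <- tab[tab$atom == atom, ]
    stats::setNames(sub$shift_ppm, sub$position)
  }
  ha <- amide(a, "HN"); hb <- amide(b, "HN")
  na <- amide(a, "N");  nb <- amide(b, "N")
  pos <- sort(as.integer(intersect(names(ha), names(hb))))
  if (length(pos) == 0L) {
    stop("no shared amide (HN) entries between the tables", call. = FALSE)
  }
  d_h <- hb[as.character(pos)] - ha[as.character(pos)]
  d_n <- rep(0, length(pos))
  pos_n <- intersect(as.character(pos), intersect(names(na), names(nb)))
  d_n[match(pos_n, as.character(pos))] <- nb[pos_n] - na[pos_n]
  combined <- sqrt(d_h^2 + (w_n * d_n)^2)
  res_letters <- a$residue[match(pos, a$position)]
  out <- data.frame(position = pos, residue = res_letters,
                    d_h_ppm = unname(d_h), d_n_ppm = unname(d_n),
                    csp_ppm = unname(combined),
                    above_average = unname(combined > mean(combined)))
  rownames(out) <- NULL
  out
}

# circular separation of two positions on a repeat unit of length L:
# position L of one repeat adjoins position 1 of the next, because the
# repeats are indistinguishable by NMR
.circular_distance <- function(p1, p2, unit_length) {
  d <- abs(p1 - p2)
  pmin(d, unit_length - d)
}

#' Classify NOESY cross peaks into contact categories
#'
#' Matches each cross peak to all proton resonances within the matching
#' tolerance on each axis, lists every candidate atom pair when shifts
#' are degenerate (ambiguity is reported, never resolved), and
#' categorizes contacts by the circular sequential convention of a
#' perfectly repetitive sequence: positions are sequential when they are
#' adjacent within the repeat or across the junction between consecutive
#' repeats, and long-range at circular separation >= 2. Peaks on the
#' spectrum diagonal stem mostly from untransferred magnetization and are
#' flagged and excluded from the contact categories; peaks matching no
#' resonance are reported as orphans.
#'
#' @param peaks Data frame with columns `w1`, `w2` (ppm) and optionally
#'   `intensity`, `assignment`.
#' @param shifts Proton shift table: data frame with columns `label`
#'   (e.g. `"F4-HD"`) and `shift_ppm`.
#' @param unit_length Length of the repeat unit (default 12).
#' @param tol_ppm Matching tolerance per axis in ppm (default 0.03).
#' @param diagonal_tol_ppm `|w1 - w2|` below which a peak is diagonal
#'   (default 0.05).
#' @return A list with `contacts` (data frame: `peak`, `w1`, `w2`,
#'   `category`, `n_candidates`, `ambiguous`, `candidates` as a
#'   semicolon-separated pair list), `diagonal` (row indices of diagonal
#'   peaks) and `orphans` (row indices of unmatched peaks).
#' @export
classify_noe <- function(peaks, shifts, unit_length = 12,
                         tol_ppm = 0.03, diagonal_tol_ppm = 0.05) {
  if (!all(c("w1", "w2") %in% names(peaks))) {
    stop("peaks must have columns w1 and w2", call. = FALSE)
  }
  if (!all(c("label", "shift_ppm") %in% names(shifts))) {
    stop("shifts must have columns label and shift_ppm", call. = FALSE)
  }
  atoms <- .parse_atom_label(shifts$label)
  atoms$shift_ppm <- shifts$shift_ppm
  contacts <- list()
  diagonal <- integer(0)
  orphans <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    w1 <- peaks$w1[i]; w2 <- peaks$w2[i]
    if (abs(w1 - w2) < diagonal_tol_ppm) {
      diagonal <- c(diagonal, i)
      next
    }
    c1 <- which(abs(atoms$shift_ppm - w1) <= tol_ppm)
    c2 <- which(abs(atoms$shift_ppm - w2) <= tol_ppm)
    if (length(c1) == 0L || length(c2) == 0L) {
      orphans <- c(orphans, i)
      next
    }
    pairs <- expand.grid(a1 = c1, a2 = c2)
    pairs <- pairs[atoms$label[pairs$a1] != atoms$label[pairs$a2], ,
                   drop = FALSE]
    if (nrow(pairs) == 0L) {
      orphans <- c(orphans, i)
      next
    }
    dsep <- .circular_distance(atoms$position[pairs$a1],
                               atoms$position[pairs$a2], unit_length)
    category <- ifelse(dsep == 0, "intra-residue",
                       ifelse(dsep == 1, "sequential", "long-range"))
    # with degenerate candidates the most conservative (shortest-range)
    # interpretation labels the contact
    cat_label <- category[which.min(dsep)]
    cand <- paste(atoms$label[pairs$a1], atoms$label[pairs$a2], sep = "~")
    contacts[[length(contacts) + 1L]] <- data.frame(
      peak = i, w1 = w1, w2 = w2, category = cat_label,
      n_candidates = nrow(pairs), ambiguous = nrow(pairs) > 1L,
      candidates = paste(cand, collapse = ";"))
  }
  contacts <- if (length(contacts) > 0L) {
    do.call(rbind, contacts)
  } else {
    data.frame(peak = integer(), w1 = numeric(), w2 = numeric(),
               category = character(), n_candidates = integer(),
               ambiguous = logical(), candidates = character())
  }
  rownames(contacts) <- NULL
  list(contacts = contacts, diagonal = diagonal, orphans = orphans)
}

#' Synthetic proton/amide shift table for the GGLFGGNTQPAT repeat
#'
#' A synthetic but chemically plausible chemical-shift table for the
#' 12-mer repeat unit, covering the backbone amides (HN, N) of the 11
#' non-proline residues and a set of side-chain protons (aromatic ring,
#' methyl and methylene groups). The values are NOT experimental: they
#' are random-coil-like placeholders intended for simulation and testing;
#' real-data analyses require a user-supplied table.
#'
#' @return Data frame with columns `label`, `position`, `residue`,
#'   `atom`, `shift_ppm`.
#' @export
synthetic_shift_table <- function() {
  tab <- rbind(
    # backbone amides (1H HN and 15N N)
    data.frame(label = c("G1-HN", "G2-HN", "L3-HN", "F4-HN", "G5-HN",
                         "G6-HN", "N7-HN", "T8-HN", "Q9-HN", "A11-HN",
                         "T12-HN"),
               shift_ppm = c(8.42, 8.31, 8.10, 8.02, 8.46, 8.36, 8.52,
                             8.16, 8.26, 8.21, 8.07)),
    data.frame(label = c("G1-N", "G2-N", "L3-N", "F4-N", "G5-N", "G6-N",
                         "N7-N", "T8-N", "Q9-N", "A11-N", "T12-N"),
               shift_ppm = c(109.5, 108.9, 121.8, 120.3, 110.2, 109.1,
                             118.9, 113.8, 120.1, 124.6, 112.4)),
    # side-chain protons
    data.frame(label = c("L3-HD", "F4-HD", "F4-HE", "F4-HZ", "F4-HB",
                         "N7-HB", "T8-HG", "T8-HB", "Q9-HG", "P10-HB",
                         "A11-HB", "T12-HG", "T12-HB"),
               shift_ppm = c(0.86, 7.24, 7.34, 7.29, 3.05,
                             2.79, 1.20, 4.20, 2.36, 2.06,
                             1.38, 1.15, 4.12))
  )
  parsed <- .parse_atom_label(tab$label)
  parsed$shift_ppm <- tab$shift_ppm
  parsed
}
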