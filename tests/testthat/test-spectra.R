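test_that("expected amide peak counts exclude prolines", {
  expect_equal(expected_amide_peaks(repeat_unit), 11)
  expect_equal(expected_amide_peaks("PPPP"), 0)
  expect_equal(expected_amide_peaks("GGLFGGNTQAT"), 11)
  # complement invariant over assorted units
  for (u in c(repeat_unit, "GGLFGGATNSQT", "PGPG", "AAAA")) {
    res <- strsplit(u, "")[[1]]
    expect_equal(expected_amide_peaks(u) + sum(res == "P"), nchar(u))
  }
})

test_that("aromatic multiplicity patterns follow ring symmetry", {
  expect_equal(unname(aromatic_multiplicity("F")), c(2, 2, 1))
  expect_equal(unname(aromatic_multiplicity("Y")), c(2, 2))
  expect_length(aromatic_multiplicity("G"), 0)
  expect_length(aromatic_multiplicity("W"), 5)
})

test_that("chemical shift perturbations combine amide 1H and 15N shifts", {
  tabs <- gen_shift_tables()
  same <- csp(tabs$a, tabs$b)
  expect_true(all(same$csp_ppm == 0))
  expect_false(any(same$above_average))

  # hand-checked combination: dH = 0.03, dN = 0.15 -> 0.0424
  pert <- gen_shift_tables(data.frame(label = c("F4-HN", "F4-N"),
                                      d_ppm = c(0.03, 0.15)))
  out <- csp(pert$a, pert$b)
  expect_equal(out$csp_ppm[out$position == 4],
               sqrt(0.03^2 + (0.2 * 0.15)^2), tolerance = 1e-12)
  expect_equal(out$csp_ppm[out$position == 4], 0.0424, tolerance = 1e-3)

  # symmetry: swapping the conditions leaves the combined shift unchanged
  expect_equal(csp(pert$b, pert$a)$csp_ppm, out$csp_ppm,
               tolerance = 1e-12)

  # perturbations injected only at the hydrophobic patch flag exactly
  # those residues
  patch <- gen_shift_tables(data.frame(label = c("L3-HN", "F4-HN"),
                                       d_ppm = c(0.04, 0.06)))
  flagged <- csp(patch$a, patch$b)
  expect_equal(flagged$position[flagged$above_average], c(3, 4))

  stranger <- synthetic_shift_table()
  stranger$position <- stranger$position + 100
  stranger$label <- sub("[0-9]+", "999", stranger$label)
  expect_error(csp(tabs$a, stranger), "share no")
})

test_that("NOESY classification recovers injected long-range contacts and
           excludes the diagonal", {
  contacts <- c("F4-HD~T8-HG", "T8-HG~P10-HB")
  peaks <- gen_noesy_peaks(contacts)
  out <- classify_noe(peaks, proton_shifts())
  expect_equal(nrow(out$contacts), 2)
  expect_true(all(out$contacts$category == "long-range"))
  expect_false(any(out$contacts$ambiguous))
  expect_equal(out$contacts$candidates,
               c("F4-HD~T8-HG", "T8-HG~P10-HB"))
  # every diagonal peak flagged, none classified
  expect_equal(length(out$diagonal), nrow(peaks) - 2)
  expect_length(out$orphans, 0)
})

test_that("sequential contacts use the circular repeat convention", {
  # L3 methyl to F4 ring: sequential within the repeat
  p1 <- gen_noesy_peaks("L3-HD~F4-HD", include_diagonal = FALSE)
  expect_equal(classify_noe(p1, proton_shifts())$contacts$category,
               "sequential")
  # T12 to G1: sequential across the repeat junction
  p2 <- gen_noesy_peaks("T12-HG~G1-HN", include_diagonal = FALSE)
  expect_equal(classify_noe(p2, proton_shifts())$contacts$category,
               "sequential")
  # F4 beta-methylene to its own ring: intra-residue
  p3 <- gen_noesy_peaks("F4-HB~F4-HD", include_diagonal = FALSE)
  expect_equal(classify_noe(p3, proton_shifts())$contacts$category,
               "intra-residue")
})

test_that("degenerate shifts produce listed ambiguity; tolerance widening
           only grows candidate sets", {
  shifts <- proton_shifts()
  shifts$shift_ppm[shifts$label == "T12-HG"] <-
    shifts$shift_ppm[shifts$label == "T8-HG"]
  peaks <- gen_noesy_peaks("F4-HD~T8-HG", shifts = shifts,
                           include_diagonal = FALSE)
  amb <- classify_noe(peaks, shifts)
  expect_equal(amb$contacts$n_candidates, 2)
  expect_true(amb$contacts$ambiguous)

  # zero tolerance on exact synthetic shifts: no ambiguity at all
  exact <- classify_noe(gen_noesy_peaks("F4-HD~T8-HG",
                                        include_diagonal = FALSE),
                        proton_shifts(), tol_ppm = 0)
  expect_equal(exact$contacts$n_candidates, 1)
  # monotonicity in the tolerance
  n_cand <- vapply(c(0.005, 0.03, 0.1, 0.3), function(tol) {
    classify_noe(gen_noesy_peaks("F4-HD~T8-HG", include_diagonal = FALSE),
                 proton_shifts(), tol_ppm = tol)$contacts$n_candidates
  }, numeric(1))
  expect_true(all(diff(n_cand) >= 0))
})

test_that("every peak lands in exactly one of contacts, diagonal, orphans", {
  peaks <- rbind(
    gen_noesy_peaks(c("F4-HD~T8-HG", "L3-HD~F4-HE")),
    data.frame(w1 = 0.31, w2 = 5.9, intensity = 1, assignment = "?"))
  out <- classify_noe(peaks, proton_shifts())
  ids <- c(out$contacts$peak, out$diagonal, out$orphans)
  expect_setequal(ids, seq_len(nrow(peaks)))
  expect_equal(length(ids), nrow(peaks))
  expect_equal(out$orphans, nrow(peaks))
})
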