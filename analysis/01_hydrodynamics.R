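#!/usr/bin/env Rscript
# Closed-form hydrodynamic predictions for the engineered FG-repeat
# proteins: molecular mass, hydrated Stokes radius, rigid-sphere
# rotational correlation time and translational diffusion coefficient at
# 24 degC, plus the condensed-phase concentration arithmetic.

library(fgphase)
dir.create("results", showWarnings = FALSE)

unit <- "GGLFGGNTQPAT"

pred <- rbind(hydrodynamic_predictions(unit, 52, temp_c = 24),
              hydrodynamic_predictions(unit, 7, temp_c = 24))
write.csv(pred, "results/01_hydrodynamic_predictions.csv",
          row.names = FALSE)

cat("Rigid-sphere predictions at 24 degC (vbar 0.73, hydration 3.2 A):\n")
print(pred, digits = 4)
cat("\nIf the 52-repeat protein tumbled as a hydrated sphere its tau_c\n")
cat(sprintf("would be %.1f ns; the 7-repeat fragment's would be %.1f ns.\n",
            pred$tau_c_ns[1], pred$tau_c_ns[2]))
cat("Measured per-residue values in solution are an order of magnitude\n")
cat("shorter, showing segmental rather than whole-body tumbling.\n\n")

# condensed-phase concentration bookkeeping
mw <- pred$mw_da[1]
chain_mm <- 4.5                                   # mM in the dense phase
mass <- molar_to_mass_conc(chain_mm * 1e-3, mw)   # mg/ml
motifs <- motif_molarity(chain_mm, 52)            # mM of FG motifs
local <- sphere_local_concentration(52, 5) * 1000 # mM within one chain
enrich <- enrichment_factor(mass, molar_to_mass_conc(20e-6, mw))

conc <- data.frame(chain_mm = chain_mm, mass_mg_ml = mass,
                   fg_motif_mm = motifs, local_fg_motif_mm = local,
                   enrichment_fold = enrich)
write.csv(conc, "results/01_concentration_arithmetic.csv",
          row.names = FALSE)
cat(sprintf("Dense phase at %.1f mM chains = %.0f mg/ml = %.0f mM FG motifs;\n",
            chain_mm, mass, motifs))
cat(sprintf("a single 5 nm chain already confines its motifs to ~%.0f mM.\n",
            local))
cat(sprintf("Phase separation from a 20 uM dilution concentrates the protein %.0f-fold.\n",
            enrich))
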