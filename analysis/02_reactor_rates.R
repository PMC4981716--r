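#!/usr/bin/env Rscript
# Specific rates from the steady-state O2 mass balance: net specific O2
# production qO2 = [D([O2]-[O2_in]) + kla([O2]-kH pO2_in)] / x and
# carbon-mole biomass production qX = mu * 1000 / 24.59, plus the
# steady-state continuity check on the monitored channels.

library(photoacclim)

bundle <- "results/synthetic_bundle"
gas <- gas_params(0.83, kla_units = "per_min", kH = 1.08, pO2_in = 0)

ss <- read_steady_state_table(file.path(bundle, "steady_states.tsv"))
ss <- ss[, !startsWith(names(ss), "truth_")]
ss$qO2 <- compute_qO2(ss, gas)
ss$qX <- compute_qX(ss$mu)
write_units_tsv(ss, "results/rates.tsv",
                units = c(Ii = "umol_photons.m-2.s-1", D = "h-1",
                          mu = "h-1", x = "g_AFDW.L-1", O2_uM = "uM",
                          qO2 = "mmol.h-1.g-1", qX = "Cmmol.h-1.g-1"))

top <- ss[ss$Ii == max(ss$Ii), ]
cat(sprintf("qO2 at the highest irradiance (%g): %.1f +/- %.1f mmol h-1 g-1\n",
            max(ss$Ii), mean(top$qO2), sd(top$qO2)))
cat(sprintf("equilibrium dissolved O2 at pO2 0.78: %.1f uM\n",
            equilibrium_O2(gas, 0.78)))

# continuity criterion on a window of replicate observations at one
# steady state: <= 3% channel variation and >= 5 residence times
w <- ss[ss$Ii == 164, ]
verdict <- detect_steady_state(list(OD730 = w$OD730, pH = w$pH,
                                    O2 = w$O2_uM),
                               residence_times_elapsed = 6)
cat("steady-state continuity at Ii = 164:",
    if (verdict$steady) "accepted" else "rejected",
    sprintf("(max variation %.1f%%)\n", 100 * max(verdict$max_variation)))
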