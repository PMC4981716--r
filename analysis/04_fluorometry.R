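#!/usr/bin/env Rscript
# PAM chlorophyll-fluorescence statistics: the post-illumination
# fluorescence rise in darkness as a cyclic-electron-flow proxy (rCEF),
# rapid-light-curve parameters rETR_max and alpha_r from the saturating
# light-response fit, and the dark-adapted quantum yield Fv/Fm.

library(photoacclim)

bundle <- "results/synthetic_bundle"
trace <- read_units_tsv(file.path(bundle, "pam_trace.tsv"))
rlc <- read_units_tsv(file.path(bundle, "rapid_light_curve.tsv"))

cef <- estimate_rCEF(trace, window = 10)
cat(sprintf("rCEF (dark-phase rise, first %.0f s): %.3f +/- %.3f f.u. s-1\n",
            cef$window_used, cef$rCEF, cef$se))

r <- fit_rapid_light_curve(rlc)
cat(sprintf("rapid light curve: rETR_max %.1f (observed max %.1f), alpha_r %.3f\n",
            r$rETRmax, r$rETRmax_observed, r$alpha_r))

fvfm <- optimal_quantum_yield(Fo = 0.8, Fm = 2.5)  # phase i/iv levels
cat(sprintf("Fv/Fm from the dark levels: %.2f\n", as.numeric(fvfm)))

stats <- list(rCEF = cef$rCEF, rCEF_se = cef$se,
              rETRmax = r$rETRmax, alpha_r = r$alpha_r,
              Ik_rlc = r$Ik, FvFm = as.numeric(fvfm))
jsonlite::write_json(stats, "results/pam_stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
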