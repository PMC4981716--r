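#!/usr/bin/env Rscript
# Fit the saturating/photoinhibition light-response model
# R = Rmax [1 - exp(-Ii/Ik)] exp(-Ii/beta) to growth and photosynthesis
# rates (weighted NLS; the beta = Inf submodel is selected by F test
# when inhibition is unsupported), classify the light regimes around the
# fitted Ik, and estimate the growth-to-photosynthesis yields Q per
# regime as slopes of qX on qO2.

library(photoacclim)

rates <- read_units_tsv("results/rates.tsv")

agg <- function(col) {
  list(Ii = sort(unique(rates$Ii)),
       mean = tapply(rates[[col]], rates$Ii, mean),
       sd = tapply(rates[[col]], rates$Ii, sd))
}
gm <- agg("mu")
fit <- fit_light_response(gm$Ii, gm$mean, sd = gm$sd)
cat("growth light response:\n"); print(fit)
cat(sprintf("doubling time at mu_max: %.2f h\n", log(2) / fit$Rmax))

go <- agg("qO2")
fit_o2 <- fit_light_response(go$Ii, go$mean, sd = go$sd)
cat(sprintf("qO2 response: asymptote %.1f mmol h-1 g-1 (%s model)\n",
            fit_o2$Rmax, fit_o2$model))

pred <- data.frame(Ii = seq(1, 800, by = 1))
pred$mu_fit <- light_response(pred$Ii, fit$Rmax, fit$Ik, fit$beta)
pred$qO2_fit <- light_response(pred$Ii, fit_o2$Rmax, fit_o2$Ik, fit_o2$beta)
write_units_tsv(pred, "results/light_response_curves.tsv",
                units = c(Ii = "umol_photons.m-2.s-1", mu_fit = "h-1",
                          qO2_fit = "mmol.h-1.g-1"))

regime <- classify_regimes(gm$Ii, fit$Ik, delta = 0.25)
qmeans <- data.frame(Ii = gm$Ii, qO2 = as.numeric(go$mean),
                     qX = as.numeric(tapply(rates$qX, rates$Ii, mean)),
                     regime = regime)
Q <- photosynthetic_quotient(qmeans$qO2, qmeans$qX, qmeans$regime)
write_units_tsv(Q, "results/quotients.tsv")
cat("growth-to-photosynthesis yields per regime:\n")
print(Q, digits = 3)

fitrep <- list(growth = fit[c("Rmax", "Ik", "beta", "alpha", "peak_Ii",
                              "se", "sse", "model", "f_p_value", "n")],
               qO2 = fit_o2[c("Rmax", "Ik", "beta", "alpha", "model")],
               regimes = split(gm$Ii, regime))
jsonlite::write_json(fitrep, "results/light_response_fit.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     force = TRUE)
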