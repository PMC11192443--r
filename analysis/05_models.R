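#!/usr/bin/env Rscript
# Stage 5 -- the mixed-model suite over the ISC table: the condition-type
# model (crossed random intercepts for fROI, participant, condition), the
# per-stimulus recoding with three FDR-grouped baselines, per-fROI models,
# and the fROI x condition-type interaction model.

library(natisc)

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
isc <- read_isc_table("results/isc.tsv")

fit <- fit_condition_model(isc)
print(fit)
write_lme_fit(fit, "results/models/condition_model.tsv",
              "results/models/condition_model.json")

per_cond <- per_condition_tests(isc)
write.table(per_cond, "results/models/per_condition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nper-stimulus tests (each +M/-L stimulus vs three baselines, FDR n=3):\n")
print(per_cond, row.names = FALSE, digits = 3)

froi_fits <- fit_per_froi_model(isc)
froi_tab <- attr(froi_fits, "fdr_table")
write.table(froi_tab, "results/models/per_froi.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nper-fROI intercepts (+M/-L vs 0, FDR across 5 fROIs):\n")
print(froi_tab[froi_tab$name == "(Intercept)", ], row.names = FALSE, digits = 3)

inter <- fit_interaction_model(isc)
write_lme_fit(inter, "results/models/interaction_model.tsv",
              "results/models/interaction_model.json")
cat(sprintf("\ninteraction model: %d fixed terms, logLik %.1f, AIC %.1f\n",
            nrow(inter$terms), inter$loglik, inter$aic))
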