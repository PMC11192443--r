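#!/usr/bin/env Rscript
# Stage 6 -- Content-Unit scoring of the description corpus and its
# association with ISC: per-subclip CU counts (cleaning, lemmatization,
# >= 3-participant inclusion filter, repeated tokens counted), the CU
# condition-type model, and the CU-ISC correlation plus model comparisons
# over the meaningful stimuli.

library(natisc)

corpus <- read_corpus("results/data/corpus.json")
isc <- read_isc_table("results/isc.tsv")
design <- jsonlite::read_json("results/data/design.json", simplifyVector = TRUE)
manifest <- design$conditions

cu_tab <- do.call(rbind, lapply(unique(corpus$stimulus), function(s) {
  count_cus(corpus, s)$table
}))
write.table(cu_tab, "results/cu_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

per_stim <- aggregate(cu_count ~ stimulus, cu_tab, mean)
per_stim$condition_type <- manifest$condition_type[
  match(per_stim$stimulus, manifest$name)]
cat("mean CU count per stimulus:\n")
print(per_stim[order(per_stim$condition_type), ], row.names = FALSE, digits = 3)

fit <- cu_condition_model(cu_tab, manifest)
print(fit)

meaningful <- manifest$name[manifest$condition_type != "-M/-L"]
assoc <- cu_isc_association(cu_tab, isc, metric = "mean_cu",
                            scope = meaningful)
cat(sprintf("\nCU-ISC association over %d meaningful stimuli: r = %.3f (p = %.3f)\n",
            assoc$n_stimuli, assoc$pearson_r, assoc$p))
cat(sprintf("adding centered CU to the condition-type model: LRT chi2(%d) = %.2f, p = %.3f\n",
            assoc$model_comparisons$lrt$df, assoc$model_comparisons$lrt$chi2,
            assoc$model_comparisons$lrt$p))
cat(sprintf("CU-only vs condition-type model: delta AIC = %.2f (positive favours condition type)\n",
            assoc$model_comparisons$delta_aic))

shared <- do.call(rbind, lapply(unique(corpus$stimulus), function(s) {
  data.frame(stimulus = s,
             shared = shared_cu_pairwise(corpus, s)$clip_mean)
}))
write.table(shared, "results/cu_shared.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
assoc2 <- cu_isc_association(
  within(shared, cu <- shared)[, c("stimulus", "cu")], isc,
  metric = "shared_cu", scope = meaningful)
cat(sprintf("shared-CU metric: r = %.3f (p = %.3f), LRT p = %.3f\n",
            assoc2$pearson_r, assoc2$p, assoc2$model_comparisons$lrt$p))
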