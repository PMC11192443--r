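#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study: ten naturalistic conditions with
# their published durations and Ns, a 10-participant rest scan, and a
# free-description corpus (20 describers per stimulus). Everything is
# seeded; rerunning reproduces the files bit for bit.

library(natisc)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- make_design("paper", seed = seed)
print(design)
write_design(design, file.path(out, "design.json"))

tcs <- simulate_timecourses(design)
write_timecourses(tcs, file.path(out, "timecourses.tsv"))

rest <- simulate_rest(10, 300, design)
write_timecourses(rest, file.path(out, "rest.tsv"))

corpus <- simulate_corpus(design, n_participants = 20, seed = seed)
write_corpus(corpus, file.path(out, "corpus.json"))

cat(sprintf("wrote %d conditions (%d series), rest scan, %d description rows\n",
            nrow(design$conditions),
            sum(design$conditions$n_participants) * length(design$froi_modifiers),
            nrow(corpus)))
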