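#!/usr/bin/env Rscript
# Generate the synthetic psychophysical cohort: five observers per
# condition, both tasks, nine ISIs; 80 2AFC trials per ISI for direction
# discrimination and 4 MAE duration measurements per ISI. Per-observer
# true k values mirror the published individual fits.

suppressPackageStartupMessages(library(twostroke))
dir.create("results", showWarnings = FALSE)

seed <- 1
dat <- make_fixture_dataset(seed = seed,
                            path = "results/synthetic_observers.csv")
cat("Synthetic cohort written to results/synthetic_observers.csv\n")
cat(sprintf("  %d rows: %d observers x 2 conditions x 2 tasks x %d ISIs (seed %d)\n",
            nrow(dat), length(unique(dat$observer)),
            length(unique(dat$isi_ms)), seed))
cat("True k layout:\n")
print(as.data.frame(fixture_k_layout()))
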