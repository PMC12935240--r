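#!/usr/bin/env Rscript
# Stage 4: dataset-level summary table (mean absolute slope, slope SD,
# direction split, mean |days/decade|, species count) and a check of the
# estimates against the simulated truth.

suppressPackageStartupMessages(library(phenocirc))

truth <- read.csv("results/truth.csv")
summaries <- do.call(rbind, lapply(1:6, function(id) {
  est <- read.csv(sprintf("results/estimates_dataset%d.csv", id))
  summarize_dataset(est, dataset_id = id)
}))
write.csv(summaries, "results/dataset_summaries.csv", row.names = FALSE)
print(summaries, row.names = FALSE, digits = 3)

est1 <- read.csv("results/estimates_dataset1.csv")
m <- merge(est1, truth, by = "species")
message(sprintf(
  "dataset 1 vs truth: sign recovered %d/%d, mean |error| %.2f d/decade",
  sum(sign(m$days_per_decade) == sign(m$drift_days_per_decade)), nrow(m),
  mean(abs(m$days_per_decade - m$drift_days_per_decade))))
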