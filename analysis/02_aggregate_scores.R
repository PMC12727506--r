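#!/usr/bin/env Rscript
# Stage 2: aggregate per-expert intactness scores.
#
# Reads the raw score table, validates it against the group registry,
# averages across experts per (group, land use, biome) with 95% t-intervals
# clipped to [0, 2], and summarises expert participation.

suppressPackageStartupMessages(library(biimapr))
reg <- load_group_registry()

rec <- read_score_table("results/data/expert_scores.csv", registry = reg)
load_rep <- attr(rec, "load_report")
cat(sprintf("loaded %d records (%d blank cells dropped)\n",
            load_rep$n_records, load_rep$n_blank_dropped))

agg <- aggregate_scores(rec, ci_level = 0.95)
write.csv(agg, "results/aggregated_scores.csv", row.names = FALSE)

cnt <- expert_count_summary(rec)
write.csv(data.frame(mean_experts = cnt$mean, sd_experts = cnt$sd,
                     n_combinations = cnt$n_combinations),
          "results/expert_count_summary.csv", row.names = FALSE)

cat(sprintf("aggregated %d combinations; %d scored by a single expert\n",
            nrow(agg), sum(agg$single_expert)))
cat(sprintf("mean experts per combination: %.1f (sd %.1f)\n",
            cnt$mean, cnt$sd))
cat(sprintf("mean CI width: %.3f (widest: %.3f)\n",
            mean(agg$ci_upper - agg$ci_lower), max(agg$ci_upper - agg$ci_lower)))
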