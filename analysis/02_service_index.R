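#!/usr/bin/env Rscript
# Stage 2: composite service (non-)delivery index.
#
# Z-scores the seven components across municipalities, sums them into the
# composite (higher = poorer delivery), square-root transforms the shifted
# score into the model covariate, computes the Pearson correlation matrix
# of the components, and aggregates rates and scores to provinces with
# CI-overlap ranking.

suppressPackageStartupMessages(library(servmort))
dir.create("results", showWarnings = FALSE)

table <- read_area_table("results/data/area_table.csv")
index <- composite_index(table)
ineq <- classify_inequality(table$gini)

out <- data.frame(area_id = index$area_id,
                  composite_score = index$composite_score,
                  transformed_score = index$transformed_score,
                  gini = table$gini, inequality_high = ineq)
write.csv(cbind(out, index$z), "results/service_index.csv", row.names = FALSE)

corr <- component_correlation(table)
write.csv(as.data.frame(corr$r), "results/component_correlation.csv")
n_sig <- sum(corr$significant[upper.tri(corr$significant)], na.rm = TRUE)
cat(sprintf("component correlations: %d of %d pairs significant at 5%%\n",
            n_sig, sum(upper.tri(corr$r))))

prov <- provincial_summary(table, index)
write.csv(prov, "results/provincial_summary.csv", row.names = FALSE)
cat("provincial mortality ranking (rate per 1000, CI-overlap ties):\n")
print(prov[, c("province", "rate_per_1000", "rank_mortality",
               "score", "rank_service")], digits = 3)
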