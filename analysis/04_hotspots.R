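#!/usr/bin/env Rscript
# Stage 4: exceedance-probability hotspot maps.
#
# Flags municipalities whose smoothed standardized mortality ratio exceeds
# 1 with posterior probability above 0.9 (the stringent variant of
# Richardson's criterion), and applies the same machinery to a
# standardized poor-service ratio built from the composite index.

suppressPackageStartupMessages(library(servmort))

table <- read_area_table("results/data/area_table.csv")
adj <- read_adjacency("results/data/adjacency.gal")
index <- composite_index(table)
mc <- mcmc_config(n_burnin = 2000, n_retain = 5000, seed = 20070103)

fit <- fit_bym(table, adj, model_spec(), mc)
hot <- flag_hotspots(fit, threshold = 0.9)
write.csv(hot, "results/mortality_hotspots.csv", row.names = FALSE)
cat(sprintf("mortality hotspots: %d of %d municipalities (threshold 0.9)\n",
            sum(hot$hotspot), nrow(hot)))

serv <- service_hotspots(table, adj, index, mc, threshold = 0.9)
write.csv(serv, "results/service_hotspots.csv", row.names = FALSE)
cat(sprintf("service non-delivery hotspots: %d of %d municipalities\n",
            sum(serv$hotspot), nrow(serv)))

both <- hot$hotspot & serv$hotspot
cat(sprintf("municipalities flagged on both maps: %d\n", sum(both)))
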