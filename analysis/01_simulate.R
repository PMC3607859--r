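#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study area.
#
# Emulates the structure of the South African local-municipality data: 248
# units on an 8 x 31 rook lattice grouped into 9 pseudo-provinces,
# correlated service-delivery components, lognormal household incomes,
# HIV seroprevalence, density/metro classes, and Poisson death counts from
# a convolution (spatial + heterogeneity) log-linear risk field with the
# default covariate effects. Writes the area table, GAL adjacency and the
# latent truth under results/data/.

suppressPackageStartupMessages(library(servmort))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20070101)
sim <- simulate_dataset(cfg)

write_area_table(sim$table, "results/data/area_table.csv")
write_adjacency(sim$adj, "results/data/adjacency.gal")
jsonlite::write_json(
  list(alpha = sim$truth$alpha, beta = as.list(sim$truth$beta),
       lambda = sim$truth$lambda),
  "results/data/truth.json", auto_unbox = TRUE, digits = NA)

rep <- validate_areal(sim$table, sim$adj)
stopifnot(rep$pass)
rate <- 1000 * sum(sim$table$deaths) / sum(sim$table$population)
cat(sprintf("simulated %d units in %d provinces; crude rate %.1f per 1000\n",
            nrow(sim$table), length(unique(sim$table$province)), rate))
cat(sprintf("true covariate RRs: %s\n",
            paste(sprintf("%s=%.2f", names(sim$truth$beta),
                          exp(sim$truth$beta)), collapse = ", ")))
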