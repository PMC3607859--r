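# Deterministic in-code fixtures shared across test files.

# A small valid area table with all schema columns and n >= 3 units.
fixture_table <- function(n = 6, seed = 424) {
  set.seed(seed)
  tab <- data.frame(
    area_id = sprintf("a%02d", seq_len(n)),
    province = rep(c("P1", "P2"), length.out = n),
    population = sample(2000:8000, n),
    comp_no_water = runif(n, 0.05, 0.6),
    comp_no_toilet = runif(n, 0.02, 0.3),
    comp_no_refuse = runif(n, 0.1, 0.7),
    comp_no_electricity = runif(n, 0.05, 0.5),
    comp_no_schooling = runif(n, 0.05, 0.4),
    comp_informal = runif(n, 0.02, 0.35),
    comp_health_ratio = runif(n, 0.2, 0.9),
    hiv_prev = runif(n, 5, 35),
    gini = runif(n, 0.35, 0.75),
    density_class = rep(c("low_medium", "high_nonmetro", "high_metro"),
                        length.out = n),
    stringsAsFactors = FALSE
  )
  tab$deaths <- rbinom(n, tab$population, 0.02)
  as_area_table(tab)
}

# Write a GAL file from lines and read it back.
read_gal_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gal", .local_envir = parent.frame())
  writeLines(lines, path)
  read_adjacency(path)
}

# O(n^2) pairwise Gini oracle: mean |x_i - x_j| over all ordered pairs
# divided by twice the mean.
gini_pairwise_oracle <- function(x) {
  mean(abs(outer(x, x, "-"))) / (2 * mean(x))
}

# Minimal bym_fit-shaped object for testing posterior summary operations
# against hand-built chains.
fake_fit <- function(alpha_chains = NULL, beta = NULL, lambda = NULL,
                     deviance = NULL, O = NULL, E = NULL,
                     covariates = character(0)) {
  chains <- NULL
  pooled <- list()
  if (!is.null(alpha_chains)) {
    chains <- lapply(alpha_chains, function(a) list(alpha = a))
    pooled$alpha <- unlist(alpha_chains)
  }
  if (!is.null(beta)) pooled$beta <- beta
  if (!is.null(lambda)) {
    pooled$lambda <- lambda
    if (is.null(E)) E <- rep(1, ncol(lambda))
    if (is.null(O)) O <- round(colMeans(lambda))
  }
  if (!is.null(deviance)) pooled$deviance <- deviance
  structure(list(chains = chains, pooled = pooled, O = O, E = E,
                 area_id = if (!is.null(lambda)) {
                   colnames(lambda) %||% sprintf("a%02d", seq_len(ncol(lambda)))
                 },
                 covariates = covariates,
                 spec = list(heterogeneity = FALSE, spatial = FALSE)),
            class = "bym_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-effect variant of the default covariate effect vector.
null_beta <- c(service_sqrt = 0, inequality_high = 0, hiv_centered = 0,
               density_high_nonmetro = 0, density_high_metro = 0)
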