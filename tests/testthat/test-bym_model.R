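test_that("expected counts are internally standardized and conserved", {
  tab <- data.frame(area_id = c("A", "B"), population = c(1000, 3000),
                    deaths = c(10, 30))
  expect_equal(unname(expected_counts(tab)), c(10, 30))
  one <- data.frame(area_id = "A", population = 500, deaths = 17)
  expect_equal(unname(expected_counts(one)), 17)
  tab2 <- fixture_table(7)
  expect_equal(sum(expected_counts(tab2)), sum(tab2$deaths))
  z <- data.frame(area_id = "A", population = 10, deaths = 0)
  expect_warning(E <- expected_counts(z), "unfittable")
  expect_equal(unname(E), 0)
})

test_that("chains are bitwise reproducible under a fixed seed", {
  sim <- simulate_dataset(sim_config(n_rows = 4, n_cols = 4, n_provinces = 2,
                                     seed = 21))
  mc <- mcmc_config(n_burnin = 200, n_retain = 300, seed = 5)
  f1 <- fit_bym(sim$table, sim$adj, model_spec(), mc)
  f2 <- fit_bym(sim$table, sim$adj, model_spec(), mc)
  expect_identical(f1$pooled$alpha, f2$pooled$alpha)
  expect_identical(f1$pooled$lambda, f2$pooled$lambda)
  expect_identical(f1$pooled$deviance, f2$pooled$deviance)
})

test_that("every retained spatial field satisfies the sum-to-zero constraint", {
  sim <- simulate_dataset(sim_config(n_rows = 4, n_cols = 4, n_provinces = 2,
                                     seed = 22))
  fit <- fit_bym(sim$table, sim$adj, model_spec(),
                 mcmc_config(n_burnin = 200, n_retain = 300, seed = 6))
  expect_lt(max(abs(rowMeans(fit$pooled$phi))), 1e-10)
})

test_that("Gelman-Rubin separates mixed from unmixed chains", {
  x <- rnorm(2000)
  ident <- fake_fit(alpha_chains = list(x, x))
  expect_lte(gelman_rubin(ident)$rhat[["alpha"]], 1.01)

  set.seed(31)
  same <- fake_fit(alpha_chains = list(rnorm(10000), rnorm(10000)))
  expect_lt(gelman_rubin(same)$rhat[["alpha"]], 1.05)

  apart <- fake_fit(alpha_chains = list(rnorm(1000, 0), rnorm(1000, 10)))
  gr <- gelman_rubin(apart)
  expect_gt(gr$rhat[["alpha"]], 2)
  expect_false(gr$converged)

  expect_error(gelman_rubin(fake_fit(alpha_chains = list(rnorm(10)))),
               ">= 2 chains")
})

test_that("R-hat agrees with the coda reference on real chains", {
  sim <- simulate_dataset(sim_config(n_rows = 4, n_cols = 4, n_provinces = 2,
                                     seed = 23))
  fit <- fit_bym(sim$table, sim$adj, model_spec(),
                 mcmc_config(n_burnin = 500, n_retain = 1000, seed = 7))
  ml <- coda::mcmc.list(lapply(fit$chains, function(c) coda::mcmc(c$alpha)))
  ref <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
  expect_equal(unname(gelman_rubin(fit)$rhat[["alpha"]]), ref, tolerance = 0.01)
})

test_that("DIC components satisfy their identities", {
  # degenerate posterior: a single repeated draw has no effective parameters
  O <- c(5, 7); E <- c(6, 6)
  lam <- matrix(rep(c(0.9, 1.1), each = 50), nrow = 50)
  dev <- rep(-2 * sum(dpois(O, E * c(0.9, 1.1), log = TRUE)), 50)
  fit <- fake_fit(lambda = lam, deviance = dev, O = O, E = E)
  d <- dic(fit)
  expect_equal(d$pD, 0, tolerance = 1e-10)
  expect_equal(d$DIC, d$Dbar, tolerance = 1e-10)

  # recomputation from stored traces is exact
  sim <- simulate_dataset(sim_config(n_rows = 4, n_cols = 4, n_provinces = 2,
                                     seed = 24))
  f <- fit_bym(sim$table, sim$adj, model_spec(),
               mcmc_config(n_burnin = 200, n_retain = 300, seed = 8))
  expect_identical(dic(f), dic(f))
  expect_equal(dic(f)$DIC, dic(f)$Dbar + dic(f)$pD)
  expect_error(dic(fake_fit(lambda = lam, O = O, E = E)), "deviance")
})

test_that("covariate summaries match sort-based order statistics", {
  set.seed(41)
  b <- matrix(rnorm(1000, 0.3, 0.2), ncol = 1, dimnames = list(NULL, "x1"))
  fit <- fake_fit(beta = b, covariates = "x1")
  cs <- covariate_summaries(fit)
  srt <- sort(exp(b[, 1]))
  expect_equal(cs$rr, quantile(exp(b), 0.5, names = FALSE))
  expect_equal(cs$rr_lower, quantile(exp(b), 0.025, names = FALSE))
  expect_equal(cs$p_rr_gt_1, mean(b > 0))

  allpos <- fake_fit(beta = matrix(abs(rnorm(100)) + 0.01, ncol = 1,
                                   dimnames = list(NULL, "x1")),
                     covariates = "x1")
  cs <- covariate_summaries(allpos)
  expect_equal(cs$p_rr_gt_1, 1)
  expect_true(cs$significant)

  sym <- fake_fit(beta = matrix(c(rnorm(500), -rnorm(500)), ncol = 1,
                                dimnames = list(NULL, "x1")),
                  covariates = "x1")
  cs <- covariate_summaries(sym)
  expect_lt(abs(cs$p_rr_gt_1 - 0.5), 0.1)
  expect_false(cs$significant)
})

test_that("exceedance probabilities are sample fractions above the reference", {
  lam <- matrix(c(rep(2, 10), rep(c(0.5, 1.5), 5)), ncol = 2,
                dimnames = list(NULL, c("A", "B")))
  fit <- fake_fit(lambda = lam)
  ex <- exceedance_probs(fit)
  expect_equal(unname(ex), c(1, 0.5))
  set.seed(42)
  lam <- matrix(rlnorm(200), ncol = 4)
  colnames(lam) <- sprintf("a%02d", 1:4)
  fit <- fake_fit(lambda = lam)
  expect_equal(unname(exceedance_probs(fit)),
               apply(lam, 2, function(x) sum(x > 1) / length(x)),
               ignore_attr = TRUE)
})

test_that("disabling both random effects gives a standard Poisson fit", {
  sim <- simulate_dataset(sim_config(n_rows = 4, n_cols = 4, n_provinces = 2,
                                     seed = 25))
  fit <- fit_bym(sim$table, sim$adj,
                 model_spec(spatial = FALSE, heterogeneity = FALSE),
                 mcmc_config(n_burnin = 500, n_retain = 1000, seed = 9))
  expect_equal(max(abs(fit$pooled$eps)), 0)
  expect_equal(max(abs(fit$pooled$phi)), 0)
  # null standard Poisson: lambda is a single level exp(alpha) shared by
  # every unit (the stored risk trace is a thinning of the alpha trace)
  expect_equal(apply(fit$pooled$lambda, 1, function(r) diff(range(r))),
               rep(0, nrow(fit$pooled$lambda)))
  gap <- vapply(log(fit$pooled$lambda[, 1]),
                function(v) min(abs(v - fit$pooled$alpha)), numeric(1))
  expect_lt(max(gap), 1e-10)
})
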