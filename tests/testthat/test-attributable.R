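af_table <- function(rates, pops = rep(10000L, length(rates))) {
  # minimal table for reduction computations: deaths chosen to give the
  # requested rates per 1000 exactly
  data.frame(area_id = sprintf("r%02d", seq_along(rates)),
             population = pops, deaths = as.integer(rates * pops / 1000),
             stringsAsFactors = FALSE)
}

test_that("attributable fraction follows its defining arithmetic", {
  expect_equal(attributable_fraction(0.3, 1), 0)
  expect_equal(attributable_fraction(0, 4.2), 0)
  expect_equal(attributable_fraction(0.5, 2), 1 / 3, tolerance = 1e-12)
  expect_lt(attributable_fraction(0.4, 0.5), 0)  # protective exposure
  expect_error(attributable_fraction(1.3, 2), "\\[0, 1\\]")
  expect_error(attributable_fraction(0.5, 0), "positive")
  # strictly increasing in both arguments for RR > 1, p_e > 0
  pe <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(attributable_fraction(pe, 2)) > 0))
  rr <- seq(1.05, 5, by = 0.05)
  expect_true(all(diff(attributable_fraction(0.5, rr)) > 0))
})

test_that("per-unit reductions combine determinants multiplicatively", {
  tab <- af_table(c(30, 30))
  prev <- cbind(d1 = c(0.5, 0.5))
  red <- per_unit_reduction(tab, c(d1 = 2), prev)
  expect_equal(red$units$total_reduction, c(10, 10))
  expect_equal(red$units$residual_rate, c(20, 20))

  # RR = 1 everywhere: nothing to reduce
  red0 <- per_unit_reduction(tab, c(d1 = 1, d2 = 1), cbind(d1 = c(1, 1), d2 = c(1, 0.2)))
  expect_equal(red0$units$total_reduction, c(0, 0))

  # two determinants with AF = 0.5 each: residual factor 0.25
  red2 <- per_unit_reduction(af_table(40), c(d1 = 2, d2 = 2),
                             cbind(d1 = 1, d2 = 1))
  expect_equal(red2$units$combined_af, 0.75)
  expect_equal(red2$units$residual_rate, 10)
  expect_equal(red2$units$reduction_d1, 20)  # additive decomposition

  # order invariance of the combined residual
  tab3 <- af_table(c(25, 18, 33))
  prev3 <- cbind(a = c(0.2, 0.5, 0.9), b = c(0.7, 0.1, 0.4))
  f1 <- per_unit_reduction(tab3, c(a = 1.8, b = 1.3), prev3)
  f2 <- per_unit_reduction(tab3, c(b = 1.3, a = 1.8), prev3[, c("b", "a")])
  expect_equal(f1$units$residual_rate, f2$units$residual_rate)

  expect_error(per_unit_reduction(tab3, c(a = 2), cbind(a = c(0.2, 1.4, 0.5))),
               "\\[0, 1\\]")
})

test_that("national aggregation is the population-weighted mean with shares", {
  tab <- af_table(c(30, 30, 30))
  red <- per_unit_reduction(tab, c(d1 = 2), cbind(d1 = rep(0.5, 3)))
  expect_equal(red$national$mean_reduction, red$units$total_reduction[1])

  tab <- af_table(c(10, 20, 40), pops = c(1000L, 2000L, 7000L))
  red <- per_unit_reduction(tab, c(d1 = 2), cbind(d1 = c(0.1, 0.5, 0.9)))
  w <- tab$population / sum(tab$population)
  expect_equal(red$national$mean_reduction, sum(w * red$units$total_reduction))
  expect_equal(red$national$range, range(red$units$total_reduction))
  # additive per-determinant parts bound the multiplicative total from above
  red2 <- per_unit_reduction(tab, c(d1 = 2, d2 = 1.5),
                             cbind(d1 = c(0.1, 0.5, 0.9), d2 = c(0.4, 0.4, 0.4)))
  expect_gte(sum(red2$national$per_determinant), red2$national$mean_reduction)
  expect_equal(sum(red2$national$shares), 1)
})

test_that("reduction curves are sorted, bounded and reproducible from CSV", {
  set.seed(61)
  tab <- af_table(round(runif(12, 5, 45), 1))
  prev <- cbind(a = runif(12), b = runif(12))
  red <- per_unit_reduction(tab, c(a = 1.9, b = 1.2), prev)
  cur <- reduction_curve(red)
  expect_true(all(diff(cur$observed_rate) <= 0))
  expect_true(all(cur$projected_rate <= cur$observed_rate + 1e-12))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cur, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$projected_rate, cur$projected_rate)
})

test_that("posterior RR draws propagate into a national uncertainty interval", {
  set.seed(62)
  tab <- af_table(c(20, 35), pops = c(3000L, 5000L))
  prev <- cbind(a = c(0.3, 0.8))
  draws <- cbind(a = exp(rnorm(500, log(2), 0.1)))
  red <- per_unit_reduction(tab, c(a = 2), prev, rr_samples = draws)
  expect_true(red$national$lower < red$national$mean_reduction)
  expect_true(red$national$upper > red$national$mean_reduction)
  # brute-force oracle for the draws
  w <- tab$population / sum(tab$population)
  obs <- 1000 * tab$deaths / tab$population
  nd <- vapply(draws[, 1], function(r)
    sum(w * obs * attributable_fraction(prev[, 1], r)), numeric(1))
  expect_equal(unname(quantile(nd, c(0.025, 0.975), names = FALSE)),
               c(red$national$lower, red$national$upper))
})

test_that("component-level fits recover the truth-implied national reduction", {
  dets <- c("comp_no_water", "comp_no_electricity", "comp_no_schooling")
  true_rr <- c(comp_no_water = 1.6, comp_no_electricity = 1.8,
               comp_no_schooling = 2.2)
  hits <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_rows = 7, n_cols = 7, n_provinces = 2,
                      covariate_cols = dets, true_beta = log(true_rr),
                      sigma_eps = 0.05, sigma_phi = 0.1, seed = 700 + s)
    sim <- simulate_dataset(cfg)
    fit <- fit_bym(sim$table, sim$adj, model_spec(covariates = dets),
                   mcmc_config(n_burnin = 1000, n_retain = 2000, seed = s))
    cs <- covariate_summaries(fit)
    rr_hat <- setNames(cs$rr, cs$covariate)
    est <- per_unit_reduction(sim$table, rr_hat,
                              rr_samples = exp(fit$pooled$beta))
    truth <- per_unit_reduction(sim$table, true_rr)
    hits <- hits + (truth$national$mean_reduction >= est$national$lower &&
                      truth$national$mean_reduction <= est$national$upper)
  }
  expect_gte(hits, 2)
})
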