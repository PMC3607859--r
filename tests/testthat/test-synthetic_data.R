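test_that("lattice adjacencies have the contiguity-implied neighbour counts", {
  expect_equal(unname(make_lattice(2, 2, "rook")$num_neighbours), rep(2L, 4))
  expect_equal(unname(make_lattice(2, 2, "queen")$num_neighbours), rep(3L, 4))
  q <- make_lattice(3, 3, "queen")
  expect_equal(unname(q$num_neighbours[5]), 8L)  # centre unit, row-major
  r <- make_lattice(3, 3, "rook")
  expect_equal(sort(unique(unname(r$num_neighbours))), c(2L, 3L, 4L))
  expect_error(make_lattice(1, 5), ">= 2")
})

test_that("intrinsic CAR fields are centred, spatially correlated and scale to zero", {
  adj <- make_lattice(6, 6)
  phi <- simulate_car_field(adj, sigma_phi = 0.5, seed = 1)
  expect_lt(abs(mean(phi)), 1e-10)
  expect_gt(stats::sd(phi), 0)
  expect_equal(unname(simulate_car_field(adj, 0, seed = 1)), rep(0, 36))

  # positive spatial autocorrelation on average (Moran's I oracle)
  adj10 <- make_lattice(10, 10)
  W <- servmort:::adjacency_matrix(adj10)
  mi <- vapply(1:30, function(s) {
    ape::Moran.I(simulate_car_field(adj10, 0.4, seed = s), W)$observed
  }, numeric(1))
  expect_gt(mean(mi), 0.2)

  # isolated units stay at zero, connected block still varies
  expect_warning(mix <- adjacency(list(A = "B", B = "A", C = character(0))))
  phi <- simulate_car_field(mix, 0.5, seed = 2)
  expect_identical(unname(phi["C"]), 0)
  expect_lt(abs(mean(phi[c("A", "B")])), 1e-10)
})

test_that("service components honour the target correlation and [0,1] range", {
  x0 <- simulate_components(500, 0, seed = 3)
  r0 <- cor(x0)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.15)

  x6 <- simulate_components(500, 0.6, seed = 4)
  r6 <- cor(x6)
  off <- r6[upper.tri(r6)]
  expect_true(all(off > 0.45 & off < 0.75))
  expect_true(all(x6 >= 0 & x6 <= 1))
  expect_error(simulate_components(10, -0.5), "positive definite")
})

test_that("income draws reproduce known Gini values", {
  eq <- simulate_incomes_and_gini(100, 0, seed = 5)
  expect_equal(eq$gini, 0)
  ln <- simulate_incomes_and_gini(10000, 1, seed = 6)
  expect_lt(abs(ln$gini - (2 * pnorm(1 / sqrt(2)) - 1)), 0.02)
})

test_that("simulated datasets are deterministic and match the generative rate", {
  cfg <- sim_config(n_rows = 4, n_cols = 5, n_provinces = 2, seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$table$deaths, b$table$deaths)
  expect_identical(a$truth$phi, b$truth$phi)

  # all effects off: national rate ~ baseline_rate within 3 MC SEs
  cfg0 <- sim_config(n_rows = 8, n_cols = 8, n_provinces = 2,
                     true_beta = null_beta, sigma_eps = 0, sigma_phi = 0,
                     seed = 8)
  s0 <- simulate_dataset(cfg0)
  P <- sum(s0$table$population)
  rate <- sum(s0$table$deaths) / P
  se <- sqrt(cfg0$baseline_rate / P)
  expect_lt(abs(rate - cfg0$baseline_rate), 3 * se)
  # stored truth gives the death expectations exactly
  expect_equal(unname(s0$truth$expected * s0$truth$lambda),
               cfg0$baseline_rate * s0$table$population)
})

test_that("spatial structure in the generator shows up in Moran's I of log SMR", {
  mi_for <- function(sigma_phi, seed) {
    cfg <- sim_config(n_rows = 8, n_cols = 8, n_provinces = 2,
                      true_beta = null_beta, sigma_eps = 0.05,
                      sigma_phi = sigma_phi, seed = seed)
    s <- simulate_dataset(cfg)
    E <- expected_counts(s$table)
    W <- servmort:::adjacency_matrix(s$adj)
    ape::Moran.I(log((s$table$deaths + 0.5) / E), W)$observed
  }
  seeds <- 1:10
  expect_gt(mean(vapply(seeds, function(s) mi_for(0.5, 900 + s), numeric(1))),
            mean(vapply(seeds, function(s) mi_for(0, 900 + s), numeric(1))))
})

test_that("impossible expected counts are caught or capped as configured", {
  cfg <- sim_config(n_rows = 2, n_cols = 2, n_provinces = 1, true_alpha = 6,
                    true_beta = null_beta, sigma_eps = 0, sigma_phi = 0,
                    seed = 9)
  expect_error(simulate_dataset(cfg), "exceed population")
  cfg$on_excess <- "cap"
  expect_warning(s <- simulate_dataset(cfg), "capping")
  expect_true(all(s$table$deaths <= s$table$population))
})
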