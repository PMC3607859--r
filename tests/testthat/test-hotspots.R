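# fake lambda samples whose per-unit exceedance probabilities are exact
lambda_with_probs <- function(probs, S = 1000) {
  lam <- vapply(probs, function(p) {
    n_hi <- round(S * p)
    c(rep(1.5, n_hi), rep(0.5, S - n_hi))
  }, numeric(S))
  colnames(lam) <- sprintf("a%02d", seq_along(probs))
  lam
}

test_that("hotspot flags are deterministic thresholding of exceedance probabilities", {
  fit <- fake_fit(lambda = lambda_with_probs(c(0.95, 0.89, 0.91)))
  h9 <- flag_hotspots(fit, 0.9)
  expect_equal(h9$hotspot, c(TRUE, FALSE, TRUE))
  expect_equal(attr(h9, "threshold"), 0.9)
  h8 <- flag_hotspots(fit, 0.8)
  expect_equal(h8$hotspot, rep(TRUE, 3))
  expect_error(flag_hotspots(fit, 1.2), "strictly in")
})

test_that("lowering the threshold never unflags a unit", {
  set.seed(51)
  fit <- fake_fit(lambda = lambda_with_probs(runif(20)))
  for (thr in c(0.95, 0.9, 0.8, 0.5)) {
    hi <- flag_hotspots(fit, thr)$hotspot
    lo <- flag_hotspots(fit, thr - 0.2)$hotspot
    expect_true(all(lo[hi]))
  }
})

test_that("service hotspot mapping flags the maximally deprived unit", {
  tab <- fixture_table(9)
  comps <- area_table_schema()$components
  # near-homogeneous table with one severely deprived unit
  for (cc in comps) tab[[cc]] <- rep(mean(tab[[cc]]), 9) + seq(0, 0.008, length.out = 9)
  for (cc in comps) tab[[cc]][5] <- tab[[cc]][5] + 0.4
  adj <- make_lattice(3, 3)
  tab$area_id <- adj$ids
  mc <- mcmc_config(n_burnin = 300, n_retain = 500, seed = 10)
  res <- service_hotspots(tab, adj, mcmc = mc)
  expect_equal(which.max(res$exceedance_prob), 5L)
  res2 <- service_hotspots(tab, adj, mcmc = mc)
  expect_identical(res$exceedance_prob, res2$exceedance_prob)

  flat <- tab
  for (cc in comps) flat[[cc]] <- rep(0.3, 9)
  w <- capture_warnings(r0 <- service_hotspots(flat, adj, mcmc = mc))
  expect_true(any(grepl("identical", w)))
  expect_false(any(r0$hotspot))
})

test_that("provincial rates, CIs and CI-overlap ranks behave as documented", {
  tab <- fixture_table(2)
  tab$province <- c("P1", "P1")
  tab$population <- c(1000L, 1000L)
  tab$deaths <- c(10L, 30L)
  ps <- suppressWarnings(provincial_summary(tab))
  expect_equal(ps$rate_per_1000, 20)

  # identical provinces tie on rank; distinct ones do not
  tab4 <- fixture_table(4)
  tab4$province <- c("P1", "P1", "P2", "P2")
  tab4$population <- rep(5000L, 4)
  tab4$deaths <- c(100L, 101L, 100L, 101L)
  ps <- provincial_summary(tab4)
  expect_equal(ps$rank_mortality, c(1L, 1L))

  # same rate, larger population: CI must be narrower
  big <- fixture_table(2)
  big$province <- c("P1", "P2")
  big$population <- c(1000L, 100000L)
  big$deaths <- c(20L, 2000L)
  ps <- suppressWarnings(provincial_summary(big))
  widths <- ps$rate_upper - ps$rate_lower
  expect_lt(widths[ps$population == 100000], widths[ps$population == 1000])

  # rates are invariant to how units are split within a province
  split2 <- data.frame(area_id = c("x1", "x2"), province = "P1",
                       population = c(4000, 6000), deaths = c(40, 80))
  split4 <- data.frame(area_id = paste0("y", 1:4), province = "P1",
                       population = c(2000, 2000, 3000, 3000),
                       deaths = c(15, 25, 35, 45))
  idx <- list(composite_score = c(0, 0), area_id = c("x1", "x2"))
  class(idx) <- "service_index"
  idx4 <- list(composite_score = c(0, 0, 0, 0), area_id = paste0("y", 1:4))
  class(idx4) <- "service_index"
  expect_equal(provincial_summary(split2, idx)$rate_per_1000,
               provincial_summary(split4, idx4)$rate_per_1000)

  zp <- split2; zp$population <- c(0, 0)
  expect_error(provincial_summary(zp, idx), "zero population")
})

test_that("GeoJSON export adds result properties without touching geometry", {
  gj <- list(type = "FeatureCollection", features = lapply(1:3, function(i) {
    list(type = "Feature",
         properties = list(area_id = sprintf("a%02d", i), name = LETTERS[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(i, 0), c(i + 1, 0),
                                                 c(i + 1, 1), c(i, 1),
                                                 c(i, 0)))))
  }))
  fin <- withr::local_tempfile(fileext = ".geojson")
  fout <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, fin, auto_unbox = TRUE, digits = NA)

  res <- flag_hotspots(fake_fit(lambda = lambda_with_probs(c(0.95, 0.5, 0.91))), 0.9)
  export_geojson(res, fin, fout)
  out <- jsonlite::read_json(fout)
  expect_length(out$features, 3)
  for (i in 1:3) {
    f <- out$features[[i]]
    expect_equal(f$properties$exceedance_prob, res$exceedance_prob[i])
    expect_equal(f$properties$hotspot, res$hotspot[i])
    expect_equal(f$geometry$coordinates, jsonlite::read_json(fin)$features[[i]]$geometry$coordinates)
  }

  res_bad <- res; res_bad$area_id[2] <- "zz"
  expect_error(export_geojson(res_bad, fin, fout), "zz")
})
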