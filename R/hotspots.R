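# Reporting products: hotspot flags from exceedance probabilities, a
# service-delivery analogue of the mortality risk map, provincial
# aggregation with ranking, and GeoJSON attribute export.

#' Flag hotspots by posterior exceedance probability
#'
#' A unit is flagged when its posterior probability that the smoothed
#' standardized ratio exceeds 1 is above `threshold`. The default 0.9 is
#' the stringent variant of Richardson's criterion (whose standard value
#' is 0.8). Lowering the threshold never unflags a unit.
#'
#' @param fit A `bym_fit`.
#' @param threshold Probability threshold in (0, 1).
#' @return A `hotspot_result` data frame: `area_id`, `smoothed_ratio`
#'   (posterior median), `exceedance_prob`, `hotspot`; the threshold used
#'   is recorded as an attribute.
#' @export
flag_hotspots <- function(fit, threshold = 0.9) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  probs <- exceedance_probs(fit)
  sm <- smoothed_ratios(fit)
  out <- data.frame(area_id = fit$area_id, smoothed_ratio = sm$smoothed,
                    exceedance_prob = unname(probs),
                    hotspot = unname(probs > threshold),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("hotspot_result", class(out))
  out
}

#' Service-delivery hotspot map
#'
#' Applies the same BYM machinery to a "standardized poor service ratio":
#' the composite score, shifted to be non-negative, is discretized to a
#' per-unit pseudo-count (`round(shifted_score * count_scale)`); every unit
#' gets the same size measure, so the expected count is the table-wide mean
#' count. Units whose smoothed ratio of observed to expected service
#' deprivation significantly exceeds 1 are flagged exactly as mortality
#' hotspots are. The count conversion is an explicit modelling device: only
#' its internal consistency (monotonicity, determinism) is meaningful, not
#' the absolute count scale.
#'
#' @param table A validated area table.
#' @param adj The companion adjacency.
#' @param index Optional precomputed [composite_index()].
#' @param mcmc An [mcmc_config()].
#' @param threshold Exceedance probability threshold (default 0.9).
#' @param count_scale Pseudo-count per unit of shifted composite score.
#' @return A `hotspot_result` data frame (see [flag_hotspots()]).
#' @export
service_hotspots <- function(table, adj, index = NULL, mcmc = mcmc_config(),
                             threshold = 0.9, count_scale = 25) {
  if (is.null(index)) index <- composite_index(table)
  shifted <- index$composite_score - min(index$composite_score)
  counts <- as.integer(round(shifted * count_scale))
  if (sum(counts) == 0L) {
    warning("composite scores are identical across units; nothing to map")
    out <- data.frame(area_id = as.character(table$area_id),
                      smoothed_ratio = NA_real_, exceedance_prob = NA_real_,
                      hotspot = FALSE, row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "threshold") <- threshold
    class(out) <- c("hotspot_result", class(out))
    return(out)
  }
  pseudo <- data.frame(area_id = as.character(table$area_id),
                       population = rep(1e6L, nrow(table)),
                       deaths = counts, stringsAsFactors = FALSE)
  fit <- fit_bym(pseudo, adj, spec = model_spec(), mcmc = mcmc)
  flag_hotspots(fit, threshold = threshold)
}

#' Provincial aggregation and ranking
#'
#' Per province: the crude mortality rate per 1000 (`sum(deaths) /
#' sum(population) * 1000`) with a normal-approximation binomial 95% CI,
#' and the population-weighted mean composite service score with a 95% CI
#' from the across-unit variance (`1.96 * sd(unit scores) /
#' sqrt(n units)`). Provinces are ranked in descending order; a province
#' whose CI overlaps the current rank-group leader's CI shares the
#' leader's rank, otherwise it starts a new group at its position.
#'
#' @param table A validated area table with province labels.
#' @param index Optional precomputed [composite_index()].
#' @return A `provincial_summary` data frame sorted by descending rate.
#' @export
provincial_summary <- function(table, index = NULL) {
  if (is.null(index)) index <- composite_index(table)
  provs <- split(seq_len(nrow(table)), table$province)
  rows <- lapply(names(provs), function(pv) {
    i <- provs[[pv]]
    N <- sum(table$population[i])
    if (N <= 0) stop("province with zero population: ", pv, call. = FALSE)
    D <- sum(table$deaths[i])
    phat <- D / N
    se <- sqrt(phat * (1 - phat) / N)
    sc <- index$composite_score[i]
    w <- table$population[i]
    sc_mean <- sum(w * sc) / sum(w)
    sc_se <- if (length(i) > 1L) stats::sd(sc) / sqrt(length(i)) else 0
    data.frame(province = pv, n_units = length(i), population = N, deaths = D,
               rate_per_1000 = 1000 * phat,
               rate_lower = 1000 * max(0, phat - 1.96 * se),
               rate_upper = 1000 * (phat + 1.96 * se),
               score = sc_mean,
               score_lower = sc_mean - 1.96 * sc_se,
               score_upper = sc_mean + 1.96 * sc_se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  rank_with_ties <- function(value, lower, upper) {
    ord <- order(-value)
    rk <- integer(length(value))
    leader <- NA_integer_
    for (pos in seq_along(ord)) {
      i <- ord[pos]
      if (pos == 1L || lower[i] > upper[leader] || upper[i] < lower[leader]) {
        leader <- i
        rk[i] <- pos
      } else {
        rk[i] <- rk[leader]
      }
    }
    rk
  }
  out$rank_mortality <- rank_with_ties(out$rate_per_1000, out$rate_lower, out$rate_upper)
  out$rank_service <- rank_with_ties(out$score, out$score_lower, out$score_upper)
  out <- out[order(-out$rate_per_1000), ]
  rownames(out) <- NULL
  class(out) <- c("provincial_summary", class(out))
  out
}

#' Attach per-unit results to GeoJSON features
#'
#' Reads a GeoJSON FeatureCollection, matches each feature to a result row
#' via the feature property `id_property`, adds the smoothed ratio,
#' exceedance probability and hotspot flag as properties, and writes the
#' result. Geometries pass through unchanged.
#'
#' @param results A `hotspot_result` data frame.
#' @param geojson_in Path to the input FeatureCollection.
#' @param geojson_out Output path.
#' @param id_property Feature property holding the area id (default
#'   `"area_id"`).
#' @return `geojson_out`, invisibly.
#' @export
export_geojson <- function(results, geojson_in, geojson_out,
                           id_property = "area_id") {
  gj <- jsonlite::read_json(geojson_in)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  feat_ids <- vapply(gj$features, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) NA_character_ else as.character(id)
  }, character(1))
  missing <- setdiff(results$area_id, feat_ids)
  if (length(missing) > 0L) {
    stop("result id(s) missing from geometry file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- match(feat_ids, results$area_id)
  for (k in seq_along(gj$features)) {
    r <- rows[k]
    if (is.na(r)) next
    gj$features[[k]]$properties$smoothed_ratio <- results$smoothed_ratio[r]
    gj$features[[k]]$properties$exceedance_prob <- results$exceedance_prob[r]
    gj$features[[k]]$properties$hotspot <- results$hotspot[r]
  }
  jsonlite::write_json(gj, geojson_out, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(geojson_out)
}
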