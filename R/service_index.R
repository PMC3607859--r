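# Composite service (non-)delivery index: per-component z-scores summed with
# equal weight, a square-root transformed model covariate, the Gini
# coefficient of household income, the component correlation matrix and the
# high-inequality classification.

#' Normalize a vector to z-scores
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation. A
#' constant vector has no scale and maps to all zeros with a warning.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector with sample mean 0 and sample sd 1 (non-constant
#'   input).
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("zscore needs at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("constant input to zscore; returning zeros")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' Build the composite service (non-)delivery index
#'
#' Each of the seven components (proportion with no water service provider,
#' no toilet, no refuse disposal, no electricity, no schooling, living in
#' informal housing, and the population-to-health-facility ratio) is
#' z-scored across units and the z-scores are summed with equal weight.
#' Higher scores mean poorer service delivery. Components are measured on
#' different scales; z-scoring makes the sum scale-free, so the composite is
#' invariant to affine rescaling of any raw component.
#'
#' Informal housing correlates negatively with the other deprivation
#' components in typical data; by default it enters with the sign it is
#' stored with, and `weights` allows a per-component sign flip or
#' reweighting.
#'
#' @param table A validated area table.
#' @param weights Named numeric vector of per-component weights; defaults to
#'   1 for every component.
#' @return A `service_index` object: list with `area_id`, `z` (n x 7 matrix
#'   of component z-scores), `composite_score` (row sums, mean 0 across
#'   units) and `transformed_score` (see [transform_score()]).
#' @export
composite_index <- function(table, weights = NULL) {
  comps <- .component_cols
  missing <- setdiff(comps, names(table))
  if (length(missing) > 0L) {
    stop("missing component column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(comps)), comps)
  if (is.null(names(weights)) || !all(comps %in% names(weights))) {
    stop("weights must be named by component", call. = FALSE)
  }
  z <- vapply(comps, function(cc) zscore(table[[cc]]), numeric(nrow(table)))
  if (nrow(table) == 1L) z <- matrix(z, nrow = 1L, dimnames = list(NULL, comps))
  score <- as.numeric(z %*% weights[comps])
  idx <- structure(list(area_id = as.character(table$area_id), z = z,
                        composite_score = score, weights = weights[comps]),
                   class = "service_index")
  idx$transformed_score <- transform_score(idx)
  idx
}

#' Square-root transform of the composite score
#'
#' The raw composite (a sum of z-scores) can be negative; it is shifted by
#' its minimum and square-rooted: `sqrt(score - min(score))`. The transform
#' is zero for the best-served unit, non-negative, and strictly
#' rank-preserving. It linearizes the relationship between the score and
#' log-mortality for use as a Poisson-model covariate.
#'
#' @param index A `service_index`, or a numeric vector of composite scores.
#' @return Non-negative numeric vector.
#' @export
transform_score <- function(index) {
  score <- if (inherits(index, "service_index")) index$composite_score else index
  sqrt(score - min(score))
}

#' Gini coefficient of a non-negative income vector
#'
#' Half the relative mean absolute difference over all ordered pairs:
#' `G = mean(|x_i - x_j|) / (2 * mean(x))`. Computed in O(n log n) via the
#' sorted-vector identity; equal to the brute-force pairwise definition
#' exactly. Scale-invariant; 0 for equal incomes; a single value gives 0.
#'
#' @param incomes Non-negative numeric vector, not all zero.
#' @return Gini coefficient in `[0, 1)`.
#' @export
compute_gini <- function(incomes) {
  if (length(incomes) < 1L) stop("empty income vector", call. = FALSE)
  if (any(incomes < 0)) stop("incomes must be non-negative", call. = FALSE)
  if (all(incomes == 0)) stop("Gini undefined for all-zero incomes", call. = FALSE)
  n <- length(incomes)
  if (n == 1L) return(0)
  x <- sort(incomes)
  # sum_{i<j} (x_j - x_i) = sum_i (2i - n - 1) x_(i); ordered-pair mean
  # |diff| = 2 * that / n^2
  num <- sum((2 * seq_len(n) - n - 1) * x)
  num / (n^2 * mean(x))
}

#' Pearson correlation matrix of the service components
#'
#' Pairwise Pearson correlations among the seven components with two-sided
#' p-values and a 5%-level significance flag. A constant component has no
#' defined correlation; its entries are reported as `NA`.
#'
#' @param table A validated area table with n >= 3 units.
#' @return A `component_correlation` object: list with matrices `r`, `p`
#'   and logical `significant`.
#' @export
component_correlation <- function(table) {
  comps <- .component_cols
  if (nrow(table) < 3L) stop("need at least 3 units for correlations", call. = FALSE)
  X <- as.matrix(as.data.frame(table)[, comps])
  k <- length(comps)
  r <- matrix(NA_real_, k, k, dimnames = list(comps, comps))
  p <- r
  for (a in seq_len(k)) {
    for (b in seq_len(a)) {
      if (stats::sd(X[, a]) == 0 || stats::sd(X[, b]) == 0) next
      if (a == b) {
        r[a, b] <- 1
        p[a, b] <- 0
      } else {
        ct <- stats::cor.test(X[, a], X[, b], method = "pearson")
        r[a, b] <- r[b, a] <- unname(ct$estimate)
        p[a, b] <- p[b, a] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, significant = p < 0.05),
            class = "component_correlation")
}

#' Flag high-income-inequality units
#'
#' Units whose Gini lies strictly above a quantile of the observed Ginis
#' (default: the upper tertile, quantile 2/3) are flagged high. With the
#' strict comparison, all-equal Ginis flag nothing and `quantile = 0` flags
#' everything above the minimum.
#'
#' @param ginis Numeric vector of per-unit Gini coefficients.
#' @param quantile Threshold quantile in `[0, 1)`; default `2/3`.
#' @return Logical vector, `TRUE` = high inequality.
#' @export
classify_inequality <- function(ginis, quantile = 2 / 3) {
  if (quantile < 0 || quantile >= 1) stop("quantile must lie in [0, 1)", call. = FALSE)
  thr <- stats::quantile(ginis, probs = quantile, names = FALSE, type = 7)
  ginis > thr
}
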