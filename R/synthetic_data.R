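# Synthetic areal data with the statistical structure the analysis assumes:
# lattice adjacency, an intrinsic-CAR spatial field, correlated service
# components, lognormal household incomes, and Poisson death counts generated
# from log lambda_i = alpha + eps_i + phi_i + X_i beta.

#' Simulation configuration
#'
#' Defaults follow a South-Africa-scale reference preset: 248 units on an 8 x 31 rook
#' lattice grouped into 9 pseudo-provinces, covariate effects of the
#' magnitude estimated for South African local municipalities (relative
#' risk 1.84 per unit of the square-root service score, 1.14 for high
#' income inequality, 0.97 / 0.73 for high-density non-metro / metro
#' classes, 1.02 per HIV percentage point), a baseline mortality rate of
#' 15 per 1000, and moderately correlated service components.
#'
#' @param n_rows,n_cols Lattice dimensions (units = `n_rows * n_cols`).
#' @param contiguity `"rook"` (shared edges) or `"queen"` (edges+corners).
#' @param n_provinces Number of pseudo-provinces (contiguous column bands).
#' @param true_alpha National-average log relative risk against
#'   `baseline_rate` (the covariate effects are centered at generation
#'   time and the realized intercept, recorded in `truth`, absorbs their
#'   mean, so the crude national rate stays near
#'   `baseline_rate * exp(true_alpha)`).
#' @param true_beta Named vector of log relative risks for the covariates
#'   `service_sqrt`, `inequality_high`, `hiv_centered`,
#'   `density_high_nonmetro`, `density_high_metro` (see
#'   [prepare_covariates()]).
#' @param sigma_eps Std. dev. of the unstructured heterogeneity term.
#' @param sigma_phi Conditional std. dev. of the intrinsic-CAR spatial term.
#' @param baseline_rate Reference deaths per person (in (0, 1)).
#' @param pop_range Min/max population per unit.
#' @param component_corr Target latent correlation among service components.
#' @param n_households Households sampled per unit for the income draw.
#' @param income_sigma Lognormal sigma of household income.
#' @param density_probs Probabilities of the three density classes.
#' @param hiv_mean,hiv_sd Mean and sd of HIV seroprevalence (percent).
#' @param covariate_cols `NULL` to generate risk from the standard model
#'   design ([prepare_covariates()]), or a character vector of table
#'   columns (e.g. individual service components) used directly as the
#'   generative design matrix; `true_beta` must then be named by those
#'   columns.
#' @param on_excess What to do when `baseline_rate * lambda_i >= 1` (the
#'   expected deaths would exceed the population): `"error"` or `"cap"`
#'   (cap lambda with a warning).
#' @param log_risk_offset Optional length-n vector added to the log relative
#'   risk (used to embed known excess-risk clusters).
#' @param seed Integer seed; every random draw is a deterministic function
#'   of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_rows = 8, n_cols = 31, contiguity = "rook",
                       n_provinces = 9,
                       true_alpha = 0,
                       true_beta = c(service_sqrt = log(1.84),
                                     inequality_high = log(1.14),
                                     hiv_centered = log(1.02),
                                     density_high_nonmetro = log(0.97),
                                     density_high_metro = log(0.73)),
                       sigma_eps = 0.1, sigma_phi = 0.3,
                       baseline_rate = 0.015, pop_range = c(5000, 50000),
                       component_corr = 0.5, n_households = 300,
                       income_sigma = 0.9,
                       density_probs = c(0.6, 0.25, 0.15),
                       hiv_mean = 20, hiv_sd = 8,
                       covariate_cols = NULL,
                       on_excess = c("error", "cap"),
                       log_risk_offset = NULL,
                       seed = 1L) {
  cfg <- list(n_rows = n_rows, n_cols = n_cols, contiguity = contiguity,
              n_provinces = n_provinces, true_alpha = true_alpha,
              true_beta = true_beta, sigma_eps = sigma_eps,
              sigma_phi = sigma_phi, baseline_rate = baseline_rate,
              pop_range = pop_range, component_corr = component_corr,
              n_households = n_households, income_sigma = income_sigma,
              density_probs = density_probs, hiv_mean = hiv_mean,
              hiv_sd = hiv_sd, covariate_cols = covariate_cols,
              on_excess = match.arg(on_excess),
              log_risk_offset = log_risk_offset, seed = as.integer(seed))
  stopifnot(cfg$n_rows * cfg$n_cols >= 4,
            cfg$baseline_rate > 0, cfg$baseline_rate < 1,
            cfg$sigma_eps >= 0, cfg$sigma_phi >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Regular lattice adjacency
#'
#' @param n_rows,n_cols Grid dimensions, both >= 2.
#' @param contiguity `"rook"` (4-neighbour) or `"queen"` (8-neighbour).
#' @return An `adjacency` over ids `"u001", "u002", ...` in row-major order.
#' @export
make_lattice <- function(n_rows, n_cols, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  if (n_rows < 2 || n_cols < 2) stop("lattice dimensions must be >= 2", call. = FALSE)
  n <- n_rows * n_cols
  ids <- sprintf("u%03d", seq_len(n))
  idx <- function(r, c) (r - 1L) * n_cols + c
  steps <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (contiguity == "queen") {
    steps <- rbind(steps, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nb <- vector("list", n)
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      rr <- r + steps[, 1]; cc <- c + steps[, 2]
      ok <- rr >= 1 & rr <= n_rows & cc >= 1 & cc <= n_cols
      nb[[idx(r, c)]] <- ids[idx(rr[ok], cc[ok])]
    }
  }
  names(nb) <- ids
  adjacency(nb)
}

#' Sample an intrinsic-CAR spatial field
#'
#' Draws from the intrinsic conditional-autoregressive distribution with
#' precision `(1/sigma_phi^2) * (D - W)` restricted to the sum-to-zero
#' subspace: the zero-eigenvalue mode of each connected component is
#' excluded, so each component (and hence the field) has mean zero exactly.
#' Isolated units receive `phi = 0`. `sigma_phi` is the conditional standard
#' deviation scale: `phi_i | phi_(-i) ~ N(mean of neighbours,
#' sigma_phi^2 / n_i)`.
#'
#' @param adj An `adjacency` object.
#' @param sigma_phi Conditional sd (>= 0; 0 gives an all-zero field).
#' @param seed Optional integer seed.
#' @return Numeric vector named by area id, mean zero.
#' @export
simulate_car_field <- function(adj, sigma_phi, seed = NULL) {
  stopifnot(inherits(adj, "adjacency"), sigma_phi >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(adj$ids)
  phi <- stats::setNames(rep(0, n), adj$ids)
  if (sigma_phi == 0) return(phi)
  g <- igraph::graph_from_data_frame(
    d = do.call(rbind, lapply(adj$ids, function(i) {
      if (length(adj$nb[[i]]) == 0L) return(NULL)
      data.frame(from = i, to = adj$nb[[i]], stringsAsFactors = FALSE)
    })),
    directed = FALSE,
    vertices = data.frame(name = adj$ids, stringsAsFactors = FALSE))
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  W <- adjacency_matrix(adj)
  tau <- 1 / sigma_phi^2
  for (k in seq_len(comp$no)) {
    members <- adj$ids[comp$membership[adj$ids] == k]
    m <- length(members)
    if (m < 2L) next  # isolated unit: phi fixed at 0
    Wk <- W[members, members, drop = FALSE]
    Q <- diag(rowSums(Wk)) - Wk
    eg <- eigen(Q, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    z <- stats::rnorm(sum(pos), sd = 1 / sqrt(tau * eg$values[pos]))
    phi[members] <- as.numeric(eg$vectors[, pos, drop = FALSE] %*% z)
    phi[members] <- phi[members] - mean(phi[members])  # numerical recentring
  }
  phi
}

#' Correlated service-component proportions
#'
#' Gaussian-copula generator: a latent multivariate normal with
#' equicorrelation `component_corr` across the seven components is pushed
#' through a probit transform `pnorm(a_k + b * Z)`, so every output lies in
#' (0, 1) and component k has marginal mean near its target level. The
#' health-facility component is generated on the same `[0, 1]` scale (a
#' normalized population-per-facility pressure).
#'
#' @param n Number of units.
#' @param component_corr Latent equicorrelation; must keep the 7 x 7
#'   equicorrelation matrix positive definite (`> -1/6`).
#' @param seed Optional integer seed.
#' @param levels Named target marginal means for the seven components.
#' @param spread Latent slope `b` controlling marginal dispersion.
#' @return n x 7 matrix with columns named as in [area_table_schema()].
#' @export
simulate_components <- function(n, component_corr, seed = NULL,
                                levels = c(comp_no_water = 0.25,
                                           comp_no_toilet = 0.12,
                                           comp_no_refuse = 0.35,
                                           comp_no_electricity = 0.20,
                                           comp_no_schooling = 0.18,
                                           comp_informal = 0.15,
                                           comp_health_ratio = 0.50),
                                spread = 0.7) {
  k <- length(.component_cols)
  if (component_corr <= -1 / (k - 1) || component_corr > 1) {
    stop("component_corr must keep the equicorrelation matrix positive definite",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  R <- matrix(component_corr, k, k); diag(R) <- 1
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * k), n, k) %*% L
  a <- stats::qnorm(levels[.component_cols]) * sqrt(1 + spread^2)
  out <- stats::pnorm(sweep(Z * spread, 2, a, "+"))
  colnames(out) <- .component_cols
  out
}

#' Lognormal household incomes and their Gini coefficient
#'
#' @param n_households Number of households (>= 2).
#' @param lognormal_sigma Lognormal sigma; 0 gives equal incomes and Gini 0.
#'   The population Gini of a lognormal is `2 * pnorm(sigma / sqrt(2)) - 1`.
#' @param seed Optional integer seed.
#' @param median_income Median income (scale parameter, currency units).
#' @return List with `incomes` and `gini` (from [compute_gini()]).
#' @export
simulate_incomes_and_gini <- function(n_households, lognormal_sigma, seed = NULL,
                                      median_income = 30000) {
  stopifnot(n_households >= 2, lognormal_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  incomes <- stats::rlnorm(n_households, meanlog = log(median_income),
                           sdlog = lognormal_sigma)
  list(incomes = incomes, gini = compute_gini(incomes))
}

#' Simulate a full areal dataset
#'
#' Generates, in order: the lattice adjacency and pseudo-province labels;
#' populations; correlated service components; household incomes and Gini
#' per unit; HIV seroprevalence (normal, truncated to `[0, 100]`); density
#' classes; then the latent field `log lambda_i = alpha + X_i beta + eps_i
#' + phi_i` (design matrix from [prepare_covariates()], so generation and
#' fitting share one covariate definition) and death counts
#' `O_i ~ Poisson(E_i lambda_i)` with `E_i = baseline_rate * population_i`.
#' All latent values are stored in `truth` for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_dataset` list: `table` (validated area table, including
#'   the covariate columns actually used), `adj`, and `truth` (alpha, beta,
#'   eps, phi, lambda, expected, design matrix `X`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_rows * cfg$n_cols
  adj <- make_lattice(cfg$n_rows, cfg$n_cols, cfg$contiguity)
  ids <- adj$ids

  # contiguous column bands as pseudo-provinces
  col_of <- rep(seq_len(cfg$n_cols), times = cfg$n_rows)
  band <- ceiling(col_of * min(cfg$n_provinces, cfg$n_cols) / cfg$n_cols)
  province <- sprintf("P%d", band)

  population <- as.integer(round(stats::runif(n, cfg$pop_range[1], cfg$pop_range[2])))
  comps <- simulate_components(n, cfg$component_corr)
  ginis <- numeric(n)
  incomes <- vector("list", n)
  for (i in seq_len(n)) {
    ig <- simulate_incomes_and_gini(cfg$n_households, cfg$income_sigma)
    ginis[i] <- ig$gini
    incomes[[i]] <- round(ig$incomes, 2)
  }
  hiv <- pmin(100, pmax(0, stats::rnorm(n, cfg$hiv_mean, cfg$hiv_sd)))
  density_class <- sample(.density_levels, n, replace = TRUE,
                          prob = cfg$density_probs)

  table <- data.frame(area_id = ids, province = province,
                      population = population, deaths = 0L,
                      comps, hiv_prev = hiv, gini = ginis,
                      density_class = density_class,
                      stringsAsFactors = FALSE)
  table$incomes <- incomes

  X <- if (is.null(cfg$covariate_cols)) {
    prepare_covariates(table)
  } else {
    as.matrix(as.data.frame(table)[, cfg$covariate_cols, drop = FALSE])
  }
  beta <- cfg$true_beta[colnames(X)]
  if (any(is.na(beta))) {
    stop("true_beta must name every covariate column: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  eps <- stats::rnorm(n, 0, cfg$sigma_eps)
  phi <- simulate_car_field(adj, cfg$sigma_phi)
  # anchor the national level: true_alpha is the average log relative risk
  # against baseline_rate, so the covariate effects are centered here and
  # the realized intercept (recorded in truth) absorbs their mean
  xb <- as.numeric(X %*% beta)
  alpha <- cfg$true_alpha - mean(xb)
  eta <- alpha + xb + eps + phi
  if (!is.null(cfg$log_risk_offset)) {
    stopifnot(length(cfg$log_risk_offset) == n)
    eta <- eta + cfg$log_risk_offset
  }
  lambda <- exp(eta)
  if (any(cfg$baseline_rate * lambda >= 1)) {
    if (cfg$on_excess == "error") {
      stop("expected deaths would exceed population (baseline_rate * lambda >= 1) ",
           "for ", sum(cfg$baseline_rate * lambda >= 1), " unit(s); ",
           "reduce effect sizes or set on_excess = 'cap'", call. = FALSE)
    }
    warning("capping relative risk so expected deaths stay below population")
    lambda <- pmin(lambda, 0.9 / cfg$baseline_rate)
  }
  expected <- cfg$baseline_rate * population
  table$deaths <- stats::rpois(n, expected * lambda)
  table$deaths <- pmin(table$deaths, population)
  table <- as_area_table(table)

  structure(list(table = table, adj = adj,
                 truth = list(alpha = alpha, beta = beta, eps = eps,
                              phi = phi, lambda = lambda, expected = expected,
                              X = X, config = cfg)),
            class = "sim_dataset")
}

#' Model design matrix from an area table
#'
#' Builds the covariates of the multivariable mortality model: the
#' square-root transformed composite service score (via
#' [composite_index()]), the high-income-inequality indicator (upper
#' tertile of Gini, [classify_inequality()]), HIV seroprevalence centered
#' at its sample mean (centering changes only the intercept, not the RR
#' per percentage point), and indicators for the high-density non-metro
#' and metro classes (low/medium density is the reference).
#'
#' @param table A validated area table (gini present or computable).
#' @param index Optional precomputed [composite_index()]; built if `NULL`.
#' @return n x 5 numeric matrix with columns `service_sqrt`,
#'   `inequality_high`, `hiv_centered`, `density_high_nonmetro`,
#'   `density_high_metro`.
#' @export
prepare_covariates <- function(table, index = NULL) {
  if (is.null(index)) index <- composite_index(table)
  gini <- table$gini
  if (is.null(gini) || any(!is.finite(gini))) {
    gini <- vapply(table$incomes, compute_gini, numeric(1))
  }
  X <- cbind(service_sqrt = index$transformed_score,
             inequality_high = as.numeric(classify_inequality(gini)),
             hiv_centered = table$hiv_prev - mean(table$hiv_prev),
             density_high_nonmetro = as.numeric(table$density_class == "high_nonmetro"),
             density_high_metro = as.numeric(table$density_class == "high_metro"))
  rownames(X) <- as.character(table$area_id)
  X
}
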