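# Fitting the BYM convolution CAR spatial Poisson model:
#   O_i ~ Poisson(E_i lambda_i),  log lambda_i = alpha + X_i beta + eps_i + phi_i
# with internally standardized expected counts, two-chain adaptive
# Metropolis-within-Gibbs MCMC (compiled core), a Monte-Carlo-error stopping
# rule, Gelman-Rubin diagnostics, DIC, covariate relative-risk summaries and
# per-unit exceedance probabilities.

#' @useDynLib servmort, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Expected death counts by internal standardization
#'
#' `E_i = (sum of deaths / sum of population) * population_i`, so that
#' `sum(E) == sum(O)` exactly and the relative risks are standardized to
#' the table's overall rate.
#'
#' @param table A validated area table.
#' @return Numeric vector of expected counts named by area id.
#' @export
expected_counts <- function(table) {
  if (sum(table$population) <= 0) stop("total population must be positive", call. = FALSE)
  if (sum(table$deaths) == 0) {
    warning("zero total deaths: expected counts are all zero and the model is unfittable")
  }
  rate <- sum(table$deaths) / sum(table$population)
  E <- rate * table$population
  s <- sum(E)
  if (s > 0) E <- E * (sum(table$deaths) / s)  # absorb rounding in the sum
  stats::setNames(E, as.character(table$area_id))
}

#' Model specification
#'
#' @param covariates Either `NULL` (null model: intercept plus random
#'   effects only), a character vector of numeric columns of the area
#'   table, or a numeric design matrix with one row per unit.
#' @param spatial Include the intrinsic-CAR spatial term `phi`?
#' @param heterogeneity Include the unstructured term `eps`? Setting both
#'   to `FALSE` gives a standard (non-spatial) Poisson regression.
#' @param prior_alpha_var,prior_beta_var Variances of the vague normal
#'   priors on the intercept and coefficients.
#' @param prior_tau_shape,prior_tau_rate Gamma(shape, rate) prior for both
#'   precision parameters; the default Gamma(0.5, 0.0005) is the
#'   conventional weakly-informative disease-mapping choice.
#' @return A `model_spec` list.
#' @export
model_spec <- function(covariates = NULL, spatial = TRUE, heterogeneity = TRUE,
                       prior_alpha_var = 1e6, prior_beta_var = 1e6,
                       prior_tau_shape = 0.5, prior_tau_rate = 0.0005) {
  stopifnot(prior_alpha_var > 0, prior_beta_var > 0,
            prior_tau_shape > 0, prior_tau_rate > 0)
  structure(list(covariates = covariates, spatial = spatial,
                 heterogeneity = heterogeneity,
                 prior_alpha_var = prior_alpha_var,
                 prior_beta_var = prior_beta_var,
                 prior_tau_shape = prior_tau_shape,
                 prior_tau_rate = prior_tau_rate),
            class = "model_spec")
}

#' MCMC configuration
#'
#' Two chains by default, each with its own burn-in (during which
#' random-walk scales adapt; adaptation is frozen afterwards so the
#' retained chain is a valid fixed-kernel sample). After the initial run
#' the batch-means Monte-Carlo error of every monitored scalar (intercept,
#' coefficients, precisions) must be below `mc_error_frac` of that
#' parameter's posterior standard deviation; otherwise sampling is extended
#' in blocks until the rule passes or `max_samples` pooled retained
#' samples are reached (then the fit is flagged, never silently accepted).
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_burnin Burn-in iterations per chain.
#' @param n_retain Retained iterations per chain per block.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param mc_error_frac Monte-Carlo error threshold as a fraction of the
#'   posterior sd (default 0.05).
#' @param n_batches Batches for the batch-means MC error estimate.
#' @param max_samples Hard cap on pooled retained samples.
#' @param adapt_interval Iterations between scale adaptations in burn-in.
#' @param field_thin Storage thinning for the per-unit arrays (`eps`,
#'   `phi`, relative risks): every `field_thin`-th retained sample is
#'   stored, bounding memory on long runs; scalar parameters and the
#'   deviance are always stored unthinned. Default: chosen so that at
#'   most ~50,000 thinned field samples can accumulate at `max_samples`.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2, n_burnin = 5000, n_retain = 5000,
                        seed = 1L, mc_error_frac = 0.05, n_batches = 30,
                        max_samples = 200000, adapt_interval = 100,
                        field_thin = NULL) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_retain >= n_batches)
  if (is.null(field_thin)) field_thin <- max(1L, as.integer(ceiling(max_samples / 50000)))
  stopifnot(field_thin >= 1, n_retain %/% field_thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_burnin = as.integer(n_burnin),
                 n_retain = as.integer(n_retain), seed = as.integer(seed),
                 mc_error_frac = mc_error_frac, n_batches = as.integer(n_batches),
                 max_samples = as.integer(max_samples),
                 adapt_interval = as.integer(adapt_interval),
                 field_thin = as.integer(field_thin)),
            class = "mcmc_config")
}

# batch-means Monte-Carlo standard error of a single chain
.mc_error <- function(x, n_batches = 30) {
  n <- length(x)
  bs <- n %/% n_batches
  if (bs < 1L) return(NA_real_)
  bm <- colMeans(matrix(x[seq_len(bs * n_batches)], nrow = bs))
  stats::sd(bm) / sqrt(n_batches)
}

.build_design <- function(table, covariates) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = nrow(table), ncol = 0))
  }
  if (is.character(covariates)) {
    missing <- setdiff(covariates, names(table))
    if (length(missing) > 0L) {
      stop("covariate column(s) not in table: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(as.data.frame(table)[, covariates, drop = FALSE])
    storage.mode(X) <- "double"
    return(X)
  }
  X <- as.matrix(covariates)
  if (nrow(X) != nrow(table)) stop("design matrix row count mismatch", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

#' Fit the BYM convolution model
#'
#' Runs adaptive Metropolis-within-Gibbs MCMC (compiled core) on the BYM
#' convolution model. The design matrix is mean-centered internally for
#' sampling efficiency; reported intercept samples are mapped back to the
#' uncentered scale, so coefficients and the intercept are on the natural
#' scale of the covariates as supplied. Isolated (zero-neighbour) units
#' keep `phi = 0` and are carried by the heterogeneity term alone.
#' Deterministic given `mcmc$seed`.
#'
#' @param table A validated area table.
#' @param adj An `adjacency` covering every unit in the table.
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_config()].
#' @return A `bym_fit` object: per-chain posterior sample arrays for
#'   `alpha`, `beta`, `eps`, `phi`, the precisions, per-unit relative risks
#'   `lambda` and the deviance trace, plus pooled arrays, expected counts,
#'   and the Monte-Carlo-error report (`mc_ok`, `failed`).
#' @export
fit_bym <- function(table, adj, spec = model_spec(), mcmc = mcmc_config()) {
  stopifnot(inherits(adj, "adjacency"))
  ids <- as.character(table$area_id)
  if (!setequal(ids, adj$ids)) {
    stop("area table and adjacency cover different units; run validate_areal()",
         call. = FALSE)
  }
  E <- expected_counts(table)
  if (any(E <= 0)) stop("non-positive expected count; model unfittable", call. = FALSE)
  O <- as.numeric(table$deaths)
  n <- length(O)

  X <- .build_design(table, spec$covariates)
  p <- ncol(X)
  xbar <- if (p > 0) colMeans(X) else numeric(0)
  Xc <- if (p > 0) sweep(X, 2, xbar) else X

  # flat 0-based neighbour index in table order
  nb_idx_list <- lapply(ids, function(i) match(adj$nb[[i]], ids) - 1L)
  n_nb <- vapply(nb_idx_list, length, integer(1))
  nb_index <- as.integer(unlist(nb_idx_list))
  if (is.null(nb_index)) nb_index <- integer(0)
  nb_start <- as.integer(c(0L, cumsum(n_nb)[-n]))

  active <- n_nb > 0L
  car_rank <- 0L
  Qvec <- matrix(0, 0, 0)
  Qval <- numeric(0)
  if (spec$spatial && any(active)) {
    W <- adjacency_matrix(adj, ids)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
    comp <- igraph::components(g)
    n_comp_active <- length(unique(comp$membership[active]))
    car_rank <- as.integer(sum(active) - n_comp_active)
    if (spec$heterogeneity && all(active) && n > 1L) {
      # spectral basis of the graph Laplacian for the exact joint
      # eps/phi split move (see the sampler source)
      eg <- eigen(diag(rowSums(W)) - W, symmetric = TRUE)
      Qval <- eg$values
      Qval[Qval < max(Qval) * 1e-10] <- 0
      Qvec <- eg$vectors
    }
  }

  xsd <- if (p > 0) pmax(apply(Xc, 2, stats::sd), 1e-8) else numeric(0)
  chains <- vector("list", mcmc$n_chains)
  rng_states <- vector("list", mcmc$n_chains)
  scale_states <- vector("list", mcmc$n_chains)
  alpha0 <- log((sum(O) + 0.5) / sum(E))

  run_block <- function(chain, init, scales, n_burnin, n_keep) {
    .bym_mcmc_cpp(O, log(E), Xc, nb_index, nb_start, n_nb, car_rank,
                  Qvec, Qval, spec$spatial, spec$heterogeneity,
                  spec$prior_alpha_var, spec$prior_beta_var,
                  spec$prior_tau_shape, spec$prior_tau_rate,
                  as.integer(n_burnin), as.integer(n_keep),
                  mcmc$adapt_interval, mcmc$field_thin, init, scales)
  }

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    init <- list(alpha = alpha0 + stats::rnorm(1, 0, 0.3),
                 beta = stats::rnorm(p, 0, 0.1),
                 eps = rep(0, n), phi = rep(0, n),
                 tau_eps = 10, tau_phi = 10)
    scales <- list(alpha = 0.1, beta = if (p > 0) 0.2 / xsd else numeric(0),
                   eps = 0.3, phi = 0.3, adapt = TRUE)
    res <- run_block(ch, init, scales, mcmc$n_burnin, mcmc$n_retain)
    res$scales$adapt <- FALSE
    chains[[ch]] <- res
    scale_states[[ch]] <- res$scales
    rng_states[[ch]] <- .Random.seed
  }

  monitored <- function() {
    out <- list(alpha = lapply(chains, `[[`, "alpha"))
    if (p > 0) for (k in seq_len(p)) {
      out[[colnames(X)[k]]] <- lapply(chains, function(c) c$beta[, k])
    }
    if (spec$heterogeneity) out$tau_eps <- lapply(chains, `[[`, "tau_eps")
    if (spec$spatial && car_rank > 0) out$tau_phi <- lapply(chains, `[[`, "tau_phi")
    out
  }
  mc_check <- function() {
    mon <- monitored()
    vapply(mon, function(xs) {
      se <- sqrt(sum(vapply(xs, .mc_error, numeric(1), mcmc$n_batches)^2)) /
        length(xs)
      s <- stats::sd(unlist(xs))
      if (!is.finite(s) || s == 0) TRUE else is.finite(se) && se < mcmc$mc_error_frac * s
    }, logical(1))
  }

  append_block <- function(a, b) {
    a$alpha <- c(a$alpha, b$alpha)
    a$beta <- rbind(a$beta, b$beta)
    a$eps <- rbind(a$eps, b$eps)
    a$phi <- rbind(a$phi, b$phi)
    a$tau_eps <- c(a$tau_eps, b$tau_eps)
    a$tau_phi <- c(a$tau_phi, b$tau_phi)
    a$lambda <- rbind(a$lambda, b$lambda)
    a$deviance <- c(a$deviance, b$deviance)
    a$state <- b$state
    a
  }

  ok <- mc_check()
  while (!all(ok) &&
         length(chains[[1]]$alpha) * mcmc$n_chains + mcmc$n_chains * mcmc$n_retain
         <= mcmc$max_samples) {
    for (ch in seq_len(mcmc$n_chains)) {
      .Random.seed <<- rng_states[[ch]]
      res <- run_block(ch, chains[[ch]]$state, scale_states[[ch]],
                       0L, mcmc$n_retain)
      rng_states[[ch]] <- .Random.seed
      chains[[ch]] <- append_block(chains[[ch]], res)
    }
    ok <- mc_check()
  }
  failed <- !all(ok)
  if (failed) {
    warning("Monte-Carlo error rule not met within max_samples; fit flagged")
  }

  # uncentered-scale intercept: alpha_nat = alpha_c - xbar . beta, per sample
  for (ch in seq_along(chains)) {
    if (p > 0) {
      chains[[ch]]$alpha <- chains[[ch]]$alpha -
        as.numeric(chains[[ch]]$beta %*% xbar)
      colnames(chains[[ch]]$beta) <- colnames(X)
    }
    colnames(chains[[ch]]$lambda) <- ids
    colnames(chains[[ch]]$eps) <- ids
    colnames(chains[[ch]]$phi) <- ids
  }

  pooled <- list(
    alpha = unlist(lapply(chains, `[[`, "alpha")),
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    eps = do.call(rbind, lapply(chains, `[[`, "eps")),
    phi = do.call(rbind, lapply(chains, `[[`, "phi")),
    tau_eps = unlist(lapply(chains, `[[`, "tau_eps")),
    tau_phi = unlist(lapply(chains, `[[`, "tau_phi")),
    lambda = do.call(rbind, lapply(chains, `[[`, "lambda")),
    deviance = unlist(lapply(chains, `[[`, "deviance")))

  structure(list(chains = chains, pooled = pooled, area_id = ids,
                 covariates = colnames(X), O = O, E = E, spec = spec,
                 mcmc = mcmc, mc_ok = ok, failed = failed,
                 n_retained = length(pooled$alpha)),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("BYM convolution model fit:", length(x$area_id), "units,",
      length(x$chains), "chains,", x$n_retained, "pooled retained samples\n")
  cat("  covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(null model)", "\n")
  cat("  spatial:", x$spec$spatial, " heterogeneity:", x$spec$heterogeneity, "\n")
  cat("  MC-error rule:", if (x$failed) "NOT MET (flagged)" else "met", "\n")
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per monitored scalar (intercept, each
#' coefficient, precisions), computed across chains:
#' `R-hat = sqrt(((N-1)/N * W + B/N) / W)`. The fit is deemed converged
#' when every monitored R-hat is below the threshold (default 1.1).
#'
#' @param fit A `bym_fit` with at least 2 chains.
#' @param threshold Convergence threshold on R-hat.
#' @return List with `rhat` (named vector) and logical `converged`.
#' @export
gelman_rubin <- function(fit, threshold = 1.1) {
  if (length(fit$chains) < 2L) stop("Gelman-Rubin needs >= 2 chains", call. = FALSE)
  mon <- list(alpha = lapply(fit$chains, `[[`, "alpha"))
  for (k in seq_along(fit$covariates)) {
    mon[[fit$covariates[k]]] <- lapply(fit$chains, function(c) c$beta[, k])
  }
  if (fit$spec$heterogeneity) mon$tau_eps <- lapply(fit$chains, `[[`, "tau_eps")
  if (fit$spec$spatial && stats::sd(fit$pooled$tau_phi) > 0) {
    mon$tau_phi <- lapply(fit$chains, `[[`, "tau_phi")
  }
  rhat <- vapply(mon, function(xs) {
    m <- length(xs)
    N <- length(xs[[1]])
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, stats::var, numeric(1))
    W <- mean(vars)
    B <- N * stats::var(means)
    if (W == 0) return(1)
    sqrt(((N - 1) / N * W + B / N) / W)
  }, numeric(1))
  list(rhat = rhat, converged = all(rhat < threshold), threshold = threshold)
}

#' Deviance Information Criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(posterior means)`, the deviance evaluated at the
#' posterior means of the log relative risks (i.e. of all parameters
#' entering the linear predictor).
#'
#' @param fit A `bym_fit` with a stored deviance trace.
#' @return List with `DIC`, `Dbar`, `pD`, `Dhat`.
#' @export
dic <- function(fit) {
  if (is.null(fit$pooled$deviance)) stop("fit has no deviance trace", call. = FALSE)
  Dbar <- mean(fit$pooled$deviance)
  eta_hat <- colMeans(log(fit$pooled$lambda)) + log(fit$E)
  Dhat <- -2 * sum(stats::dpois(fit$O, exp(eta_hat), log = TRUE))
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, Dbar = Dbar, pD = pD, Dhat = Dhat)
}

#' Posterior covariate summaries as relative risks
#'
#' Exponentiated coefficients summarized by the posterior median and the
#' 2.5/97.5 percentile Bayesian credible interval, with the exceedance
#' probability `P(RR > 1)`. Following the stringent Richardson-style
#' criterion, a covariate is flagged significant when `P(beta > 0)` or
#' `P(beta < 0)` exceeds `prob` (default 0.95).
#'
#' @param fit A `bym_fit` with covariates.
#' @param prob Significance exceedance threshold.
#' @return Data frame: one row per covariate with `rr`, `rr_lower`,
#'   `rr_upper`, `p_rr_gt_1`, `significant`.
#' @export
covariate_summaries <- function(fit, prob = 0.95) {
  if (length(fit$covariates) == 0L) {
    return(data.frame(covariate = character(0), rr = numeric(0),
                      rr_lower = numeric(0), rr_upper = numeric(0),
                      p_rr_gt_1 = numeric(0), significant = logical(0)))
  }
  B <- fit$pooled$beta
  q <- t(apply(exp(B), 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
               names = FALSE))
  pgt <- colMeans(B > 0)
  data.frame(covariate = fit$covariates,
             rr = q[, 1], rr_lower = q[, 2], rr_upper = q[, 3],
             p_rr_gt_1 = pgt,
             significant = pgt > prob | (1 - pgt) > prob,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-unit exceedance probabilities
#'
#' Posterior probability that the smoothed standardized ratio (relative
#' risk `lambda_i`) exceeds `threshold_rr` (default 1), computed as the
#' fraction of retained samples above it.
#'
#' @param fit A `bym_fit`.
#' @param threshold_rr Relative-risk reference (default 1).
#' @return Named numeric vector of probabilities in unit order.
#' @export
exceedance_probs <- function(fit, threshold_rr = 1) {
  colMeans(fit$pooled$lambda > threshold_rr)
}

#' Posterior summaries of the smoothed standardized ratios
#'
#' @param fit A `bym_fit`.
#' @return Data frame with per-unit raw SMR `O/E`, posterior median and
#'   mean smoothed ratio, and 95% credible bounds.
#' @export
smoothed_ratios <- function(fit) {
  L <- fit$pooled$lambda
  q <- t(apply(L, 2, stats::quantile, probs = c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(area_id = fit$area_id, raw_smr = fit$O / fit$E,
             smoothed = q[, 1], smoothed_mean = colMeans(L),
             lower = q[, 2], upper = q[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}
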