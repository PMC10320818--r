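#' Grid-search model fitting via kernel-density synthetic likelihood
#'
#' Neither sampler model has a closed-form likelihood, so fitting uses
#' probability density approximation (PDA): for every cell of a parameter
#' grid, responses are simulated from the model, a kernel density estimate is
#' fitted to them, and the synthetic log-likelihood of the observed responses
#' is the sum of log densities. The estimated parameters are those of the
#' grid cell with the highest synthetic likelihood. The Bayesian variant has
#' two free parameters (chain length, beta); the plain relative-frequency
#' variant is its beta = 0 restriction with one free parameter.
#'
#' @name model-fitting
NULL

#' Total variation distance between a symmetric Beta prior and the uniform
#'
#' Computes 0.5 * integral over \[0,1\] of |f(x; beta, beta) - 1| dx. On
#' (0, 0.5) the symmetric Beta density is monotone and crosses 1 exactly once
#' (for beta != 1), so the integral reduces to twice the excess mass beyond
#' the crossing, evaluated with the exact Beta CDF; the crossing is located
#' by root finding to absolute tolerance below 1e-10.
#'
#' @param beta Positive shape parameter.
#' @return Total variation distance in \[0, 1\]; 0 at beta = 1.
#' @export
beta_tvd <- function(beta) {
  stopifnot(length(beta) == 1L)
  if (!is.finite(beta) || beta <= 0)
    stop("beta must be positive (the beta = 0 two-point prior is handled symbolically elsewhere)")
  if (beta == 1) return(0)
  x0 <- stats::uniroot(function(x) stats::dbeta(x, beta, beta) - 1,
                       interval = c(1e-12, 0.5 - 1e-12), tol = 1e-12)$root
  2 * abs(stats::pbeta(x0, beta, beta) - x0)
}

#' Build the 21-value beta grid symmetric about the uniform prior
#'
#' Starts from beta in 0.1, ..., 0.9 and, for each, root-solves for the
#' beta > 1 whose symmetric Beta prior has the same total variation distance
#' from the uniform distribution. The grid is these nine matched values plus
#' 0, the nine sub-unit values, 1, and 100 (the finite stand-in for the
#' infinitely concentrated counterpart of beta = 0, which would force all
#' responses to 50%).
#'
#' @return Sorted numeric vector of 21 beta values.
#' @export
build_beta_grid <- function() {
  sub_unit <- seq(0.1, 0.9, by = 0.1)
  matched <- vapply(sub_unit, function(b0) {
    target <- beta_tvd(b0)
    stats::uniroot(function(b) beta_tvd(b) - target,
                   interval = c(1 + 1e-9, 1e6), tol = 1e-10)$root
  }, numeric(1))
  sort(c(0, sub_unit, 1, matched, 100))
}

#' Parameter grid for the grid search
#'
#' Defaults reproduce the full estimation grid: 35 even chain lengths from 2
#' to 70 crossed with the 21-value beta grid (735 cells).
#'
#' @param chain_lengths Ordered vector of positive integer chain lengths.
#' @param betas Ordered vector of non-negative beta values.
#' @return A list of class `"parameter_grid"`.
#' @export
parameter_grid <- function(chain_lengths = seq(2L, 70L, by = 2L),
                           betas = build_beta_grid()) {
  stopifnot(all(chain_lengths >= 1), all(betas >= 0),
            !is.unsorted(chain_lengths), !is.unsorted(betas))
  structure(list(chain_lengths = as.integer(chain_lengths), betas = betas),
            class = "parameter_grid")
}

#' Coarse grid used for parameter recovery
#'
#' Every other chain length (2, 6, ..., 70) and an 11-value beta subset that
#' keeps the grid symmetric about the uniform prior in total variation
#' distance (0, 0.2, 0.4, 0.6, 0.8, 1 and their matched counterparts plus
#' 100).
#'
#' @return A [parameter_grid()].
#' @export
coarse_parameter_grid <- function() {
  full <- build_beta_grid()
  keep <- c(0, 0.2, 0.4, 0.6, 0.8, 1, 100)
  matched <- full[full > 1 & full < 100]
  # counterparts of 0.2..0.8 are the 2nd, 4th, 6th, 8th largest matched values
  parameter_grid(chain_lengths = seq(2L, 70L, by = 4L),
                 betas = sort(c(keep, rev(matched)[c(2, 4, 6, 8)])))
}

#' Kernel density settings for the synthetic likelihood
#'
#' @param bandwidth Fixed bandwidth in percent points, or `NULL` for
#'   Silverman's rule of thumb ([stats::bw.nrd0()]).
#' @param fallback_bandwidth Bandwidth used when the rule of thumb is
#'   degenerate (near-constant simulated responses).
#' @param floor Density floor preventing -Inf log-likelihood contributions.
#' @return A list of class `"kde_options"`.
#' @export
kde_options <- function(bandwidth = NULL, fallback_bandwidth = 2, floor = 1e-10) {
  stopifnot(is.null(bandwidth) || bandwidth > 0, fallback_bandwidth > 0, floor > 0)
  structure(list(bandwidth = bandwidth, fallback_bandwidth = fallback_bandwidth,
                 floor = floor),
            class = "kde_options")
}

kde_bandwidth <- function(simulated, kde) {
  if (!is.null(kde$bandwidth)) return(kde$bandwidth)
  bw <- tryCatch(stats::bw.nrd0(simulated), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- kde$fallback_bandwidth
  bw
}

# Gaussian KDE density of `simulated` evaluated at each point of `at`.
kde_density_at <- function(simulated, at, bw) {
  .colMeans(stats::dnorm(outer(simulated, at, "-"), sd = bw),
            length(simulated), length(at))
}

#' Synthetic log-likelihood of observed responses under simulated ones
#'
#' Fits a Gaussian kernel density estimate to the simulated responses
#' (no boundary reflection at 0/100) and returns the summed log density of
#' the observed responses, each floored to avoid -Inf.
#'
#' @param simulated Numeric vector of model-simulated responses (percent).
#' @param observed Numeric vector of observed responses; empty gives 0.
#' @param kde A [kde_options()].
#' @return Scalar synthetic log-likelihood.
#' @export
pda_log_likelihood <- function(simulated, observed, kde = kde_options()) {
  stopifnot(length(simulated) >= 1)
  if (length(observed) == 0L) return(0)
  bw <- kde_bandwidth(simulated, kde)
  sum(log(pmax(kde_density_at(simulated, observed, bw), kde$floor)))
}

#' Precompute per-grid-cell simulation tallies for fitting
#'
#' Chains depend only on the joint and the chain length, so one batch of
#' `n_sims` chains per chain length serves every beta value and every query.
#' The returned object stores, per chain length and query, the per-chain
#' N_match and N_other tallies from which any cell's simulated responses are
#' reconstructed instantly.
#'
#' @param network A [causal_network()] or length-8 joint vector.
#' @param grid A [parameter_grid()].
#' @param queries Query set as from [enumerate_queries()].
#' @param n_sims Simulated chains per chain length.
#' @param seed Optional integer seed.
#' @return A list of class `"grid_predictions"`.
#' @export
precompute_grid_predictions <- function(network, grid = parameter_grid(),
                                        queries = enumerate_queries(),
                                        n_sims = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  joint <- as_joint(network)
  qs <- lapply(seq_len(nrow(queries)), function(i) as_query(queries[i, ]))
  km <- vapply(qs, function(q) length(matching_states(q)), integer(1))
  ko <- vapply(qs, function(q) length(matching_states(q, 1L - q$target_value)), integer(1))
  nm <- no <- vector("list", length(grid$chain_lengths))
  for (i in seq_along(grid$chain_lengths)) {
    counts <- simulate_chain_counts(joint, grid$chain_lengths[i], n_sims)
    nm[[i]] <- vapply(qs, function(q)
      rowSums(counts[, matching_states(q), drop = FALSE]), numeric(n_sims))
    no[[i]] <- vapply(qs, function(q)
      rowSums(counts[, matching_states(q, 1L - q$target_value), drop = FALSE]),
      numeric(n_sims))
  }
  structure(list(grid = grid, queries = queries, n_sims = n_sims,
                 nm = nm, no = no, k_match = km, k_other = ko),
            class = "grid_predictions")
}

# Simulated responses (percent) for one (chain-length index, query index,
# beta) cell, reconstructed from precomputed tallies.
cell_responses <- function(pred, i_cl, i_q, beta) {
  nm <- pred$nm[[i_cl]][, i_q]
  no <- pred$no[[i_cl]][, i_q]
  if (beta == 0) {
    nm <- nm + .COUNT_FLOOR * pred$k_match[i_q]
    no <- no + .COUNT_FLOOR * pred$k_other[i_q]
    100 * nm / (nm + no)
  } else {
    100 * (nm + beta) / (nm + no + 2 * beta)
  }
}

# Synthetic log-likelihood of each unit (row of `observed`) in each grid
# cell. Cells are ordered chain length-major, beta ascending within, so a
# first-maximum argmax breaks ties toward the smaller chain length, then the
# smaller beta. Returns list(ll = units x cells matrix, cells = data frame).
grid_loglik <- function(observed, pred, betas = pred$grid$betas,
                        kde = kde_options()) {
  if (is.null(dim(observed))) observed <- matrix(observed, nrow = 1L)
  n_q <- nrow(pred$queries)
  stopifnot(ncol(observed) == n_q, all(is.finite(observed)))
  cls <- pred$grid$chain_lengths
  cells <- expand.grid(beta = betas, chain_length = cls)[, 2:1]
  ll <- matrix(0, nrow(observed), nrow(cells))
  cell <- 0L
  for (i in seq_along(cls)) for (b in betas) {
    cell <- cell + 1L
    for (q in seq_len(n_q)) {
      resp <- cell_responses(pred, i, q, b)
      dens <- kde_density_at(resp, observed[, q], kde_bandwidth(resp, kde))
      ll[, cell] <- ll[, cell] + log(pmax(dens, kde$floor))
    }
  }
  list(ll = ll, cells = cells)
}

#' Fit one unit of observed responses by grid search
#'
#' A unit is one participant in one condition: one response per query of the
#' design (27 in the standard query set). The BMS searches the full
#' (chain length, beta) grid; the MS is restricted to the beta = 0 row. Ties
#' in the argmax are broken toward the smaller chain length, then the smaller
#' beta. BIC is k log(n_obs) - 2 logL with k = 2 (BMS) or 1 (MS).
#'
#' @param observed Numeric vector with one response (0--100) per query, in
#'   the row order of the prediction object's query set, or a data frame with
#'   columns `query_id` and `response`.
#' @param network A [causal_network()]; ignored if `predictions` is given.
#' @param grid A [parameter_grid()].
#' @param model `"BMS"` or `"MS"`.
#' @param n_sims Simulated chains per chain length (when precomputing).
#' @param seed Optional integer seed for the precomputation.
#' @param predictions Optional precomputed [precompute_grid_predictions()]
#'   object, reusable across units.
#' @param kde A [kde_options()].
#' @return One-row data frame of class `"bms_fit"`: `model`, `chain_length`,
#'   `beta`, `log_likelihood`, `bic`, `n_obs`.
#' @export
fit_unit <- function(observed, network = NULL, grid = parameter_grid(),
                     model = c("BMS", "MS"), n_sims = 10000, seed = NULL,
                     predictions = NULL, kde = kde_options()) {
  model <- match.arg(model)
  if (is.data.frame(observed) && nrow(observed) == 0L || length(observed) == 0L)
    stop("no observed responses to fit")
  if (is.null(predictions)) {
    if (is.null(network)) stop("supply either 'network' or precomputed 'predictions'")
    predictions <- precompute_grid_predictions(network, grid, n_sims = n_sims,
                                               seed = seed)
  }
  if (is.data.frame(observed)) {
    idx <- match(predictions$queries$query_id, observed$query_id)
    if (anyNA(idx)) stop("observed responses do not cover the full query set")
    observed <- observed$response[idx]
  }
  betas <- if (model == "MS") 0 else predictions$grid$betas
  gl <- grid_loglik(observed, predictions, betas = betas, kde = kde)
  best <- which.max(gl$ll[1L, ])
  n_obs <- length(observed)
  k <- if (model == "MS") 1 else 2
  out <- data.frame(model = model,
                    chain_length = gl$cells$chain_length[best],
                    beta = gl$cells$beta[best],
                    log_likelihood = gl$ll[1L, best],
                    bic = k * log(n_obs) - 2 * gl$ll[1L, best],
                    n_obs = n_obs, stringsAsFactors = FALSE)
  class(out) <- c("bms_fit", class(out))
  out
}

#' BIC weights across a set of candidate models
#'
#' w_i = exp(-(BIC_i - min BIC)/2), normalized to sum to 1; an approximation
#' to posterior model probabilities.
#'
#' @param bics Numeric vector of BIC values (length >= 2).
#' @return Numeric vector of weights summing to 1.
#' @export
bic_weights <- function(bics) {
  stopifnot(length(bics) >= 2)
  w <- exp(-(bics - min(bics)) / 2)
  w / sum(w)
}

#' Fit both sampler models to every participant x condition unit
#'
#' Expects the trial-level response table schema (see
#' [validate_responses()]). For each causal structure the grid simulations
#' are precomputed once and shared across participants, deadlines and both
#' models; the relative-frequency model's likelihood row (beta = 0) is part
#' of the Bayesian model's grid, so both fits come from a single likelihood
#' evaluation.
#'
#' @param responses Trial-level data frame (participant_id, structure,
#'   deadline, conditioning columns, queried_var, queried_value, response).
#' @param networks Named list of [causal_network()] per structure.
#' @param grid A [parameter_grid()].
#' @param n_sims Simulated chains per chain length per structure.
#' @param seed Optional integer seed.
#' @param kde A [kde_options()].
#' @return Data frame with one row per participant x structure x deadline x
#'   model: estimated `chain_length`, `beta`, `log_likelihood`, `bic`,
#'   `n_obs`.
#' @export
fit_experiment <- function(responses, networks = default_networks(),
                           grid = parameter_grid(), n_sims = 10000,
                           seed = NULL, kde = kde_options()) {
  responses <- validate_responses(responses)
  if (!is.null(seed)) set.seed(seed)
  queries <- enumerate_queries()
  out <- list()
  for (structure in unique(responses$structure)) {
    if (is.null(networks[[structure]]))
      stop("no network supplied for structure '", structure, "'")
    pred <- precompute_grid_predictions(networks[[structure]], grid,
                                        queries = queries, n_sims = n_sims)
    sub <- responses[responses$structure == structure, ]
    sub$unit <- interaction(sub$participant_id, sub$deadline, drop = TRUE)
    units <- split(sub, sub$unit)
    obs <- t(vapply(units, function(u) {
      idx <- match(queries$query_id, u$query_id)
      if (anyNA(idx)) stop("a unit does not cover the full 27-query set")
      u$response[idx]
    }, numeric(nrow(queries))))
    gl <- grid_loglik(obs, pred, kde = kde)
    ms_cols <- which(gl$cells$beta == 0)
    for (u in seq_along(units)) {
      info <- units[[u]][1L, c("participant_id", "structure", "deadline")]
      for (model in c("BMS", "MS")) {
        cols <- if (model == "MS") ms_cols else seq_len(nrow(gl$cells))
        best <- cols[which.max(gl$ll[u, cols])]
        k <- if (model == "MS") 1 else 2
        out[[length(out) + 1L]] <- cbind(info, data.frame(
          model = model,
          chain_length = gl$cells$chain_length[best],
          beta = gl$cells$beta[best],
          log_likelihood = gl$ll[u, best],
          bic = k * log(ncol(obs)) - 2 * gl$ll[u, best],
          n_obs = ncol(obs), stringsAsFactors = FALSE))
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare the two sampler models from a table of fits
#'
#' @param fits Output of [fit_experiment()].
#' @return List with `units` (per-unit delta BIC, Bayesian minus plain, and
#'   BIC weights) and `participants` (per-participant arithmetic mean of the
#'   unit-level BIC weight pairs, summing to 1 within participant).
#' @export
compare_models <- function(fits) {
  key <- interaction(fits$participant_id, fits$structure, fits$deadline, drop = TRUE)
  units <- lapply(split(fits, key), function(f) {
    bms <- f[f$model == "BMS", ]; ms <- f[f$model == "MS", ]
    stopifnot(nrow(bms) == 1L, nrow(ms) == 1L)
    w <- bic_weights(c(bms$bic, ms$bic))
    data.frame(participant_id = bms$participant_id, structure = bms$structure,
               deadline = bms$deadline, delta_bic = bms$bic - ms$bic,
               weight_bms = w[1], weight_ms = w[2], stringsAsFactors = FALSE)
  })
  units <- do.call(rbind, units)
  rownames(units) <- NULL
  parts <- lapply(split(units, units$participant_id), function(u)
    data.frame(participant_id = u$participant_id[1],
               mean_weight_bms = mean(u$weight_bms),
               mean_weight_ms = mean(u$weight_ms),
               n_units = nrow(u), stringsAsFactors = FALSE))
  parts <- do.call(rbind, parts)
  rownames(parts) <- NULL
  list(units = units, participants = parts)
}

#' Parameter recovery study
#'
#' Generates synthetic Bayesian-sampler participants with true parameters
#' drawn uniformly from the cells of the fitting grid, 27 responses each (one
#' per query of the design, under one causal structure), refits each by the
#' grid search, and correlates true with estimated parameters.
#'
#' @param n_participants Number of synthetic participants.
#' @param grid A [parameter_grid()] used both to draw true parameters and to
#'   refit.
#' @param network Causal structure used for generation and fitting.
#' @param n_sims Simulated chains per grid cell for the synthetic likelihood.
#' @param seed Optional integer seed.
#' @param kde A [kde_options()].
#' @return List of class `"recovery_study"` with `results` (true and
#'   estimated parameters per participant) and `correlations` (Pearson, named
#'   `chain_length` and `beta`).
#' @export
recover_parameters <- function(n_participants = 40, grid = coarse_parameter_grid(),
                               network = causal_network("common_cause"),
                               n_sims = 2000, seed = NULL, kde = kde_options()) {
  stopifnot(n_participants >= 2)
  if (!is.null(seed)) set.seed(seed)
  queries <- enumerate_queries()
  qs <- lapply(seq_len(nrow(queries)), function(i) as_query(queries[i, ]))
  true_cl <- sample(grid$chain_lengths, n_participants, replace = TRUE)
  true_beta <- sample(grid$betas, n_participants, replace = TRUE)
  obs <- matrix(NA_real_, n_participants, length(qs))
  for (p in seq_len(n_participants)) {
    counts <- simulate_chain_counts(network, true_cl[p], length(qs))
    obs[p, ] <- vapply(seq_along(qs), function(i)
      100 * bms_estimate(counts[i, ], qs[[i]], true_beta[p]), numeric(1))
  }
  pred <- precompute_grid_predictions(network, grid, queries = queries,
                                      n_sims = n_sims)
  gl <- grid_loglik(obs, pred, kde = kde)
  best <- apply(gl$ll, 1L, which.max)
  results <- data.frame(participant = seq_len(n_participants),
                        true_chain_length = true_cl, true_beta = true_beta,
                        est_chain_length = gl$cells$chain_length[best],
                        est_beta = gl$cells$beta[best])
  correlations <- c(
    chain_length = stats::cor(results$true_chain_length, results$est_chain_length),
    beta = stats::cor(results$true_beta, results$est_beta))
  structure(list(results = results, correlations = correlations),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d synthetic participants\n",
              nrow(x$results)))
  cat(sprintf("  r(chain length) = %.3f\n  r(beta)         = %.3f\n",
              x$correlations[["chain_length"]], x$correlations[["beta"]]))
  invisible(x)
}
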