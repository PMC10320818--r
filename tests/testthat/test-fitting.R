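test_that("total variation distance from uniform matches closed forms", {
  expect_equal(beta_tvd(1), 0)
  # arcsine law: Beta(1/2, 1/2) CDF is (2/pi) asin(sqrt(x))
  x0 <- (1 - sqrt(1 - 4 / pi^2)) / 2
  expect_equal(beta_tvd(0.5), 2 * ((2 / pi) * asin(sqrt(x0)) - x0),
               tolerance = 1e-6)
  # Beta(2, 2) density 6x(1-x) crosses 1 at (1 - 1/sqrt(3))/2
  x1 <- (1 - 1 / sqrt(3)) / 2
  expect_equal(beta_tvd(2), 2 * abs(x1^2 * (3 - 2 * x1) - x1), tolerance = 1e-6)
  expect_error(beta_tvd(0), "positive")
})

test_that("distance grows as the prior departs the uniform in either direction", {
  below <- sapply(seq(0.9, 0.1, by = -0.2), beta_tvd)
  above <- sapply(c(1.5, 3, 10, 50), beta_tvd)
  expect_true(all(diff(below) > 0))
  expect_true(all(diff(above) > 0))
})

test_that("the matched beta grid reproduces the printed estimation grid", {
  grid <- build_beta_grid()
  expect_length(grid, 21)
  expect_equal(round(grid, 2),
               c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1,
                 1.11, 1.26, 1.45, 1.73, 2.14, 2.83, 4.14, 7.35, 21.54, 100))
  full <- parameter_grid()
  expect_equal(length(full$chain_lengths) * length(full$betas), 35 * 21)
  # matched pairs really are equidistant from the uniform prior
  expect_equal(beta_tvd(grid[grid > 2.1 & grid < 2.2]), beta_tvd(0.5),
               tolerance = 1e-6)
})

test_that("synthetic likelihood behaves like a density", {
  expect_equal(pda_log_likelihood(rep(50, 100), numeric(0)), 0)
  sims <- rnorm(500, 50, 1)
  expect_gt(pda_log_likelihood(sims, 50), pda_log_likelihood(sims, 100))
  far <- pda_log_likelihood(sims, 100, kde_options(floor = 1e-10))
  expect_true(is.finite(far))
  expect_gte(far, log(1e-10))
  # degenerate simulations fall back to the fixed bandwidth
  expect_true(is.finite(pda_log_likelihood(rep(50, 100), 49)))
})

test_that("BIC weights normalize and rank as expected", {
  expect_equal(bic_weights(c(10, 10)), c(0.5, 0.5))
  expect_equal(bic_weights(c(0, 2)), c(0.731, 0.269), tolerance = 1e-3)
  w <- bic_weights(c(3, 1, 7))
  expect_equal(sum(w), 1)
  expect_equal(order(w), order(-c(3, 1, 7)))
})

test_that("grid search recovers the generating cell and nests the plain model", {
  cc <- default_cc()
  grid <- parameter_grid(chain_lengths = c(4L, 12L, 40L), betas = c(0, 1, 21.54))
  pred <- precompute_grid_predictions(cc, grid, n_sims = 1500, seed = 301)
  queries <- enumerate_queries()
  qs <- lapply(seq_len(nrow(queries)), function(i) as_query(queries[i, ]))
  set.seed(302)
  counts <- simulate_chain_counts(cc, 12, length(qs))
  observed <- vapply(seq_along(qs), function(i)
    100 * bms_estimate(counts[i, ], qs[[i]], 1), numeric(1))
  fit <- fit_unit(observed, predictions = pred, model = "BMS")
  expect_equal(fit$chain_length, 12L)
  expect_equal(fit$beta, 1)
  expect_equal(fit$bic, 2 * log(27) - 2 * fit$log_likelihood)
  # the reported optimum really is the argmax over all evaluated cells,
  # re-evaluated one cell at a time on the same simulation tallies
  cell_pred <- function(i_cl, b) {
    p <- pred
    p$grid <- parameter_grid(grid$chain_lengths[i_cl], b)
    p$nm <- pred$nm[i_cl]
    p$no <- pred$no[i_cl]
    p
  }
  lls <- sapply(seq_along(grid$chain_lengths), function(i)
    sapply(grid$betas, function(b)
      fit_unit(observed, predictions = cell_pred(i, b))$log_likelihood))
  expect_equal(fit$log_likelihood, max(lls))
  # nesting: the one-parameter model equals the beta = 0 restriction
  ms <- fit_unit(observed, predictions = pred, model = "MS")
  expect_equal(ms$beta, 0)
  restricted <- sapply(seq_along(grid$chain_lengths), function(i)
    fit_unit(observed, predictions = cell_pred(i, 0))$log_likelihood)
  expect_equal(ms$log_likelihood, max(restricted))
  expect_equal(ms$bic, log(27) - 2 * ms$log_likelihood)
})

test_that("fit_unit rejects unusable inputs", {
  expect_error(fit_unit(numeric(0), default_cc()), "either|no observed")
  expect_error(fit_unit(runif(27, 0, 100)), "supply either")
})

test_that("recovery correlations tighten when long chains are excluded", {
  coarse <- coarse_parameter_grid()
  short <- parameter_grid(
    chain_lengths = coarse$chain_lengths[coarse$chain_lengths <= 40],
    betas = coarse$betas)
  rec_full <- recover_parameters(n_participants = 30, grid = coarse,
                                 n_sims = 1000, seed = 71)
  rec_short <- recover_parameters(n_participants = 30, grid = short,
                                  n_sims = 1000, seed = 71)
  expect_gte(rec_short$correlations[["chain_length"]],
             rec_full$correlations[["chain_length"]])
})
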