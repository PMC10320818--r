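#' From sampled states to probability judgments
#'
#' A chain's state tallies are turned into a judgment for a query by
#' comparing N_match, the visits to states consistent with the conditioning
#' in which the target has the queried value, against N_other, the visits to
#' states consistent with the conditioning in which it has the opposite
#' value. Unknown non-queried variables are marginalized over: both their
#' values contribute to the tallies. The relative-frequency rule (Mutation
#' Sampler) returns N_match / (N_match + N_other), with every state's tally
#' initialized at 1e-10 so that unvisited state sets yield the default
#' responses 0, 0.5 or 1 rather than 0/0. The Bayesian rule adds beta
#' pseudo-observations from a symmetric Beta(beta, beta) prior to each
#' outcome and responds with the posterior mean
#' (N_match + beta) / (N_match + N_other + 2 beta); beta = 0 recovers the
#' relative-frequency rule exactly.
#'
#' @name judgment
NULL

.COUNT_FLOOR <- 1e-10  # per-state visit initialization

# N_match / N_other for one query, from a counts vector or an n x 8 matrix.
query_tallies <- function(counts, q) {
  m <- matching_states(q)
  o <- matching_states(q, value = 1L - q$target_value)
  if (is.matrix(counts)) {
    list(n_match = rowSums(counts[, m, drop = FALSE]),
         n_other = rowSums(counts[, o, drop = FALSE]),
         k_match = length(m), k_other = length(o))
  } else {
    stopifnot(length(counts) == 8L)
    list(n_match = sum(counts[m]), n_other = sum(counts[o]),
         k_match = length(m), k_other = length(o))
  }
}

#' Relative-frequency (Mutation Sampler) probability estimate
#'
#' @param counts State tallies: a length-8 vector from [state_counts()] or an
#'   n x 8 matrix from [simulate_chain_counts()] (one estimate per row).
#' @param q A [query()].
#' @return Probability estimate(s) in \[0, 1\].
#' @export
ms_estimate <- function(counts, q) {
  t <- query_tallies(counts, q)
  nm <- t$n_match + .COUNT_FLOOR * t$k_match
  no <- t$n_other + .COUNT_FLOOR * t$k_other
  nm / (nm + no)
}

#' Beta pseudo-count (Bayesian Mutation Sampler) probability estimate
#'
#' @inheritParams ms_estimate
#' @param beta Non-negative shape parameter of the symmetric Beta prior;
#'   `beta = 0` reduces to [ms_estimate()].
#' @return Probability estimate(s) in \[0, 1\].
#' @export
bms_estimate <- function(counts, q, beta) {
  stopifnot(length(beta) == 1L, beta >= 0)
  if (beta == 0) return(ms_estimate(counts, q))
  t <- query_tallies(counts, q)
  (t$n_match + beta) / (t$n_match + t$n_other + 2 * beta)
}

#' Linearly scaled response mapping
#'
#' Maps an internal probability to a response as `s * p`. The result is not
#' clipped, so scalings above 1 can produce responses outside the response
#' scale; clipping, if wanted, is the caller's decision. Provided for
#' completeness; not part of the default model menu.
#'
#' @param p Probability (or vector).
#' @param s Positive scaling factor.
#' @return `s * p`.
#' @export
scaled_estimate <- function(p, s) {
  stopifnot(s > 0)
  s * p
}

#' Classify responses by state visitation
#'
#' A response is "computed" iff both required state sets were visited;
#' otherwise it is a default: "50" if neither was visited, "100" if only the
#' matching set was, "0" if only the opposing set was. This visitation
#' criterion, not floating-point comparison with 0/50/100, defines default
#' responses throughout.
#'
#' @param n_match,n_other Raw visit tallies (vectors).
#' @return Factor with levels `"computed"`, `"0"`, `"50"`, `"100"`.
#' @export
classify_response <- function(n_match, n_other) {
  kind <- ifelse(n_match > 0 & n_other > 0, "computed",
          ifelse(n_match == 0 & n_other == 0, "50",
          ifelse(n_match > 0, "100", "0")))
  factor(kind, levels = c("computed", "0", "50", "100"))
}

#' Simulate a response distribution for one query
#'
#' Runs `n_sims` independent chains and maps each through the judgment rule,
#' scaled to the 0--100 percent scale. Responses are the model's point
#' judgments (posterior means); they are kept continuous, with no rounding to
#' integer percents.
#'
#' @param network A [causal_network()] or length-8 joint vector.
#' @param q A [query()].
#' @param chain_length Recorded samples per chain.
#' @param beta Symmetric Beta prior parameter; 0 gives the relative-frequency
#'   rule.
#' @param n_sims Number of simulated responses.
#' @param seed Optional integer seed.
#' @return A list of class `"response_distribution"`: `responses` (percent),
#'   `kind` (visitation classification), `n_sims`, and the generating
#'   settings.
#' @export
simulate_responses <- function(network, q, chain_length, beta = 0,
                               n_sims = 10000, seed = NULL) {
  stopifnot(n_sims >= 1)
  counts <- simulate_chain_counts(network, chain_length, n_sims, seed = seed)
  t <- query_tallies(counts, q)
  structure(list(responses = 100 * bms_estimate(counts, q, beta),
                 kind = classify_response(t$n_match, t$n_other),
                 n_sims = n_sims, query_id = query_label(q),
                 chain_length = chain_length, beta = beta),
            class = "response_distribution")
}

#' @export
print.response_distribution <- function(x, ...) {
  cat(sprintf("%d simulated responses for %s (chain length %d, beta %g)\n",
              x$n_sims, x$query_id, x$chain_length, x$beta))
  print(summary(x$responses))
  invisible(x)
}

#' Default/computed response proportions across chain lengths
#'
#' For one query, simulates `n_sims` relative-frequency responses at each
#' chain length and tabulates the proportions of computed responses and of
#' the default responses at 0%, 50% and 100%.
#'
#' @inheritParams simulate_responses
#' @param chain_lengths Integer vector of chain lengths (one table row each).
#' @return Data frame with columns `chain_length`, `computed`, `p0`, `p50`,
#'   `p100`; rows sum to 1.
#' @export
default_response_table <- function(network, q, chain_lengths = c(2, 6, 12, 24, 48),
                                   n_sims = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(chain_lengths, function(cl) {
    sim <- simulate_responses(network, q, cl, beta = 0, n_sims = n_sims)
    pr <- prop.table(table(sim$kind))
    data.frame(chain_length = cl, computed = pr[["computed"]],
               p0 = pr[["0"]], p50 = pr[["50"]], p100 = pr[["100"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a response distribution as a tidy data frame
#'
#' @param x A `"response_distribution"`.
#' @param ... Unused.
#' @return Data frame with `query_id`, `chain_length`, `beta`, `response`,
#'   `kind`, suitable for CSV export.
#' @export
as.data.frame.response_distribution <- function(x, ...) {
  data.frame(query_id = x$query_id, chain_length = x$chain_length,
             beta = x$beta, response = x$responses, kind = x$kind,
             stringsAsFactors = FALSE)
}
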