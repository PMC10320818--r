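#' Distributional analysis of responses
#'
#' Summaries used to compare observed and predicted response distributions:
#' Gini's mean difference as a nonparametric dispersion index, accuracy
#' (negative absolute distance from the normative answer), conservatism
#' (negative absolute distance from 50%), and the symmetry-based collapsing
#' of the 27 inferences into 7 groups for the chain and common-cause
#' structures, whose joints are equivalent.
#'
#' @name response-analysis
NULL

.GROUP_LABELS <- c("Conflict 1", "Conflict 2", "Ambiguous 1", "Ambiguous 2",
                   "Consistent 1", "Consistent 2", "Base rates")

#' Gini's mean difference
#'
#' Mean absolute difference over all unordered pairs of observations
#' (identical to the mean over ordered distinct pairs). Computed via the
#' sorted-values identity in O(n log n).
#'
#' @param values Numeric vector of length >= 2.
#' @return Scalar dispersion value on the scale of the data.
#' @export
gmd <- function(values) {
  n <- length(values)
  if (n < 2) stop("gmd requires at least 2 values")
  v <- sort(values)
  sum((2 * seq_len(n) - n - 1) * v) / choose(n, 2)
}

#' Accuracy of a response
#'
#' Negative absolute distance from the normative answer, so that higher
#' values mean more accurate responding.
#'
#' @param response Response(s) on the 0--100 scale.
#' @param normative Normative probability in percent.
#' @return `-abs(response - normative)`.
#' @export
accuracy <- function(response, normative) {
  -abs(response - normative)
}

#' Conservatism of a response
#'
#' Negative absolute distance from 50%, so that higher values mean more
#' conservative (closer to the scale midpoint) responding.
#'
#' @param response Response(s) on the 0--100 scale.
#' @return `-abs(response - 50)`.
#' @export
conservatism <- function(response) {
  -abs(response - 50)
}

#' Assign a query to its symmetry-collapsed inference group
#'
#' Groups (chain and common-cause structures only, whose joints coincide):
#' with two known conditioning variables, conflicting values give the
#' conflict groups and agreeing values the consistent groups, split by
#' whether a terminal (groups 1/5) or the middle variable (2/6) is queried;
#' with one known variable the ambiguous groups split by whether the known
#' variable is graph-adjacent to the queried one (3) or not (4); with none
#' known the query is a base rate (7). The flip flag marks queries whose
#' exact normative probability is below 50%, whose responses are reflected
#' (100 - response) onto the upper half of the scale when collapsing; queries
#' at exactly 50% are never flipped.
#'
#' @param q A [query()].
#' @param structure `"chain"` or `"common_cause"`; the common-effect
#'   structure is not part of this analysis.
#' @param network Optional [causal_network()] used for the flip rule;
#'   defaults to the default-parameter network of `structure`.
#' @return List with `group` (1--7), `label`, and logical `flip`.
#' @export
assign_group <- function(q, structure = c("chain", "common_cause"),
                         network = NULL) {
  structure <- match.arg(structure)
  stopifnot(inherits(q, "cbn_query"))
  if (is.null(network)) network <- causal_network(structure)
  known <- names(q$cond)[!is.na(q$cond)]
  n_known <- length(known)
  queried_middle <- q$target == "Y"
  group <- if (n_known == 2L) {
    if (length(unique(q$cond[known])) == 2L) {
      if (queried_middle) 2L else 1L
    } else {
      if (queried_middle) 6L else 5L
    }
  } else if (n_known == 1L) {
    # Y is graph-adjacent to both terminals in either structure; X1 and X2
    # are only linked through Y
    adjacent <- queried_middle || known == "Y"
    if (adjacent) 3L else 4L
  } else 7L
  flip <- normative_probability(network, q) < 0.5
  list(group = group, label = .GROUP_LABELS[group], flip = flip)
}

#' Group assignment for a whole query table
#'
#' @param queries Data frame as from [enumerate_queries()].
#' @inheritParams assign_group
#' @return `queries` with added columns `group`, `group_label`, `flip` and
#'   `normative` (percent).
#' @export
assign_groups <- function(queries = enumerate_queries(),
                          structure = c("chain", "common_cause")) {
  structure <- match.arg(structure)
  network <- causal_network(structure)
  info <- lapply(seq_len(nrow(queries)), function(i) {
    q <- as_query(queries[i, ])
    g <- assign_group(q, structure, network)
    data.frame(group = g$group, group_label = g$label, flip = g$flip,
               normative = 100 * normative_probability(network, q))
  })
  cbind(queries, do.call(rbind, info))
}

#' Flip responses of below-midpoint queries onto the upper half-scale
#'
#' @param response Responses on the 0--100 scale.
#' @param flip Logical vector: reflect as `100 - response` where `TRUE`.
#' @return Canonical responses.
#' @export
flip_response <- function(response, flip) {
  flip <- rep_len(flip, length(response))
  response[flip] <- 100 - response[flip]
  response
}

#' Collapse a trial-level response table into inference groups
#'
#' Keeps only chain and common-cause trials, applies the flip rule, and
#' attaches group ids so that variability can be summarized per participant
#' and group (pooled over structures, deadlines and in-group queries).
#'
#' @param responses Trial-level data frame in the response-table schema (see
#'   [validate_responses()]).
#' @return Data frame with `participant_id`, `structure`, `deadline`,
#'   `query_id`, `group`, `group_label` and `canonical_value`.
#' @export
collapse_responses <- function(responses) {
  responses <- validate_responses(responses)
  responses <- responses[responses$structure %in% c("chain", "common_cause"), ]
  if (nrow(responses) == 0L) stop("no chain or common-cause trials to collapse")
  key <- assign_groups(enumerate_queries(), "common_cause")
  idx <- match(responses$query_id, key$query_id)
  data.frame(participant_id = responses$participant_id,
             structure = responses$structure, deadline = responses$deadline,
             query_id = responses$query_id, group = key$group[idx],
             group_label = key$group_label[idx],
             canonical_value = flip_response(responses$response, key$flip[idx]),
             stringsAsFactors = FALSE)
}

#' Variability predicted for an inference group
#'
#' Averages the per-query predicted response distributions of a group (after
#' flipping below-midpoint queries) into one equal-weight mixture, draws
#' `n_draws` responses from it, and returns their Gini mean difference.
#'
#' @param distributions List of numeric response vectors, one per constituent
#'   query x condition cell of the group.
#' @param flip Logical vector, one per distribution.
#' @param n_draws Samples drawn from the pooled mixture.
#' @param seed Optional integer seed.
#' @return Scalar GMD of the pooled predicted distribution.
#' @export
predicted_group_gmd <- function(distributions, flip = logical(length(distributions)),
                                n_draws = 10000, seed = NULL) {
  stopifnot(length(distributions) >= 1, length(flip) == length(distributions))
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(distributions), n_draws, replace = TRUE)
  draws <- vapply(comp, function(i) {
    v <- distributions[[i]]
    v[sample.int(length(v), 1L)]
  }, numeric(1))
  gmd(flip_response(draws, flip[comp]))
}
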