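#' Synthetic experiments
#'
#' Generates complete synthetic data sets in the layout of the judgment
#' experiment: 27 inferences x 3 causal structures x 3 response-deadline
#' blocks (243 trials per participant), populated with responses from
#' simulated Bayesian-sampler participants. Deadlines are design labels with
#' no computational effect by default (fitted priors did not differ between
#' deadlines); a hook allows deadline-dependent chain lengths for robustness
#' studies.
#'
#' @name synthetic-data
NULL

.DEADLINES <- c(3L, 9L, 20L)

#' Enumerate the full trial design
#'
#' @param structures Causal structures included.
#' @param deadlines Response-deadline labels in seconds.
#' @return Data frame of structure x deadline x query cells in stable order
#'   (243 rows for the full design), with the query columns of
#'   [enumerate_queries()].
#' @export
generate_design <- function(structures = c("chain", "common_cause", "common_effect"),
                            deadlines = .DEADLINES) {
  queries <- enumerate_queries()
  cells <- expand.grid(q = seq_len(nrow(queries)), deadline = deadlines,
                       structure = structures, stringsAsFactors = FALSE)
  out <- cbind(structure = cells$structure, deadline = cells$deadline,
               queries[cells$q, ])
  rownames(out) <- NULL
  out
}

#' Simulate one participant's full response table
#'
#' One chain and one Bayesian-sampler judgment per design cell, scaled to
#' percent. Fully reproducible from the seed.
#'
#' @param id Participant identifier.
#' @param chain_length True chain length.
#' @param beta True symmetric Beta prior parameter.
#' @param networks Named list of [causal_network()] per structure.
#' @param seed Optional integer seed.
#' @param deadline_chain_lengths Optional named vector mapping deadline
#'   labels to chain lengths, overriding `chain_length` per block.
#' @param contamination Proportion of trials replaced by uniform random
#'   responses on \[0, 100\] (off by default; for robustness testing only).
#' @return Data frame in the response-table schema (see
#'   [validate_responses()]).
#' @export
generate_participant <- function(id, chain_length, beta,
                                 networks = default_networks(), seed = NULL,
                                 deadline_chain_lengths = NULL,
                                 contamination = 0) {
  stopifnot(chain_length >= 1, beta >= 0,
            contamination >= 0, contamination <= 1)
  if (!is.null(seed)) set.seed(seed)
  design <- generate_design(structures = names(networks))
  queries <- enumerate_queries()
  qs <- lapply(seq_len(nrow(queries)), function(i) as_query(queries[i, ]))
  q_idx <- match(design$query_id, queries$query_id)
  response <- numeric(nrow(design))
  for (structure in names(networks)) {
    for (dl in unique(design$deadline)) {
      block <- which(design$structure == structure & design$deadline == dl)
      cl <- if (!is.null(deadline_chain_lengths))
        deadline_chain_lengths[[as.character(dl)]] else chain_length
      counts <- simulate_chain_counts(networks[[structure]], cl, length(block))
      response[block] <- vapply(seq_along(block), function(i)
        100 * bms_estimate(counts[i, ], qs[[q_idx[block[i]]]], beta), numeric(1))
    }
  }
  if (contamination > 0) {
    hit <- stats::runif(length(response)) < contamination
    response[hit] <- stats::runif(sum(hit), 0, 100)
  }
  state_label <- function(v) ifelse(is.na(v), "unknown", as.character(v))
  data.frame(participant_id = id, structure = design$structure,
             deadline = design$deadline,
             x1_state = state_label(design$x1), y_state = state_label(design$y),
             x2_state = state_label(design$x2), queried_var = design$target,
             queried_value = design$target_value, response = response,
             query_id = design$query_id, stringsAsFactors = FALSE)
}

#' Simulate a multi-participant synthetic experiment
#'
#' @param participants Data frame with columns `id`, `chain_length`, `beta`
#'   (one row per participant), or an integer number of participants whose
#'   true parameters are drawn uniformly from the cells of `grid`.
#' @param grid A [parameter_grid()] from which true parameters are drawn when
#'   `participants` is a count.
#' @param networks Named list of [causal_network()] per structure.
#' @param seed Optional integer seed.
#' @param ... Passed to [generate_participant()].
#' @return List with `responses` (stacked response tables) and
#'   `participants` (true parameters per participant).
#' @export
generate_experiment <- function(participants, grid = parameter_grid(),
                                networks = default_networks(), seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(participants) && length(participants) == 1L) {
    participants <- data.frame(
      id = seq_len(participants),
      chain_length = sample(grid$chain_lengths, participants, replace = TRUE),
      beta = sample(grid$betas, participants, replace = TRUE))
  }
  stopifnot(all(c("id", "chain_length", "beta") %in% names(participants)))
  tables <- lapply(seq_len(nrow(participants)), function(i)
    generate_participant(participants$id[i], participants$chain_length[i],
                         participants$beta[i], networks = networks, ...))
  list(responses = do.call(rbind, tables), participants = participants)
}

#' Validate a trial-level response table
#'
#' Checks the CSV schema shared by the generator and the fitting pipeline:
#' columns `participant_id`, `structure`, `deadline`, `x1_state`, `y_state`,
#' `x2_state` (each "1", "0" or "unknown"), `queried_var`, `queried_value`,
#' `response` in \[0, 100\]; the queried variable must be "unknown" in the
#' trial statement. Malformed rows are reported with their row numbers. A
#' `query_id` column is appended (or checked) for joining against
#' [enumerate_queries()].
#'
#' @param responses Data frame to validate.
#' @return The validated data frame (with `query_id`), invisibly usable
#'   downstream; stops with an informative error otherwise.
#' @export
validate_responses <- function(responses) {
  required <- c("participant_id", "structure", "deadline", "x1_state",
                "y_state", "x2_state", "queried_var", "queried_value", "response")
  missing_cols <- setdiff(required, names(responses))
  if (length(missing_cols))
    stop("response table lacks columns: ", paste(missing_cols, collapse = ", "))
  problems <- character()
  bad <- function(rows, msg) {
    if (any(rows))
      problems <<- c(problems, paste0(msg, " (rows ",
        paste(utils::head(which(rows), 5L), collapse = ", "),
        if (sum(rows) > 5L) ", ..." else "", ")"))
  }
  states <- c("1", "0", "unknown")
  bad(!(responses$structure %in% c("chain", "common_cause", "common_effect")),
      "unknown structure")
  for (col in c("x1_state", "y_state", "x2_state"))
    bad(!(as.character(responses[[col]]) %in% states), paste("invalid", col))
  bad(!(responses$queried_var %in% c("X1", "Y", "X2")), "invalid queried_var")
  bad(!(responses$queried_value %in% 0:1), "invalid queried_value")
  bad(!is.finite(responses$response) | responses$response < 0 |
        responses$response > 100, "response outside [0, 100]")
  qcol <- c(X1 = "x1_state", Y = "y_state", X2 = "x2_state")[responses$queried_var]
  qstate <- as.character(responses[cbind(seq_len(nrow(responses)), match(qcol, names(responses)))])
  bad(!is.na(qcol) & qstate != "unknown",
      "queried variable must be 'unknown' in the trial statement")
  if (length(problems))
    stop("invalid response table:\n  ", paste(problems, collapse = "\n  "))
  num_state <- function(col) {
    v <- as.character(responses[[col]])
    suppressWarnings(ifelse(v == "unknown", NA_integer_, as.integer(v)))
  }
  x1n <- num_state("x1_state"); yn <- num_state("y_state"); x2n <- num_state("x2_state")
  ids <- vapply(seq_len(nrow(responses)), function(i)
    query_label(as_query(list(x1 = x1n[i], y = yn[i], x2 = x2n[i],
                              target = responses$queried_var[i],
                              target_value = as.integer(responses$queried_value[i])))),
    character(1))
  if (!is.null(responses$query_id) && !identical(as.character(responses$query_id), ids))
    stop("query_id column inconsistent with the stated variable assignment")
  responses$query_id <- ids
  responses
}
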