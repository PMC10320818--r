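#' Three-variable causal Bayesian networks
#'
#' The models in this package operate on causal Bayesian networks with three
#' binary variables: two terminal variables `X1` and `X2` and a middle
#' variable `Y`. Three topologies are supported: a chain (X1 -> Y -> X2), a
#' common cause (Y -> X1, Y -> X2) and a common effect (X1 -> Y <- X2) whose
#' converging causes combine through a noisy-OR gate. Network states are
#' ordered triples (X1, Y, X2) of presence indicators, giving 8 states.
#'
#' @name networks
NULL

.VARS <- c("X1", "Y", "X2")
.STRUCTURES <- c("chain", "common_cause", "common_effect")

#' Enumerate the 8 network states
#'
#' States are ordered by their (X1, Y, X2) bit triple read as a binary
#' number, i.e. (0,0,0), (0,0,1), (0,1,0), ..., (1,1,1). This ordering is
#' fixed so that state counts and I/O are stable.
#'
#' @return An 8 x 3 integer matrix with columns `X1`, `Y`, `X2`.
#' @export
network_states <- function() {
  s <- as.matrix(expand.grid(X2 = 0:1, Y = 0:1, X1 = 0:1))[, 3:1]
  dimnames(s) <- list(apply(s, 1, paste, collapse = ""), .VARS)
  storage.mode(s) <- "integer"
  s
}

#' Index of a network state in the canonical ordering
#'
#' @param x1,y,x2 binary indicators (vectors recycle).
#' @return Integer index in 1..8 (1 + 4*X1 + 2*Y + X2).
#' @export
state_index <- function(x1, y, x2) {
  stopifnot(all(c(x1, y, x2) %in% 0:1))
  as.integer(1L + 4L * x1 + 2L * y + x2)
}

#' Causal network parameterization
#'
#' Defaults are the taught parameters used throughout: base rates of .5 for
#' all root variables; effects present with probability .75 when their parent
#' is present and .25 when it is absent; for the common-effect structure the
#' two causes combine by a noisy-OR gate with causal strengths of .5 each and
#' zero leak, so the effect is impossible when no cause is present.
#'
#' @param base_rate Base rate of each root variable.
#' @param p_effect_present Probability of an effect given its parent present
#'   (chain and common-cause links).
#' @param p_effect_absent Probability of an effect given its parent absent.
#' @param strengths Length-2 noisy-OR causal strengths (common effect only).
#' @param leak Noisy-OR leak probability (probability of the effect when no
#'   cause is present).
#' @return A list of class `"causal_parameters"`.
#' @export
causal_parameters <- function(base_rate = 0.5,
                              p_effect_present = 0.75,
                              p_effect_absent = 0.25,
                              strengths = c(0.5, 0.5),
                              leak = 0) {
  p <- c(base_rate, p_effect_present, p_effect_absent, strengths, leak)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all causal parameters must be probabilities in [0, 1]")
  if (length(strengths) != 2L)
    stop("'strengths' must give one noisy-OR strength per cause")
  structure(list(base_rate = base_rate,
                 p_effect_present = p_effect_present,
                 p_effect_absent = p_effect_absent,
                 strengths = strengths,
                 leak = leak),
            class = "causal_parameters")
}

#' Exact joint distribution over the 8 network states
#'
#' Product-form joint for the given topology. For the common effect the
#' middle variable follows a noisy-OR of its causes:
#' P(Y = 1 | causes) = 1 - (1 - leak) * prod over present causes of
#' (1 - strength).
#'
#' @param structure One of `"chain"`, `"common_cause"`, `"common_effect"`.
#' @param params A [causal_parameters()] object.
#' @return Named numeric vector of length 8 (canonical state order) summing
#'   to 1.
#' @export
build_joint <- function(structure = .STRUCTURES, params = causal_parameters()) {
  structure <- match.arg(structure, .STRUCTURES)
  stopifnot(inherits(params, "causal_parameters"))
  s <- network_states()
  link <- function(child, parent)  # P(child | one parent), chain/common-cause
    ifelse(parent == 1,
           ifelse(child == 1, params$p_effect_present, 1 - params$p_effect_present),
           ifelse(child == 1, params$p_effect_absent, 1 - params$p_effect_absent))
  root <- function(v) ifelse(v == 1, params$base_rate, 1 - params$base_rate)
  p <- switch(structure,
    chain = root(s[, "X1"]) * link(s[, "Y"], s[, "X1"]) * link(s[, "X2"], s[, "Y"]),
    common_cause = root(s[, "Y"]) * link(s[, "X1"], s[, "Y"]) * link(s[, "X2"], s[, "Y"]),
    common_effect = {
      p_y1 <- 1 - (1 - params$leak) *
        (1 - params$strengths[1])^s[, "X1"] *
        (1 - params$strengths[2])^s[, "X2"]
      root(s[, "X1"]) * root(s[, "X2"]) * ifelse(s[, "Y"] == 1, p_y1, 1 - p_y1)
    })
  if (any(p < 0 | p > 1)) stop("invalid parameters: state probability outside [0, 1]")
  names(p) <- rownames(s)
  p
}

#' Construct a causal network (structure, parameters and exact joint)
#'
#' @inheritParams build_joint
#' @return A list of class `"causal_network"` with elements `structure`,
#'   `params`, `joint` and `states`.
#' @export
causal_network <- function(structure = .STRUCTURES, params = causal_parameters()) {
  structure <- match.arg(structure, .STRUCTURES)
  structure(list(structure = structure, params = params,
                 joint = build_joint(structure, params),
                 states = network_states()),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat("Causal network:", x$structure, "\n")
  print(round(x$joint, 6))
  invisible(x)
}

# Coerce a causal_network or bare length-8 probability vector to a joint.
as_joint <- function(x) {
  if (inherits(x, "causal_network")) return(x$joint)
  if (is.numeric(x) && length(x) == 8L) {
    if (any(x < 0)) stop("joint probabilities must be non-negative")
    if (abs(sum(x) - 1) > 1e-9) stop("joint probabilities must sum to 1")
    return(x)
  }
  stop("expected a causal_network or a length-8 joint probability vector")
}

#' Marginal probability of a single variable
#'
#' @param network A [causal_network()] or a length-8 joint vector.
#' @param variable One of `"X1"`, `"Y"`, `"X2"`.
#' @param value 0 or 1.
#' @return The marginal probability.
#' @export
marginal <- function(network, variable, value = 1) {
  joint <- as_joint(network)
  variable <- match.arg(variable, .VARS)
  stopifnot(value %in% 0:1)
  sum(joint[network_states()[, variable] == value])
}

#' Conditional probability query
#'
#' A query gives a (possibly empty) conditioning assignment over the three
#' variables and asks for the probability that a target variable, not among
#' the conditioned ones, takes a given value. Variables absent from `given`
#' are unknown and marginalized over.
#'
#' @param target Queried variable, one of `"X1"`, `"Y"`, `"X2"`.
#' @param value Queried value, 0 or 1.
#' @param given Named vector of conditioning values, e.g. `c(Y = 1, X2 = 0)`;
#'   `NULL` for a base-rate query.
#' @return A list of class `"cbn_query"`.
#' @export
query <- function(target, value = 1, given = NULL) {
  target <- match.arg(target, .VARS)
  stopifnot(value %in% 0:1)
  cond <- setNames(rep(NA_integer_, 3L), .VARS)
  if (length(given)) {
    if (is.null(names(given)) || !all(names(given) %in% .VARS))
      stop("'given' must be named with variables among X1, Y, X2")
    if (target %in% names(given)) stop("target variable cannot be conditioned on")
    if (!all(given %in% 0:1)) stop("conditioning values must be 0 or 1")
    cond[names(given)] <- as.integer(given)
  }
  structure(list(cond = cond, target = target, target_value = as.integer(value)),
            class = "cbn_query")
}

#' @export
print.cbn_query <- function(x, ...) {
  cat(query_label(x), "\n")
  invisible(x)
}

#' Human-readable label of a query, e.g. `"P(X1=1|Y=1,X2=0)"`
#'
#' @param q A [query()].
#' @return Character scalar; used as the stable `query_id` in tables.
#' @export
query_label <- function(q) {
  known <- !is.na(q$cond)
  lhs <- paste0(q$target, "=", q$target_value)
  if (!any(known)) return(paste0("P(", lhs, ")"))
  rhs <- paste(paste0(.VARS[known], "=", q$cond[known]), collapse = ",")
  paste0("P(", lhs, "|", rhs, ")")
}

# Row indices of states consistent with the conditioning and with the target
# set to `value`; unknown non-target variables are marginalized over.
matching_states <- function(q, value = q$target_value) {
  s <- network_states()
  keep <- s[, q$target] == value
  for (v in .VARS)
    if (!is.na(q$cond[[v]])) keep <- keep & s[, v] == q$cond[[v]]
  which(keep)
}

#' Exact normative conditional probability of a query
#'
#' Kolmogorov conditional probability computed from the exact joint by
#' summing over the 8 states.
#'
#' @inheritParams marginal
#' @param q A [query()].
#' @return The exact conditional probability.
#' @export
normative_probability <- function(network, q) {
  joint <- as_joint(network)
  stopifnot(inherits(q, "cbn_query"))
  num <- sum(joint[matching_states(q)])
  den <- num + sum(joint[matching_states(q, value = 1L - q$target_value)])
  if (den <= 0) stop("conditioning event has probability zero; conditional undefined")
  num / den
}

#' Enumerate the 27 inferences of the experimental design
#'
#' Every trial assigns each of the three variables one of three roles:
#' present (1), absent (0) or unknown. The queried variable is unknown in the
#' trial statement and is always asked about at value 1 (presence). With two
#' known variables the remaining one is queried (12 inferences); with one
#' known variable each of the two unknowns is queried in its own trial (12);
#' with no known variable each variable contributes one base-rate query (3).
#'
#' @return A data frame with one row per query: `query_id`, conditioning
#'   columns `x1`, `y`, `x2` (0, 1 or `NA` for unknown), `target`,
#'   `target_value`, in a fixed, stable order.
#' @export
enumerate_queries <- function() {
  rows <- list()
  lv <- c(1L, 0L, NA_integer_)
  for (target in .VARS) {
    others <- setdiff(.VARS, target)
    for (a in lv) for (b in lv) {
      g <- setNames(c(a, b), others)
      g <- g[!is.na(g)]
      q <- query(target, 1L, if (length(g)) g else NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query_label(q),
        x1 = q$cond[["X1"]], y = q$cond[["Y"]], x2 = q$cond[["X2"]],
        target = target, target_value = 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild a query object from a row of [enumerate_queries()]
#'
#' @param row One-row data frame (or list) with `x1`, `y`, `x2`, `target`,
#'   `target_value`.
#' @return A [query()].
#' @export
as_query <- function(row) {
  g <- c(X1 = row$x1, Y = row$y, X2 = row$x2)
  g <- g[!is.na(g)]
  query(row$target, row$target_value, if (length(g)) g else NULL)
}

#' Read network specifications from a YAML or JSON config file
#'
#' The file may define a single network or a `networks:` list; each entry has
#' a `structure` and optional parameter fields (`base_rate`,
#' `p_effect_present`, `p_effect_absent`, `strengths`, `leak`) that override
#' the defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A named list of [causal_network()] objects.
#' @export
read_network_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  entries <- if (!is.null(cfg$networks)) cfg$networks else list(cfg)
  nets <- lapply(entries, function(e) {
    if (is.null(e$structure)) stop("network config entry lacks a 'structure' field")
    args <- e[intersect(names(e), names(formals(causal_parameters)))]
    causal_network(e$structure, do.call(causal_parameters, args))
  })
  names(nets) <- vapply(nets, `[[`, "", "structure")
  nets
}

#' Default networks for the three experimental structures
#'
#' @return Named list of [causal_network()] objects (`chain`, `common_cause`,
#'   `common_effect`) with the default taught parameters.
#' @export
default_networks <- function() {
  nets <- lapply(.STRUCTURES, causal_network)
  names(nets) <- .STRUCTURES
  nets
}
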