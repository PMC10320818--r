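#' The mutation sampling process
#'
#' Judgments are modeled as arising from a short Metropolis-Hastings chain
#' over the 8 network states. The chain starts at one of the two prototype
#' states -- all variables present (1,1,1) or all absent (0,0,0) -- with
#' equal probability. At each step one of the three states differing in a
#' single variable is proposed uniformly ("mutation") and accepted with
#' probability min(1, P(proposal)/P(current)); on rejection the current state
#' is recorded again. The chain length counts the start state, so a chain of
#' length n is the start plus n - 1 transitions. No burn-in is applied: the
#' start-state bias and the limited chain length are the model's substance,
#' not a numerical nuisance.
#'
#' @name mutation-sampler
NULL

# neighbor table: .NEIGHBORS[s, v] is the index of state s with variable v
# (1 = X1, 2 = Y, 3 = X2) flipped
.NEIGHBORS <- local({
  s <- as.matrix(expand.grid(X2 = 0:1, Y = 0:1, X1 = 0:1))[, 3:1]
  nb <- matrix(0L, 8, 3)
  for (i in 1:8) for (v in 1:3) {
    st <- s[i, ]; st[v] <- 1L - st[v]
    nb[i, v] <- 1L + 4L * st[1] + 2L * st[2] + st[3]
  }
  nb
})

.PROTOTYPES <- c(1L, 8L)  # (0,0,0) and (1,1,1) in canonical order

#' Draw a prototype starting state
#'
#' @param n Number of draws.
#' @return An n x 3 integer matrix of states, each row (1,1,1) or (0,0,0)
#'   with probability 1/2.
#' @export
prototype_start <- function(n = 1) {
  idx <- sample(.PROTOTYPES, n, replace = TRUE)
  network_states()[idx, , drop = FALSE]
}

#' Propose a single-variable mutation of a state
#'
#' @param state Length-3 binary vector (X1, Y, X2).
#' @return One of the 3 states at Hamming distance 1, chosen uniformly.
#' @export
propose_neighbor <- function(state) {
  stopifnot(length(state) == 3L, all(state %in% 0:1))
  i <- state_index(state[1], state[2], state[3])
  setNames(network_states()[.NEIGHBORS[i, sample.int(3L, 1L)], ], c("X1", "Y", "X2"))
}

#' Metropolis-Hastings acceptance probability
#'
#' @param joint A [causal_network()] or length-8 joint vector.
#' @param current,proposal Length-3 binary state vectors.
#' @return min(1, P(proposal)/P(current)).
#' @export
acceptance_probability <- function(joint, current, proposal) {
  p <- as_joint(joint)
  pc <- p[state_index(current[1], current[2], current[3])]
  pp <- p[state_index(proposal[1], proposal[2], proposal[3])]
  if (pc <= 0) stop("current state has probability zero")
  min(1, pp / pc)
}

#' Run one mutation-sampler chain
#'
#' @inheritParams acceptance_probability
#' @param chain_length Number of recorded samples (start state included).
#' @param seed Optional integer seed.
#' @return An integer matrix of class `"state_chain"` with `chain_length`
#'   rows and columns `X1`, `Y`, `X2`.
#' @export
run_chain <- function(joint, chain_length, seed = NULL) {
  stopifnot(chain_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- as_joint(joint)
  cur <- sample(.PROTOTYPES, 1L)
  idx <- integer(chain_length)
  idx[1L] <- cur
  if (chain_length > 1L) for (t in 2:chain_length) {
    prop <- .NEIGHBORS[cur, sample.int(3L, 1L)]
    if (stats::runif(1) < p[prop] / p[cur]) cur <- prop
    idx[t] <- cur
  }
  structure(network_states()[idx, , drop = FALSE], class = "state_chain")
}

#' Tally state visits of a chain
#'
#' @param chain A `"state_chain"` (matrix of states) as from [run_chain()].
#' @return Named integer vector of length 8 (canonical state order) whose
#'   tallies sum to the chain length.
#' @export
state_counts <- function(chain) {
  stopifnot(nrow(chain) >= 1L)
  idx <- state_index(chain[, 1], chain[, 2], chain[, 3])
  counts <- tabulate(idx, nbins = 8L)
  names(counts) <- rownames(network_states())
  counts
}

#' Simulate many chains at once and return per-chain state counts
#'
#' Vectorized across chains: all chains advance one MH step per iteration.
#' Statistically identical to `n_chains` independent calls to [run_chain()].
#'
#' @inheritParams run_chain
#' @param n_chains Number of independent chains.
#' @return An `n_chains` x 8 integer matrix of state tallies; each row sums
#'   to `chain_length`.
#' @export
simulate_chain_counts <- function(joint, chain_length, n_chains, seed = NULL) {
  stopifnot(chain_length >= 1, n_chains >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- as_joint(joint)
  cur <- sample(.PROTOTYPES, n_chains, replace = TRUE)
  counts <- matrix(0L, n_chains, 8L, dimnames = list(NULL, rownames(network_states())))
  rows <- seq_len(n_chains)
  counts[cbind(rows, cur)] <- 1L
  if (chain_length > 1L) for (t in 2:chain_length) {
    prop <- .NEIGHBORS[cbind(cur, sample.int(3L, n_chains, replace = TRUE))]
    accept <- stats::runif(n_chains) < p[prop] / p[cur]
    cur[accept] <- prop[accept]
    ij <- cbind(rows, cur)
    counts[ij] <- counts[ij] + 1L
  }
  counts
}
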