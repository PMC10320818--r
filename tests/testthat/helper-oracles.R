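# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force / closed form, without calling the package's own
# implementation paths.

# Brute-force product-form joint over the 8 states, hand-coded per topology.
oracle_joint <- function(structure, br = 0.5, pp = 0.75, pa = 0.25,
                         s1 = 0.5, s2 = 0.5, leak = 0) {
  p <- numeric(8)
  i <- 0
  for (x1 in 0:1) for (y in 0:1) for (x2 in 0:1) {
    idx <- 1 + 4 * x1 + 2 * y + x2
    link <- function(child, parent) {
      pr <- if (parent == 1) pp else pa
      if (child == 1) pr else 1 - pr
    }
    bern <- function(v, pr) if (v == 1) pr else 1 - pr
    p[idx] <- switch(structure,
      chain = bern(x1, br) * link(y, x1) * link(x2, y),
      common_cause = bern(y, br) * link(x1, y) * link(x2, y),
      common_effect = {
        py1 <- 1 - (1 - leak) * (1 - s1)^x1 * (1 - s2)^x2
        bern(x1, br) * bern(x2, br) * bern(y, py1)
      })
  }
  p
}

# Brute-force conditional probability from a length-8 joint: loops over all
# states, no shared code with the package's matching-state machinery.
oracle_conditional <- function(joint, target, value, given) {
  num <- den <- 0
  vars <- c("X1", "Y", "X2")
  for (x1 in 0:1) for (y in 0:1) for (x2 in 0:1) {
    st <- c(X1 = x1, Y = y, X2 = x2)
    if (length(given) && !all(st[names(given)] == given)) next
    pr <- joint[1 + 4 * x1 + 2 * y + x2]
    den <- den + pr
    if (st[[target]] == value) num <- num + pr
  }
  unname(num / den)
}

# Exact enumeration of a chain-length-2 run: start (two prototypes, 1/2
# each), one uniform single-variable proposal, Metropolis accept/reject.
# Returns the probability of each possible visited-state set outcome for the
# two states `a` and `b` (indices in 1..8).
oracle_two_step <- function(joint, a, b) {
  flip <- function(idx, v) {
    bits <- c((idx - 1) %/% 4, ((idx - 1) %/% 2) %% 2, (idx - 1) %% 2)
    bits[v] <- 1 - bits[v]
    1 + 4 * bits[1] + 2 * bits[2] + bits[3]
  }
  out <- c(neither = 0, only_a = 0, only_b = 0, both = 0)
  for (start in c(1, 8)) for (v in 1:3) {
    prop <- flip(start, v)
    acc <- min(1, joint[prop] / joint[start])
    for (accepted in c(TRUE, FALSE)) {
      pr <- 0.5 * (1 / 3) * if (accepted) acc else 1 - acc
      visited <- unique(c(start, if (accepted) prop else start))
      key <- if (a %in% visited && b %in% visited) "both"
        else if (a %in% visited) "only_a"
        else if (b %in% visited) "only_b" else "neither"
      out[key] <- out[key] + pr
    }
  }
  out
}

# Exact E|V - V'| for a discrete mixture with point masses `values` and
# probabilities `probs`.
oracle_pairwise_gmd <- function(values, probs) {
  sum(outer(probs, probs) * abs(outer(values, values, "-")))
}

default_cc <- function() causal_network("common_cause")
conflict_query <- function() query("X1", 1, c(Y = 1, X2 = 0))
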