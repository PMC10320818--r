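cc <- default_cc()
qc <- conflict_query()

# counts vector with given tallies in the two states relevant to qc
counts_for <- function(n_match, n_other) {
  counts <- setNames(integer(8), rownames(network_states()))
  counts[["110"]] <- n_match
  counts[["010"]] <- n_other
  counts
}

test_that("relative-frequency estimates reproduce the default-response algebra", {
  expect_equal(ms_estimate(counts_for(0, 0), qc), 0.5)        # neither visited
  expect_equal(ms_estimate(counts_for(2, 0), qc), 1, tolerance = 1e-9)
  expect_equal(ms_estimate(counts_for(0, 2), qc), 0, tolerance = 1e-9)
  expect_equal(ms_estimate(counts_for(3, 1), qc), 0.75, tolerance = 1e-9)
})

test_that("pseudo-count estimates shrink toward 0.5 and nest the plain rule", {
  expect_equal(bms_estimate(counts_for(0, 0), qc, beta = 1), 0.5)
  expect_equal(bms_estimate(counts_for(3, 1), qc, beta = 1), 4 / 6)
  set.seed(31)
  for (rep in 1:50) {
    counts <- setNames(as.integer(rmultinom(1, 12, rep(1 / 8, 8))),
                       rownames(network_states()))
    expect_equal(bms_estimate(counts, qc, beta = 0), ms_estimate(counts, qc))
    p1 <- bms_estimate(counts, qc, beta = 1)
    p4 <- bms_estimate(counts, qc, beta = 4)
    expect_lte(abs(p4 - 0.5), abs(p1 - 0.5))  # monotone toward 0.5 in beta
  }
})

test_that("unknown non-queried variables are marginalized in the tallies", {
  counts <- setNames(integer(8), rownames(network_states()))
  counts[c("110", "111")] <- c(2L, 4L)  # X1=1,Y=1 with either X2
  counts[c("010", "011")] <- c(1L, 1L)
  expect_equal(ms_estimate(counts, query("X1", 1, c(Y = 1))), 6 / 8,
               tolerance = 1e-9)
})

test_that("scaled responses are linear and unclipped", {
  expect_equal(scaled_estimate(0.5, 1), 0.5)
  expect_equal(scaled_estimate(0.9, 1.2), 1.08)
  expect_equal(scaled_estimate(0, 5), 0)
})

test_that("simulated response distributions reproduce the default-response mix", {
  sim12 <- simulate_responses(cc, qc, chain_length = 12, n_sims = 10000, seed = 8)
  expect_lt(abs(mean(sim12$kind == "computed") - 0.182), 0.015)
  sim48 <- simulate_responses(cc, qc, chain_length = 48, n_sims = 10000, seed = 9)
  expect_lt(abs(mean(sim48$kind == "100") - 0.218), 0.015)
  # classification agrees with the responses themselves under beta = 0
  expect_true(all(sim12$responses[sim12$kind == "50"] == 50))
  expect_true(all(abs(sim12$responses[sim12$kind == "100"] - 100) < 1e-6))
  expect_true(all(abs(sim12$responses[sim12$kind == "0"]) < 1e-6))
  computed <- sim12$responses[sim12$kind == "computed"]
  expect_true(all(computed > 1e-6 & computed < 100 - 1e-6))
})

test_that("positive priors forbid extreme responses; huge priors pin 50", {
  for (beta in c(0.1, 1, 4.14)) {
    sim <- simulate_responses(cc, qc, chain_length = 12, beta = beta,
                              n_sims = 2000, seed = 17)
    expect_true(all(sim$responses > 0 & sim$responses < 100))
  }
  sim <- simulate_responses(cc, qc, chain_length = 12, beta = 100,
                            n_sims = 500, seed = 18)
  expect_true(all(abs(sim$responses - 50) < 5))
})

test_that("mean simulated response approaches the normative answer for long chains", {
  for (q in list(qc, query("Y", 1, c(X1 = 1, X2 = 1)))) {
    sim <- simulate_responses(cc, q, chain_length = 1e4, n_sims = 500, seed = 21)
    expect_lt(abs(mean(sim$responses) - 100 * normative_probability(cc, q)), 1)
  }
})

test_that("default-response tables partition the outcomes", {
  tab <- default_response_table(cc, qc, chain_lengths = c(2, 12),
                                n_sims = 2000, seed = 5)
  expect_equal(tab$computed + tab$p0 + tab$p50 + tab$p100, c(1, 1),
               tolerance = 1e-12)
  expect_equal(tab$computed[tab$chain_length == 2], 0)  # never computable in 2
})
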