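test_that("Gini mean difference matches pairwise definitions and scales linearly", {
  expect_equal(gmd(c(7, 7, 7)), 0)
  expect_equal(gmd(c(0, 100)), 100)
  expect_equal(gmd(c(0, 50, 100)), 200 / 3)
  expect_error(gmd(5), "at least 2")
  set.seed(13)
  for (rep in 1:10) {
    v <- runif(25, 0, 100)
    pairwise <- mean(as.numeric(dist(v, method = "manhattan")))
    expect_equal(gmd(v), pairwise, tolerance = 1e-12)
    expect_equal(gmd(3 * v + 11), 3 * gmd(v), tolerance = 1e-9)
  }
})

test_that("accuracy and conservatism are signed distances", {
  expect_equal(accuracy(75, 75), 0)
  expect_equal(accuracy(50, 75), -25)
  expect_equal(accuracy(100, 0), -100)
  expect_equal(conservatism(50), 0)
  expect_equal(conservatism(0), -50)
  expect_equal(conservatism(100), -50)
})

test_that("inference groups partition the design with the canonical counts", {
  for (structure in c("chain", "common_cause")) {
    g <- assign_groups(enumerate_queries(), structure)
    expect_equal(as.integer(table(factor(g$group, levels = 1:7))),
                 c(4, 2, 8, 4, 4, 2, 3))  # x 2 structures x 3 deadlines
    # canonical normative value per group after the flip rule
    canonical <- flip_response(g$normative, g$flip)
    expect_equal(as.numeric(tapply(canonical, g$group, unique)),
                 c(75, 50, 75, 62.5, 75, 90, 50))
    # flips occur exactly where the normative value is below the midpoint
    expect_equal(g$flip, g$normative < 50)
  }
  # full design for one participant reproduces the per-group totals
  design <- generate_design(structures = c("chain", "common_cause"))
  key <- assign_groups(enumerate_queries(), "common_cause")
  groups <- key$group[match(design$query_id, key$query_id)]
  expect_equal(as.integer(table(groups)), c(24, 12, 48, 24, 24, 12, 18))
})

test_that("group examples land where the symmetry argument says", {
  g4 <- assign_group(query("X1", 1, c(X2 = 1)), "common_cause")
  expect_equal(g4$group, 4)
  expect_false(g4$flip)
  g6 <- assign_group(query("Y", 1, c(X1 = 0, X2 = 0)), "common_cause")
  expect_equal(g6$group, 6)
  expect_true(g6$flip)  # normative 10% -> canonical 100 - raw
  g3 <- assign_group(query("X1", 1, c(Y = 1)), "chain")
  expect_equal(g3$group, 3)
})

test_that("flipping is an involution on responses", {
  r <- c(0, 12.5, 50, 88, 100)
  expect_equal(flip_response(flip_response(r, TRUE), TRUE), r)
  expect_equal(flip_response(r, FALSE), r)
})

test_that("collapsed response tables carry canonical values", {
  tab <- generate_participant("p1", 12, 1, seed = 55)
  col <- collapse_responses(tab)
  expect_equal(nrow(col), 27 * 2 * 3)  # common-effect trials dropped
  expect_true(all(col$group %in% 1:7))
  raw <- tab$response[match(paste(col$structure, col$deadline, col$query_id),
                            paste(tab$structure, tab$deadline, tab$query_id))]
  flipped <- col$canonical_value != raw
  key <- assign_groups(enumerate_queries(), "common_cause")
  expect_true(all(!flipped | key$flip[match(col$query_id, key$query_id)]))
})

test_that("sampled group variability matches the exact mixture expectation", {
  expect_equal(predicted_group_gmd(list(rep(75, 50), rep(75, 9)), seed = 1), 0)
  two_point <- list(rep(25, 10), rep(75, 10))
  exact <- oracle_pairwise_gmd(c(25, 75), c(0.5, 0.5))
  expect_equal(exact, 25)
  expect_lt(abs(predicted_group_gmd(two_point, n_draws = 20000, seed = 2) - exact),
            0.02 * exact)
  # flips fold a mirrored component onto the canonical half-scale
  mirrored <- list(rep(25, 10), rep(25, 10))
  expect_equal(predicted_group_gmd(mirrored, flip = c(TRUE, FALSE),
                                   n_draws = 20000, seed = 3),
               25, tolerance = 0.5)
  # a three-point mixture against the closed-form pairwise expectation
  mix <- list(rep(60, 5), rep(75, 5), rep(90, 5))
  exact3 <- oracle_pairwise_gmd(c(60, 75, 90), rep(1 / 3, 3))
  expect_lt(abs(predicted_group_gmd(mix, n_draws = 30000, seed = 4) - exact3),
            0.02 * exact3)
})
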