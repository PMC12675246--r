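test_that("judgment matrix validation names the offending cell", {
  expect_s3_class(ahp_matrix(matrix(1, 3, 3)), "judgment_matrix")
  m <- matrix(c(1, 2, 0.4, 1), 2, byrow = TRUE)
  expect_error(ahp_matrix(m), "reciprocity",
               class = "sarcostage_validation_error")
  # zero entries are not valid pairwise comparisons
  expect_error(ahp_matrix(diag(3)), class = "sarcostage_validation_error")
  expect_error(ahp_matrix(matrix(1, 1, 1)), "order",
               class = "sarcostage_validation_error")
  expect_error(ahp_matrix(matrix(c(1, -2, -0.5, 1), 2)),
               class = "sarcostage_validation_error")
  expect_error(ahp_matrix(matrix(c(2, 1, 1, 1), 2)), "diagonal",
               class = "sarcostage_validation_error")
})

test_that("priorities of consistent matrices match closed forms exactly", {
  res <- ahp_priority(matrix(1, 3, 3))
  expect_equal(unname(res$weights), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(res$lambda_max, 3, tolerance = 1e-10)
  expect_equal(res$cr, 0, tolerance = 1e-10)

  m <- matrix(c(1, 2, 4, 1 / 2, 1, 2, 1 / 4, 1 / 2, 1), 3, byrow = TRUE)
  res <- ahp_priority(m)
  expect_equal(unname(res$weights), c(4 / 7, 2 / 7, 1 / 7),
               tolerance = 1e-10)
  expect_equal(res$lambda_max, 3, tolerance = 1e-10)
  expect_equal(res$cr, 0, tolerance = 1e-10)

  # any consistent matrix: weights proportional to the first column ratios
  w <- c(0.5, 0.3, 0.15, 0.05)
  res <- ahp_priority(consistent_matrix(w))
  expect_equal(unname(res$weights), w, tolerance = 1e-10)
  expect_equal(res$lambda_max, 4, tolerance = 1e-10)
})

test_that("power iteration agrees with a full eigen-decomposition oracle", {
  for (n in 3:7) {
    m <- random_reciprocal(n, seed = 100 + n)
    res <- ahp_priority(m)
    e <- eigen(m)
    i <- which.max(Re(e$values))
    v <- Re(e$vectors[, i])
    v <- v / sum(v)
    expect_equal(unname(res$weights), v, tolerance = 1e-8)
    expect_equal(res$lambda_max, Re(e$values[i]), tolerance = 1e-8)
    # reciprocal matrices always have lambda_max >= n
    expect_gte(res$lambda_max, n - 1e-9)
  }
})

test_that("priorities are invariant under simultaneous row/column permutation", {
  m <- random_reciprocal(5, seed = 31)
  p <- c(3, 5, 1, 4, 2)
  res <- ahp_priority(m)
  res_p <- ahp_priority(m[p, p])
  expect_equal(unname(res_p$weights), unname(res$weights[p]),
               tolerance = 1e-9)
  expect_equal(res_p$lambda_max, res$lambda_max, tolerance = 1e-9)
})

test_that("geometric-mean aggregation preserves reciprocity and fixed points", {
  m <- random_reciprocal(4, seed = 7)
  expect_equal(unclass(ahp_aggregate(list(m))), m, ignore_attr = TRUE)
  expect_equal(unclass(ahp_aggregate(rep(list(m), 10))), m,
               ignore_attr = TRUE, tolerance = 1e-12)

  # a matrix and its transpose-reciprocal partner average to all-ones
  agg <- ahp_aggregate(list(m, t(m)))
  expect_equal(unclass(agg), matrix(1, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  agg2 <- ahp_aggregate(list(m, random_reciprocal(4, seed = 8)))
  expect_lt(max(abs(agg2 * t(agg2) - 1)), 1e-12)

  expect_error(ahp_aggregate(list(m, random_reciprocal(3, seed = 9))),
               class = "sarcostage_validation_error")
})

test_that("hierarchy composition multiplies locals and normalizes per dimension", {
  # single-child chains collapse to leaf weight 1
  h <- ahp_hierarchy(list(name = "root", children = list(
    list(name = "dim1", local_weight = 0.6, children = list(
      list(name = "mid", local_weight = 1, children = list(
        list(name = "leaf1", local_weight = 1)
      ))
    )),
    list(name = "dim2", local_weight = 0.4, children = list(
      list(name = "leaf2", local_weight = 1)
    ))
  )))
  comp <- compose_hierarchy(h)
  expect_equal(comp$weight, c(1, 1))

  comp <- compose_hierarchy(canonical_hierarchy())
  sums <- tapply(comp$weight, comp$dimension, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(nrow(comp), 14)
  # within-physiological weight of postural transition: self-care local
  # times its child local, close to 0.058/0.70
  pt <- comp$weight[comp$leaf == "postural_transition"]
  expect_lt(abs(pt - 0.0829), 2e-4)

  bad <- list(name = "root", children = list(
    list(name = "d", local_weight = 0.7),
    list(name = "e", local_weight = 0.4)
  ))
  expect_error(ahp_hierarchy(bad), class = "sarcostage_validation_error")
})

test_that("hierarchy nodes can derive child locals from a judgment matrix", {
  h <- ahp_hierarchy(list(name = "root", children = list(
    list(name = "dim", local_weight = 1,
         judgment_matrix = list(c(1, 2, 4), c(1 / 2, 1, 2), c(1 / 4, 1 / 2, 1)),
         children = list(list(name = "a"), list(name = "b"), list(name = "c")))
  )))
  comp <- compose_hierarchy(h)
  expect_equal(comp$weight, c(4 / 7, 2 / 7, 1 / 7), tolerance = 1e-9)
})

test_that("synthetic expert fixtures are consistent at every level", {
  judg <- load_expert_judgments()
  expect_setequal(names(judg),
                  c("dimensions", "physiological", "self_care",
                    "psychological", "external"))
  levels <- aggregate_expert_levels(judg)
  for (lv in levels) {
    expect_lt(lv$cr, 0.1)
    expect_true(all(lv$cr_experts < 0.1))
    expect_equal(sum(lv$weights), 1, tolerance = 1e-9)
  }
  # aggregated self-care priorities stay close to the canonical locals
  loc <- canonical_local_weights()
  sc <- loc$physiological[3:9] / sum(loc$physiological[3:9])
  expect_lt(max(abs(levels$self_care$weights - sc)), 0.05)
})
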