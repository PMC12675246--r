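test_that("item scoring sums the 12 items and assigns the published bands", {
  expect_equal(score_items(rep(0, 12))$total, 0)
  expect_equal(score_items(rep(0, 12))$band, "Healthy")
  expect_equal(score_items(rep(3, 12))$total, 36)
  expect_equal(score_items(rep(3, 12))$band, "DisablingDegeneration")
  expect_equal(score_items(rep(1, 12))$total, 12)
  expect_equal(score_items(rep(1, 12))$band, "PreSarcopeniaCompensation")

  # band cut-offs at 8/9, 16/17, 24/25
  expect_equal(band_of_total(c(8, 9, 16, 17, 24, 25, 36)),
               c("Healthy", "PreSarcopeniaCompensation",
                 "PreSarcopeniaCompensation", "HighRisk", "HighRisk",
                 "DisablingDegeneration", "DisablingDegeneration"))
})

test_that("scoring is permutation-invariant and band assignment monotone", {
  withr::with_seed(5, {
    for (i in 1:20) {
      r <- sample(0:3, 12, replace = TRUE)
      expect_equal(score_items(sample(r))$total, score_items(r)$total)
    }
  })
  sev <- match(band_of_total(0:36), risk_bands())
  expect_true(all(diff(sev) >= 0))
})

test_that("scoring rejects missing and out-of-range responses", {
  expect_error(score_items(c(NA, rep(1, 11))),
               class = "sarcostage_incomplete_error")
  expect_error(score_items(rep(1, 11)), class = "sarcostage_validation_error")
  expect_error(score_items(c(4, rep(1, 11))),
               class = "sarcostage_validation_error")
  expect_error(score_items(c(1.5, rep(1, 11))),
               class = "sarcostage_validation_error")
})

test_that("cronbach alpha: identity, independence, and formula oracle", {
  # duplicated items measure the same thing perfectly
  withr::with_seed(1, x <- rnorm(50))
  expect_equal(cronbach_alpha(cbind(x, x)), 1.0)

  # 12 mutually independent items: alpha near 0
  withr::with_seed(2, ind <- matrix(rnorm(400 * 12), 400))
  expect_lt(abs(cronbach_alpha(ind)), 0.1)

  # fixture matrix against an independent covariance-matrix identity:
  # alpha = k/(k-1) * (1 - tr(C)/sum(C))
  fix <- matrix(c(2, 3, 3, 1,
                  1, 2, 2, 0,
                  3, 3, 2, 2,
                  0, 1, 1, 0,
                  2, 2, 3, 1,
                  1, 1, 2, 1), nrow = 6, byrow = TRUE)
  C <- cov(fix)
  oracle <- ncol(fix) / (ncol(fix) - 1) * (1 - sum(diag(C)) / sum(C))
  expect_equal(cronbach_alpha(fix), oracle, tolerance = 1e-12)
})

test_that("alpha is shift-invariant, at most 1, and degenerate cases error", {
  fix <- one_factor_items(n = 60, k = 4, seed = 9)
  shifted <- fix
  shifted[, 2] <- shifted[, 2] + 100
  expect_equal(cronbach_alpha(shifted), cronbach_alpha(fix),
               tolerance = 1e-10)
  for (s in 1:5) {
    expect_lte(cronbach_alpha(one_factor_items(n = 40, k = 5, seed = s)), 1)
  }
  expect_error(cronbach_alpha(matrix(1, 10, 3)),
               class = "sarcostage_degenerate_error")
  expect_error(cronbach_alpha(matrix(rnorm(10), 10, 1)),
               class = "sarcostage_validation_error")
})

test_that("KMO matches an independent partial-correlation oracle", {
  x <- one_factor_items(n = 200, k = 5, loading = 0.7, seed = 3)
  got <- kmo_measure(x)

  # oracle: partial correlations via residuals of linear regressions on
  # the remaining items, never touching the inverse-matrix route
  k <- ncol(x)
  r <- cor(x)
  q <- matrix(0, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    others <- setdiff(1:k, c(i, j))
    ri <- resid(lm(x[, i] ~ x[, others]))
    rj <- resid(lm(x[, j] ~ x[, others]))
    q[i, j] <- q[j, i] <- cor(ri, rj)
  }
  diag(r) <- 0
  oracle <- sum(r^2) / (sum(r^2) + sum(q^2))
  expect_equal(got$overall, oracle, tolerance = 1e-10)
  expect_length(got$per_item, k)
})

test_that("KMO is high for strong single-factor data, undefined when orthogonal", {
  x <- one_factor_items(n = 500, k = 12, loading = 0.9, seed = 42)
  expect_gt(kmo_measure(x)$overall, 0.8)
  expect_error(kmo_measure(orthogonal_items(5)),
               class = "sarcostage_degenerate_error")
})

test_that("Bartlett sphericity: identity case, closed form, nonnegativity", {
  # exactly-orthogonal integer columns give an identity correlation matrix
  res <- bartlett_sphericity(orthogonal_items(5))
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 10)
  expect_equal(res$p_value, 1)

  x <- one_factor_items(n = 100, k = 12, loading = 0.5, seed = 8)
  res <- bartlett_sphericity(x)
  hand <- -(100 - 1 - (2 * 12 + 5) / 6) * log(det(cor(x)))
  expect_equal(res$statistic, hand, tolerance = 1e-12)
  expect_equal(res$df, 66)
  expect_gte(res$statistic, 0)

  expect_error(bartlett_sphericity(one_factor_items(n = 5, k = 12)),
               class = "sarcostage_validation_error")
})

test_that("psychometrics report runs on the complete-response subset", {
  cfg <- sim_config(n_total = 300, seed = 21)
  co <- generate_cohort(cfg)
  rep <- psychometrics_report(co)
  expect_equal(rep$n_complete,
               sum(stats::complete.cases(co[, paste0("item_", 1:12)])))
  expect_lte(rep$alpha_overall, 1)
  expect_length(rep$alpha_subscales, 4)
  expect_true(rep$bartlett$p_value < 0.001)
})
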