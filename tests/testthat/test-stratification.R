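test_that("stage dimension weights follow the dynamic-shift scheme", {
  expect_equal(unname(stage_dimension_weights("A")), c(0.70, 0.20, 0.10))
  expect_equal(unname(stage_dimension_weights("D")), c(0.55, 0.35, 0.10))
  tab <- stage_dimension_weights()
  expect_equal(unname(rowSums(tab)), rep(1, 4))
  expect_equal(unname(tab[, "external"]), rep(0.10, 4))
  # psychological weight grows monotonically A -> D
  expect_true(all(diff(tab[, "psychological"]) > 0))
  expect_error(stage_dimension_weights("E"),
               class = "sarcostage_validation_error")
})

test_that("composite weights reproduce the published spot values", {
  get <- function(stage, leaf) {
    cw <- compose_stage_weights(stage)
    round_half_up(cw$composite[cw$leaf == leaf], 3)
  }
  expect_equal(get("B", "musculoskeletal_deterioration"), 0.209)
  expect_equal(get("D", "sports_anxiety"), 0.189)
  expect_equal(get("C", "activity_radius"), 0.074)
  for (s in c("A", "B", "C", "D")) {
    expect_equal(get(s, "familial_support"), 0.075)
    expect_equal(get(s, "financial_capacity"), 0.025)
  }
})

test_that("composite weights sum to the stage dimension weights and to 1", {
  for (s in c("A", "B", "C", "D")) {
    cw <- compose_stage_weights(s)
    expect_equal(sum(cw$composite), 1, tolerance = 1e-12)
    sums <- tapply(cw$composite, cw$dimension, sum)
    dimw <- stage_dimension_weights(s)
    expect_equal(as.numeric(sums[names(dimw)]), unname(dimw),
                 tolerance = 1e-12)
  }
  bad <- canonical_local_weights()
  bad$external <- c(familial_support = 0.7, financial_capacity = 0.2)
  expect_error(compose_stage_weights("A", bad),
               class = "sarcostage_validation_error")
})

test_that("instrument ratings hit the floor and ceiling of the 1-4 scale", {
  expect_equal(unname(rate_indicators(best_instruments())), rep(1L, 14))
  expect_equal(unname(rate_indicators(worst_instruments())), rep(4L, 14))
})

test_that("FES-I cut-point boundaries map to the higher-severity rating", {
  cuts <- default_rating_cutpoints()$fesi
  for (v in 16:64) {
    inst <- best_instruments()
    inst$fesi <- v
    got <- rate_indicators(inst)[["sports_anxiety"]]
    oracle <- if (v >= cuts[3]) 4L else if (v >= cuts[2]) 3L
              else if (v >= cuts[1]) 2L else 1L
    expect_equal(got, oracle)
  }
})

test_that("a missing instrument names the leaves it blocks", {
  inst <- best_instruments()
  inst$fesi <- NULL
  expect_error(rate_indicators(inst), "sports_anxiety",
               class = "sarcostage_rating_error")
  inst <- best_instruments()
  inst$sarcf <- 12
  expect_error(rate_indicators(inst), class = "sarcostage_validation_error")
})

test_that("intervention score is the weighted sum with the stated grade cut-offs", {
  for (s in c("A", "B", "C", "D")) {
    cw <- compose_stage_weights(s)
    expect_equal(intervention_score(full_ratings(1), cw)$total_score, 1.0,
                 tolerance = 1e-12)
    expect_equal(intervention_score(full_ratings(1), cw)$grade, "I")
    expect_equal(intervention_score(full_ratings(2), cw)$total_score, 2.0,
                 tolerance = 1e-12)
    # boundary convention: exactly 2 is already Grade II
    expect_equal(intervention_score(full_ratings(2), cw)$grade, "II")
    expect_equal(intervention_score(full_ratings(4), cw)$total_score, 4.0,
                 tolerance = 1e-12)
    expect_equal(intervention_score(full_ratings(4), cw)$grade, "III")
  }
  expect_equal(grade_of_score(c(1.999, 2, 3.2, 3.2000001)),
               c("I", "II", "II", "III"))

  # fixture ratings against an independent hand-summed dot product
  cw <- compose_stage_weights("A")
  r <- setNames(c(3L, 2L, 1L, 1L, 2L, 1L, 4L, 1L, 2L, 3L, 2L, 1L, 2L, 3L),
                cw$leaf)
  oracle <- 0
  for (leaf in cw$leaf) {
    oracle <- oracle + r[[leaf]] * cw$composite[cw$leaf == leaf]
  }
  expect_equal(intervention_score(r, cw)$total_score, oracle,
               tolerance = 1e-12)
})

test_that("intervention score rejects mismatched stages and bad ratings", {
  cw <- compose_stage_weights("B")
  r <- full_ratings(2)
  attr(r, "stage") <- "C"
  expect_error(intervention_score(r, cw),
               class = "sarcostage_validation_error")
  r2 <- full_ratings(2)
  r2[1] <- 5L
  expect_error(intervention_score(r2, cw),
               class = "sarcostage_validation_error")
  expect_error(intervention_score(full_ratings(2)[-1], cw),
               class = "sarcostage_validation_error")
})

test_that("raising any rating never lowers the score; grade is monotone", {
  cw <- lapply(setNames(nm = c("A", "B", "C", "D")), compose_stage_weights)
  withr::with_seed(99, {
    for (i in 1:250) {
      s <- sample(c("A", "B", "C", "D"), 1)
      r <- full_ratings(1)
      r[] <- sample(1:4, 14, replace = TRUE)
      base <- intervention_score(r, cw[[s]])$total_score
      j <- sample(14, 1)
      r2 <- r
      r2[j] <- min(r2[j] + 1L, 4L)
      bumped <- intervention_score(r2, cw[[s]])$total_score
      expect_gte(bumped, base)
      expect_true(base >= 1 - 1e-9 && base <= 4 + 1e-9)
    }
  })
  expect_true(all(diff(match(grade_of_score(seq(1, 4, 0.01)),
                             c("I", "II", "III"))) >= 0))
})

test_that("psychologically-dominated profiles score higher as stages progress", {
  withr::with_seed(123, {
    info <- leaf_indicators()
    for (i in 1:20) {
      r <- full_ratings(1)
      r[info$leaf[info$dimension == "physiological"]] <-
        sample(1:2, 9, replace = TRUE)
      r[info$leaf[info$dimension == "psychological"]] <-
        sample(3:4, 3, replace = TRUE)
      r[info$leaf[info$dimension == "external"]] <-
        sample(1:4, 2, replace = TRUE)
      scores <- vapply(c("A", "B", "C", "D"), function(s) {
        intervention_score(r, compose_stage_weights(s))$total_score
      }, numeric(1))
      expect_true(all(diff(scores) > 0))
    }
  })
})

test_that("stratify_cohort vectorizes ratings and grading", {
  dat <- data.frame(
    id = 1:3, stage = c("A", "C", "D"),
    sarcf = c(0, 5, 10), adl = c(100, 60, 10), fesi = c(16, 40, 64),
    hads = c(0, 18, 40), gses = c(40, 22, 10), ses_total = c(9, 5, 3),
    stringsAsFactors = FALSE
  )
  out <- stratify_cohort(dat)
  expect_equal(out$grade[1], "I")
  expect_equal(out$grade[3], "III")
  expect_true(all(out$total_score >= 1 - 1e-9 & out$total_score <= 4 + 1e-9))
})
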