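# 12-item functional self-assessment: scoring, four-band classification, and
# the scale's reliability / sampling-adequacy statistics.

#' Risk band labels
#'
#' The four risk bands of the self-assessment scale, in increasing severity.
#'
#' @return Character vector of the four band labels.
#' @export
risk_bands <- function() {
  c("Healthy", "PreSarcopeniaCompensation", "HighRisk", "DisablingDegeneration")
}

#' Questionnaire item domains
#'
#' Maps the 12 items to their four assessment domains (three items each):
#' strength performance, endurance capacity, balance regulation, and
#' functional adaptation.
#'
#' @return Named list of item index vectors.
#' @export
item_domains <- function() {
  list(
    Strength             = 1:3,
    Endurance            = 4:6,
    Balance              = 7:9,
    FunctionalAdaptation = 10:12
  )
}

#' Classify a total score into a risk band
#'
#' Cut-offs: 0-8 Healthy, 9-16 Pre-Sarcopenia Compensation, 17-24 High Risk,
#' 25 and above Disabling Degeneration.
#'
#' @param total integer total score(s) in 0..36.
#' @return character vector of band labels.
#' @export
band_of_total <- function(total) {
  if (!is.numeric(total) || anyNA(total) || any(total < 0 | total > 36)) {
    stop_validation("total score must be in 0..36 with no missing values")
  }
  risk_bands()[findInterval(total, c(0, 9, 17, 25))]
}

#' Score a single set of item responses
#'
#' Sums the 12 item responses (each 0-3) and assigns the risk band.
#' Missing responses are not imputed: any missing value is an error here,
#' and such participants are routed to the missing-data exclusion of the
#' screening funnel instead.
#'
#' @param responses numeric vector of length 12, each value in 0..3.
#' @return A list of class `banded_score` with elements `total` and `band`.
#' @export
#' @examples
#' score_items(rep(1, 12)) # total 12, PreSarcopeniaCompensation
score_items <- function(responses) {
  if (length(responses) != 12) {
    stop_validation("exactly 12 item responses are required")
  }
  if (anyNA(responses)) {
    stop_sarco("item responses contain missing values; participant belongs in the missing-data exclusion",
               "sarcostage_incomplete_error")
  }
  if (!is.numeric(responses) || any(responses != as.integer(responses)) ||
      any(responses < 0 | responses > 3)) {
    stop_validation("item responses must be integers in 0..3")
  }
  total <- as.integer(sum(responses))
  structure(list(total = total, band = band_of_total(total)),
            class = "banded_score")
}

#' @export
print.banded_score <- function(x, ...) {
  cat("self-assessment total:", x$total, "->", x$band, "\n")
  invisible(x)
}

#' Score every participant in a cohort
#'
#' @param cohort a cohort data frame with columns `item_1` .. `item_12`.
#' @return Data frame with `id`, `total` (NA when any item is missing) and
#'   `band` (NA when incomplete).
#' @export
score_cohort <- function(cohort) {
  items <- cohort_items(cohort)
  total <- rowSums(items)
  band <- rep(NA_character_, length(total))
  ok <- !is.na(total)
  band[ok] <- band_of_total(total[ok])
  data.frame(id = cohort$id, total = total, band = band,
             stringsAsFactors = FALSE)
}

cohort_items <- function(cohort) {
  cols <- paste0("item_", 1:12)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0) {
    stop_validation(paste("cohort lacks item columns:",
                          paste(missing_cols, collapse = ", ")))
  }
  as.matrix(cohort[, cols])
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \sum_i s_i^2 / s_T^2\right)},
#' where \eqn{s_i^2} are the item variances and \eqn{s_T^2} the variance of
#' the total score, all with the sample (n-1) denominator.
#'
#' @param x numeric matrix or data frame, participants in rows, items in
#'   columns; no missing cells.
#' @return Numeric scalar alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 2) {
    stop_validation("cronbach_alpha needs at least 2 items and 2 participants")
  }
  if (anyNA(x)) stop_validation("cronbach_alpha requires complete data")
  k <- ncol(x)
  total_var <- var(rowSums(x))
  if (total_var <= 0) {
    stop_degenerate("total-score variance is zero; alpha is undefined")
  }
  item_var <- apply(x, 2, var)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' Subscale alphas
#'
#' Applies [cronbach_alpha()] to each item domain block.
#'
#' @param x item response matrix (12 columns under the default domains).
#' @param domains named list of column index vectors, by default
#'   [item_domains()].
#' @return Named numeric vector of per-domain alphas.
#' @export
alpha_subscales <- function(x, domains = item_domains()) {
  vapply(domains, function(idx) cronbach_alpha(as.matrix(x)[, idx]), numeric(1))
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO \eqn{= \sum_{i \ne j} r_{ij}^2 / (\sum_{i \ne j} r_{ij}^2 +
#' \sum_{i \ne j} q_{ij}^2)} where \eqn{r} are the observed correlations and
#' \eqn{q} the anti-image partial correlations obtained from the inverse
#' correlation matrix (\eqn{q_{ij} = -s_{ij}/\sqrt{s_{ii}s_{jj}}} with
#' \eqn{S = R^{-1}}). Per-item measures use the same ratio restricted to row
#' i.
#'
#' @param x numeric matrix or data frame of item responses.
#' @return List with `overall` (scalar) and `per_item` (named vector of MSA
#'   values).
#' @export
kmo_measure <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_validation("kmo_measure requires complete data")
  R <- cor(x)
  S <- tryCatch(solve(R), error = function(e) {
    stop_degenerate("correlation matrix is singular; KMO is undefined")
  })
  d <- 1 / sqrt(diag(S))
  Q <- -S * outer(d, d)
  diag(R) <- 0
  diag(Q) <- 0
  r2 <- R^2
  q2 <- Q^2
  denom <- sum(r2) + sum(q2)
  if (denom < 1e-12) {
    stop_degenerate("all off-diagonal correlations are zero; KMO is undefined (0/0)")
  }
  per_denom <- rowSums(r2) + rowSums(q2)
  if (any(per_denom < 1e-12)) {
    stop_degenerate("an item has no correlation with any other; KMO is undefined (0/0)")
  }
  list(
    overall  = sum(r2) / denom,
    per_item = setNames(rowSums(r2) / per_denom, colnames(x))
  )
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is an identity:
#' \eqn{\chi^2 = -(n - 1 - (2k+5)/6)\,\ln\det R} on \eqn{k(k-1)/2} degrees
#' of freedom.
#'
#' @param x numeric matrix or data frame (n participants by k items, n > k).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_validation("bartlett_sphericity requires complete data")
  n <- nrow(x)
  k <- ncol(x)
  if (n <= k) stop_validation("bartlett_sphericity requires more participants than items")
  R <- cor(x)
  detR <- det(R)
  if (!is.finite(detR) || detR <= 0) {
    stop_degenerate("correlation matrix is not positive definite")
  }
  stat <- -(n - 1 - (2 * k + 5) / 6) * log(detR)
  df <- k * (k - 1) / 2
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Psychometrics report for a cohort's item responses
#'
#' Convenience wrapper computing overall alpha, the four subscale alphas,
#' KMO, and Bartlett's test on the complete-response participants.
#'
#' @param cohort cohort data frame with `item_1` .. `item_12`.
#' @return List with `n_complete`, `alpha_overall`, `alpha_subscales`,
#'   `kmo`, `bartlett`.
#' @export
psychometrics_report <- function(cohort) {
  items <- cohort_items(cohort)
  complete <- stats::complete.cases(items)
  m <- items[complete, , drop = FALSE]
  list(
    n_complete      = sum(complete),
    alpha_overall   = cronbach_alpha(m),
    alpha_subscales = as.list(alpha_subscales(m)),
    kmo             = kmo_measure(m)$overall,
    bartlett        = bartlett_sphericity(m)
  )
}
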