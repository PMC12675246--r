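# Symptom-behaviour exclusion funnel: missing-data removal, confounding
# comorbidity exclusion, and the 9-point diagnostic threshold.

#' Confounding exclusion categories
#'
#' The closed set of nine pathology categories whose presence excludes a
#' participant (conditions that mimic sarcopenic phenotypes: joint pain and
#' disuse atrophy, impaired protein anabolism, neurogenic weakness, reduced
#' exercise tolerance, and so on). The order is the fixed attribution
#' priority used when a participant carries several flags.
#'
#' @return Character vector of the nine category names, in priority order.
#' @export
exclusion_categories <- function() {
  c("JointDiseases", "MetabolicEndocrine", "Neurological", "Cardiovascular",
    "ChronicRespiratory", "PostoperativeRecovery", "VisualSystem",
    "InflammatoryAutoimmune", "Other")
}

diagnostic_statuses <- function() c("confirmed", "symptomatic_undiagnosed")

#' Serialize / parse comorbidity flag sets
#'
#' Cohort CSVs carry each participant's comorbidity set as a single string:
#' `"Category/status"` pairs joined by `";"`, empty string for none.
#'
#' @param flags data frame with columns `category`, `status`.
#' @return `format_comorbidities()`: a single string. `parse_comorbidities()`:
#'   a data frame with columns `category`, `status`.
#' @export
format_comorbidities <- function(flags) {
  if (is.null(flags) || nrow(flags) == 0) return("")
  paste(paste(flags$category, flags$status, sep = "/"), collapse = ";")
}

#' @param x a single comorbidity string.
#' @rdname format_comorbidities
#' @export
parse_comorbidities <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(category = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "/", fixed = TRUE)
  out <- data.frame(
    category = vapply(parts, `[`, character(1), 1),
    status   = vapply(parts, function(p) if (length(p) > 1) p[2] else "confirmed",
                      character(1)),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(out$category, exclusion_categories())
  if (length(bad) > 0) {
    stop_validation(paste("unknown exclusion category:", paste(bad, collapse = ", ")))
  }
  bad_status <- setdiff(out$status, diagnostic_statuses())
  if (length(bad_status) > 0) {
    stop_validation(paste("unknown diagnostic status:", paste(bad_status, collapse = ", ")))
  }
  out
}

#' Missing-data screen
#'
#' A participant is excluded when any of the 12 item responses is missing.
#'
#' @param responses numeric vector of length 12 (NA = missing).
#' @return `"pass"` or `"excluded_missing"`.
#' @export
screen_missing <- function(responses) {
  if (length(responses) != 12) stop_validation("expected 12 item response slots")
  if (anyNA(responses)) "excluded_missing" else "pass"
}

#' Comorbidity screen
#'
#' Excluded whenever the comorbidity set is non-empty (both confirmed and
#' symptomatic-undiagnosed flags count). When several categories are
#' flagged, the attributed category is the highest-priority one under the
#' fixed [exclusion_categories()] order.
#'
#' @param comorbidities either a comorbidity string (see
#'   [format_comorbidities()]) or a data frame with `category`, `status`.
#' @return `"pass"`, or a list with `status = "excluded_comorbidity"`,
#'   `category`, and `diagnostic_status`.
#' @export
screen_comorbidity <- function(comorbidities) {
  flags <- if (is.character(comorbidities)) {
    parse_comorbidities(comorbidities)
  } else {
    comorbidities
  }
  if (nrow(flags) == 0) return("pass")
  bad <- setdiff(flags$category, exclusion_categories())
  if (length(bad) > 0) {
    stop_validation(paste("unknown exclusion category:", paste(bad, collapse = ", ")))
  }
  prio <- match(flags$category, exclusion_categories())
  top <- which.min(prio)
  list(status = "excluded_comorbidity",
       category = flags$category[top],
       diagnostic_status = flags$status[top])
}

#' Score-threshold screen
#'
#' The 9-point diagnostic threshold: totals of 8 or less (the Healthy band)
#' are excluded from sarcopenia-specific assessment.
#'
#' @param total total questionnaire score(s), 0..36.
#' @param threshold minimum total to pass (default 9).
#' @return `"pass"` or `"excluded_below_threshold"` (vectorized).
#' @export
screen_threshold <- function(total, threshold = 9) {
  if (anyNA(total)) stop_validation("total score is missing")
  ifelse(total >= threshold, "pass", "excluded_below_threshold")
}

#' Run the full screening funnel
#'
#' Applies, in order: missing-data screen, questionnaire scoring, comorbidity
#' screen, score-threshold screen. Every participant receives exactly one
#' terminal status. The stage order matters only for attribution when a
#' participant is both comorbid and below threshold; the final cohort size is
#' order-invariant, and `order` lets you swap the two exclusion stages.
#'
#' @param cohort cohort data frame (columns `id`, `item_1`..`item_12`,
#'   `comorbidities`).
#' @param threshold score threshold (default 9).
#' @param order character vector giving the order of the two post-scoring
#'   screens; default `c("comorbidity", "threshold")`.
#' @return A list of class `funnel_report`: counts (`n_surveyed`,
#'   `n_missing_excluded`, `n_analytic`, `n_comorbidity_excluded`,
#'   `n_below_threshold_excluded`, `n_final`), `comorbidity_breakdown`
#'   (category by diagnostic status counts), and `statuses` (per-participant
#'   terminal status).
#' @export
run_funnel <- function(cohort, threshold = 9,
                       order = c("comorbidity", "threshold")) {
  if (nrow(cohort) == 0) stop_validation("cohort is empty")
  order <- match.arg(order, c("comorbidity", "threshold"), several.ok = TRUE)
  if (length(order) != 2 || anyDuplicated(order)) {
    stop_validation("order must contain 'comorbidity' and 'threshold' once each")
  }

  items <- cohort_items(cohort)
  n <- nrow(cohort)
  status <- rep(NA_character_, n)
  category <- rep(NA_character_, n)
  diag_status <- rep(NA_character_, n)

  miss <- apply(items, 1, anyNA)
  status[miss] <- "excluded_missing"

  totals <- rowSums(items)
  comorbid_hit <- function(i) {
    res <- tryCatch(
      screen_comorbidity(cohort$comorbidities[i]),
      sarcostage_validation_error = function(e) {
        stop_validation(paste0("participant ", cohort$id[i], ": ",
                               conditionMessage(e)))
      }
    )
    if (identical(res, "pass")) return(FALSE)
    category[i] <<- res$category
    diag_status[i] <<- res$diagnostic_status
    TRUE
  }

  for (i in which(!miss)) {
    excluded <- FALSE
    for (stage in order) {
      if (stage == "comorbidity" && comorbid_hit(i)) {
        status[i] <- "excluded_comorbidity"
        excluded <- TRUE
      } else if (stage == "threshold" && totals[i] < threshold) {
        status[i] <- "excluded_below_threshold"
        excluded <- TRUE
      }
      if (excluded) break
    }
    if (!excluded) status[i] <- "pass"
  }

  comorb <- status == "excluded_comorbidity"
  breakdown <- table(
    category = factor(category[comorb], levels = exclusion_categories()),
    status = factor(diag_status[comorb], levels = diagnostic_statuses())
  )

  report <- list(
    n_surveyed = n,
    n_missing_excluded = sum(miss),
    n_analytic = n - sum(miss),
    n_comorbidity_excluded = sum(comorb),
    n_below_threshold_excluded = sum(status == "excluded_below_threshold"),
    n_final = sum(status == "pass"),
    comorbidity_breakdown = breakdown,
    statuses = data.frame(id = cohort$id, status = status,
                          exclusion_category = category,
                          diagnostic_status = diag_status,
                          total = totals,
                          stringsAsFactors = FALSE)
  )
  class(report) <- "funnel_report"
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("screening funnel:\n")
  cat("  surveyed:            ", x$n_surveyed, "\n")
  cat("  missing excluded:    ", x$n_missing_excluded, "\n")
  cat("  analytic sample:     ", x$n_analytic, "\n")
  cat("  comorbidity excluded:", x$n_comorbidity_excluded, "\n")
  cat("  below threshold:     ", x$n_below_threshold_excluded, "\n")
  cat("  final cohort:        ", x$n_final, "\n")
  invisible(x)
}

funnel_counts <- function(report) {
  unlist(report[c("n_surveyed", "n_missing_excluded", "n_analytic",
                  "n_comorbidity_excluded", "n_below_threshold_excluded",
                  "n_final")])
}
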