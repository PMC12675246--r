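# Four-stage (A-D) behavioural progression model, socioeconomic-status
# grouping, and triangulated stage validation.

#' Stage labels and phase names
#'
#' The four progression stages form a fixed bijection with their phase
#' names: A Functional Compensation, B Compensation Attenuation,
#' C Decompensation, D Dependence.
#'
#' @return Named character vector mapping stage label to phase name.
#' @export
stage_phases <- function() {
  c(A = "FunctionalCompensation", B = "CompensationAttenuation",
    C = "Decompensation", D = "Dependence")
}

stage_labels <- function() names(stage_phases())

#' Socioeconomic-status score
#'
#' Sums three 1-3 bands (household income, education, occupation) into a
#' total of 3-9 and groups it: Low 3-4, Medium 5-6, High 7-9.
#'
#' @param income_band,education_band,occupation_band integer vectors, each
#'   element in 1..3.
#' @return Data frame with columns `income_band`, `education_band`,
#'   `occupation_band`, `total`, `group`.
#' @export
#' @examples
#' ses_score(1, 1, 1) # total 3, Low
#' ses_score(2, 2, 1) # total 5, Medium
ses_score <- function(income_band, education_band, occupation_band) {
  bands <- cbind(income_band, education_band, occupation_band)
  if (anyNA(bands) || !all(bands %in% 1:3)) {
    stop_validation("SES bands must each be 1, 2 or 3")
  }
  total <- as.integer(rowSums(bands))
  group <- cut(total, breaks = c(2, 4, 6, 9),
               labels = c("Low", "Medium", "High"))
  data.frame(income_band = bands[, 1], education_band = bands[, 2],
             occupation_band = bands[, 3], total = total,
             group = as.character(group), stringsAsFactors = FALSE)
}

#' Assign a progression stage from questionnaire band and ADL independence
#'
#' Default mapping: Pre-Sarcopenia Compensation -> A; High Risk -> B when
#' basic activities of daily living are fully independent, otherwise C;
#' Disabling Degeneration -> D. Participants in the Healthy band have passed
#' no screening threshold and are not stageable.
#'
#' @param band risk band label(s), see [risk_bands()].
#' @param adl_independence ADL independence score(s), 0-100.
#' @param adl_independent_cut minimum ADL score counted as fully independent
#'   (default 90).
#' @param mapping named character vector mapping the three stageable bands
#'   to stages; the High Risk entry names the stage used when ADL is fully
#'   independent (one severity step is added otherwise).
#' @return Character vector of stage labels.
#' @export
assign_stage <- function(band, adl_independence, adl_independent_cut = 90,
                         mapping = c(PreSarcopeniaCompensation = "A",
                                     HighRisk = "B",
                                     DisablingDegeneration = "D")) {
  if (any(band == "Healthy")) {
    stop_sarco("Healthy-band participants are below the diagnostic threshold and cannot be staged",
               "sarcostage_not_stageable_error")
  }
  bad <- setdiff(band, risk_bands())
  if (length(bad) > 0) {
    stop_validation(paste("unknown risk band:", paste(bad, collapse = ", ")))
  }
  stage <- unname(mapping[band])
  dependent <- band == "HighRisk" & adl_independence < adl_independent_cut
  idx <- match(stage, stage_labels())
  idx[dependent] <- pmin(idx[dependent] + 1L, 4L)
  stage_labels()[idx]
}

#' Stage from the SARC-F screening score
#'
#' Monotone step mapping through configurable cut-points; a score equal to a
#' cut-point maps to the higher-severity side. Defaults: 0-1 A, 2-3 B,
#' 4-6 C, 7-10 D.
#'
#' @param sarcf SARC-F score(s), 0-10.
#' @param cutpoints increasing lower bounds of stages B, C, D.
#' @return Character vector of stage labels.
#' @export
stage_from_sarcf <- function(sarcf, cutpoints = c(2, 4, 7)) {
  if (anyNA(sarcf) || any(sarcf < 0 | sarcf > 10)) {
    stop_validation("SARC-F scores must be in 0..10")
  }
  if (is.unsorted(cutpoints, strictly = TRUE) || length(cutpoints) != 3) {
    stop_validation("cutpoints must be three strictly increasing values")
  }
  stage_labels()[1L + findInterval(sarcf, cutpoints)]
}

#' Default DXA staging cut-points
#'
#' Sex-specific appendicular lean mass index (ALMI, kg/m^2) thresholds:
#' at or above the first value stage A, then B, then C, below the last
#' value stage D. Anchored on conventional low-muscle-mass reference values
#' (about 7.0 kg/m^2 for men, 5.5 kg/m^2 for women) with one step either
#' side; configurable, and validated here only for mapping mechanics.
#'
#' @return Named list with `male` and `female` descending threshold triples.
#' @export
default_dxa_cutpoints <- function() {
  list(male = c(7.6, 7.0, 6.0), female = c(6.0, 5.5, 4.8))
}

#' Stage from DXA-derived lean mass index
#'
#' Monotone decreasing mapping: lower ALMI means higher-severity stage.
#'
#' @param almi appendicular lean mass index value(s), kg/m^2, positive.
#' @param sex `"male"` or `"female"` (recycled).
#' @param cutpoints named list as in [default_dxa_cutpoints()].
#' @return Character vector of stage labels.
#' @export
stage_from_dxa <- function(almi, sex, cutpoints = default_dxa_cutpoints()) {
  if (anyNA(almi) || any(almi <= 0)) {
    stop_validation("ALMI must be positive")
  }
  if (!all(sex %in% c("male", "female"))) {
    stop_validation("sex must be 'male' or 'female'")
  }
  sex <- rep_len(sex, length(almi))
  idx <- vapply(seq_along(almi), function(i) {
    cuts <- cutpoints[[sex[i]]]
    1L + sum(almi[i] < cuts)
  }, integer(1))
  stage_labels()[idx]
}

#' Triangulated stage validation
#'
#' Compares per-subject stages assigned by three methods (questionnaire-
#' derived self-stage, SARC-F-derived, DXA-derived) on a small validation
#' subsample balanced across SES groups, and reports the exact-agreement
#' proportion overall and per SES group.
#'
#' @param subsample data frame with columns `ses_group`, `stage_self`,
#'   `stage_sarcf`, `stage_dxa`.
#' @param per_group required subjects per SES group under strict mode
#'   (default 5).
#' @param strict when TRUE (default), requires exactly the three SES groups
#'   with `per_group` subjects each.
#' @return List of class `triangulation_report`: `n`, `agreement_overall`,
#'   `agreement_by_group`, `per_subject` (logical agreement flags).
#' @export
triangulate <- function(subsample, per_group = 5, strict = TRUE) {
  needed <- c("ses_group", "stage_self", "stage_sarcf", "stage_dxa")
  missing_cols <- setdiff(needed, names(subsample))
  if (length(missing_cols) > 0) {
    stop_validation(paste("subsample lacks columns:",
                          paste(missing_cols, collapse = ", ")))
  }
  groups <- c("Low", "Medium", "High")
  counts <- table(factor(subsample$ses_group, levels = groups))
  if (strict && !all(counts == per_group)) {
    stop_validation(paste0("strict mode requires ", per_group,
                           " subjects in each of the three SES groups"))
  }
  agree <- subsample$stage_self == subsample$stage_sarcf &
    subsample$stage_self == subsample$stage_dxa
  by_group <- tapply(agree, factor(subsample$ses_group, levels = groups), mean)
  structure(list(
    n = nrow(subsample),
    agreement_overall = mean(agree),
    agreement_by_group = by_group,
    per_subject = data.frame(subsample, agree = agree,
                             stringsAsFactors = FALSE)
  ), class = "triangulation_report")
}

#' @export
print.triangulation_report <- function(x, ...) {
  cat("triangulation on", x$n, "subjects: exact agreement",
      sprintf("%.1f%%", 100 * x$agreement_overall), "\n")
  print(round(x$agreement_by_group, 3))
  invisible(x)
}
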