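# Stage-dependent dynamic weighting, composite indicator weights, severity
# ratings from clinical instruments, and intervention grading.

#' The 14 leaf indicators
#'
#' Leaf indicators of the evaluation hierarchy with their primary dimension:
#' two secondary physiological indicators plus the seven self-care leaves,
#' three psychological indicators, two external factors.
#'
#' @return Data frame with columns `leaf`, `dimension`, and `secondary`
#'   (the secondary indicator each leaf sits under).
#' @export
leaf_indicators <- function() {
  data.frame(
    leaf = c("musculoskeletal_deterioration", "activity_radius",
             "postural_transition", "ambulation", "toileting", "dressing",
             "feeding", "bathing", "grooming",
             "sports_anxiety", "social_engagement", "self_efficacy",
             "familial_support", "financial_capacity"),
    dimension = c(rep("physiological", 9), rep("psychological", 3),
                  rep("external", 2)),
    secondary = c("musculoskeletal_deterioration", "activity_radius",
                  rep("self_care", 7),
                  "sports_anxiety", "social_engagement", "self_efficacy",
                  "familial_support", "financial_capacity"),
    stringsAsFactors = FALSE
  )
}

#' Published stage-specific composite weights
#'
#' The published weight allocation across indicator levels: the composite
#' weight of each of the 14 leaf indicators at each progression stage,
#' printed to three decimals. Used as the reference that
#' [compose_stage_weights()] reproduces, and as the source from which the
#' canonical local weights are back-derived.
#'
#' @return Data frame with columns `stage`, `leaf`, `composite`.
#' @export
published_composite_weights <- function() {
  leaves <- leaf_indicators()$leaf
  vals <- list(
    A = c(0.225, 0.086, 0.058, 0.058, 0.058, 0.039, 0.078, 0.058, 0.039,
          0.108, 0.059, 0.033, 0.075, 0.025),
    B = c(0.209, 0.080, 0.054, 0.054, 0.054, 0.036, 0.072, 0.054, 0.036,
          0.135, 0.074, 0.041, 0.075, 0.025),
    C = c(0.193, 0.074, 0.050, 0.050, 0.050, 0.033, 0.067, 0.050, 0.033,
          0.162, 0.089, 0.049, 0.075, 0.025),
    D = c(0.177, 0.068, 0.046, 0.046, 0.046, 0.031, 0.061, 0.046, 0.031,
          0.189, 0.104, 0.057, 0.075, 0.025)
  )
  do.call(rbind, lapply(names(vals), function(s) {
    data.frame(stage = s, leaf = leaves, composite = vals[[s]],
               stringsAsFactors = FALSE)
  }))
}

#' Stage-specific dimension weights
#'
#' The dynamic weight-shifting scheme: physiological weight declines from
#' 70% at Stage A to 55% at Stage D while the psychological weight grows
#' from 20% to 35%; the external-factor weight is fixed at 10% throughout.
#'
#' @param stage stage label(s) in `"A".."D"`; when missing, the full 4 x 3
#'   matrix is returned.
#' @return Named numeric triple `(physiological, psychological, external)`,
#'   or the full matrix with stages in rows.
#' @export
#' @examples
#' stage_dimension_weights("A") # 0.70 0.20 0.10
stage_dimension_weights <- function(stage) {
  tab <- rbind(
    A = c(physiological = 0.70, psychological = 0.20, external = 0.10),
    B = c(physiological = 0.65, psychological = 0.25, external = 0.10),
    C = c(physiological = 0.60, psychological = 0.30, external = 0.10),
    D = c(physiological = 0.55, psychological = 0.35, external = 0.10)
  )
  if (missing(stage)) return(tab)
  if (length(stage) != 1 || !stage %in% rownames(tab)) {
    stop_validation("stage must be one of 'A', 'B', 'C', 'D'")
  }
  tab[stage, ]
}

#' Canonical within-dimension local weights
#'
#' Back-derives the local leaf weights from the published Stage A composite
#' weights: each dimension's Stage A composites are normalized to sum 1
#' within the dimension. (The printed physiological block sums to 0.699
#' rather than 0.700 because the published table rounds to three decimals;
#' normalizing restores the exact sum-to-one weight structure the scoring
#' formula assumes, at the cost of a handful of reproduced cells landing a
#' rounding half-step from the printed value.)
#'
#' @return Named list with numeric vectors `physiological` (9 leaves),
#'   `psychological` (3), `external` (2), each summing to 1.
#' @export
canonical_local_weights <- function() {
  pub <- published_composite_weights()
  a <- pub[pub$stage == "A", ]
  info <- leaf_indicators()
  out <- lapply(split(seq_len(nrow(info)), info$dimension), function(idx) {
    w <- setNames(a$composite[idx], a$leaf[idx])
    w / sum(w)
  })
  out[c("physiological", "psychological", "external")]
}

#' Canonical indicator hierarchy
#'
#' Builds the three-dimension hierarchy (with the self-care secondary node
#' above its seven tertiary leaves) carrying the canonical local weights,
#' suitable for [compose_hierarchy()].
#'
#' @param locals local weights as from [canonical_local_weights()].
#' @return A `sarco_hierarchy`.
#' @export
canonical_hierarchy <- function(locals = canonical_local_weights()) {
  phys <- locals$physiological
  selfcare_leaves <- leaf_indicators()
  selfcare_leaves <- selfcare_leaves$leaf[selfcare_leaves$secondary == "self_care"]
  selfcare_total <- sum(phys[selfcare_leaves])
  leaf_node <- function(name, w) list(name = name, local_weight = unname(w))
  hierarchy <- list(
    name = "intervention_need",
    children = list(
      list(name = "physiological", local_weight = NA, children = c(
        list(leaf_node("musculoskeletal_deterioration",
                       phys[["musculoskeletal_deterioration"]]),
             leaf_node("activity_radius", phys[["activity_radius"]])),
        list(list(name = "self_care", local_weight = selfcare_total,
                  children = lapply(selfcare_leaves, function(l) {
                    leaf_node(l, phys[[l]] / selfcare_total)
                  })))
      )),
      list(name = "psychological", local_weight = NA,
           children = lapply(names(locals$psychological), function(l) {
             leaf_node(l, locals$psychological[[l]])
           })),
      list(name = "external", local_weight = NA,
           children = lapply(names(locals$external), function(l) {
             leaf_node(l, locals$external[[l]])
           }))
    )
  )
  # dimension-level locals are stage-dependent; mark the Stage A defaults
  dimw <- stage_dimension_weights("A")
  for (i in seq_along(hierarchy$children)) {
    hierarchy$children[[i]]$local_weight <-
      unname(dimw[[hierarchy$children[[i]]$name]])
  }
  ahp_hierarchy(hierarchy)
}

#' Compose stage-specific composite weights
#'
#' Composite weight of each leaf = within-dimension local weight times the
#' stage's dimension weight. Weights are kept un-rounded for scoring;
#' rounding to three decimals is display-only.
#'
#' @param stage stage label `"A".."D"`.
#' @param locals within-dimension local weights, by default
#'   [canonical_local_weights()].
#' @return Data frame of class `composite_weights` with columns `leaf`,
#'   `dimension`, `local`, `composite`, and attribute `stage`.
#' @export
#' @examples
#' cw <- compose_stage_weights("B")
#' round_half_up(cw$composite[cw$leaf == "musculoskeletal_deterioration"], 3)
compose_stage_weights <- function(stage, locals = canonical_local_weights()) {
  dimw <- stage_dimension_weights(stage)
  for (d in names(locals)) {
    if (abs(sum(locals[[d]]) - 1) > 1e-9) {
      stop_validation(paste0("local weights for dimension '", d,
                             "' must sum to 1"))
    }
  }
  info <- leaf_indicators()
  local <- numeric(nrow(info))
  for (i in seq_len(nrow(info))) {
    local[i] <- locals[[info$dimension[i]]][[info$leaf[i]]]
  }
  out <- data.frame(info[, c("leaf", "dimension")], local = local,
                    composite = local * dimw[info$dimension],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "stage") <- stage
  class(out) <- c("composite_weights", "data.frame")
  out
}

#' Default instrument-to-rating cut-points
#'
#' Maps each clinical instrument onto the 1-4 severity scale. Values at a
#' cut-point map to the higher-severity rating. Instruments where higher
#' scores mean better function (ADL independence, GSES, SES total) are
#' reverse-scored. These cut-points are a documented, fully overridable
#' default; the tested surface is the mapping mechanics.
#'
#' @return Named list of cut-point vectors: `sarcf`, `adl`, `fesi`, `hads`,
#'   `gses`, `ses` (each length 3).
#' @export
default_rating_cutpoints <- function() {
  list(
    sarcf = c(2, 4, 7),     # 0-1 -> 1, 2-3 -> 2, 4-6 -> 3, 7-10 -> 4
    adl   = c(50, 75, 90),  # >=90 -> 1, 75-89 -> 2, 50-74 -> 3, <50 -> 4
    fesi  = c(20, 28, 38),  # 16-19 -> 1, 20-27 -> 2, 28-37 -> 3, >=38 -> 4
    hads  = c(8, 15, 22),   # 0-7 -> 1, 8-14 -> 2, 15-21 -> 3, >=22 -> 4
    gses  = c(20, 25, 30),  # >=30 -> 1, 25-29 -> 2, 20-24 -> 3, <20 -> 4
    ses   = c(4, 6, 8)      # total 8-9 -> 1, 6-7 -> 2, 4-5 -> 3, 3 -> 4
  )
}

rating_up <- function(x, cuts) 1L + findInterval(x, cuts)
rating_down <- function(x, cuts) 4L - findInterval(x, cuts)

instrument_ranges <- function() {
  list(sarcf = c(0, 10), adl = c(0, 100), fesi = c(16, 64),
       hads = c(0, 42), gses = c(10, 40), ses = c(3, 9))
}

#' Rate the 14 leaf indicators from instrument scores
#'
#' Physiological leaves are rated from SARC-F (musculoskeletal
#' deterioration, activity radius) and from ADL independence (the seven
#' self-care leaves); movement anxiety from FES-I; social engagement from
#' HADS; self-efficacy from GSES (reverse-scored); both external leaves
#' from the SES total.
#'
#' @param instruments named list or one-row data frame with `sarcf`, `adl`,
#'   `fesi`, `hads`, `gses`, `ses_total`.
#' @param cutpoints list as from [default_rating_cutpoints()].
#' @return Named integer vector of 14 ratings, each in 1..4.
#' @export
rate_indicators <- function(instruments, cutpoints = default_rating_cutpoints()) {
  need <- c(sarcf = "sarcf", adl = "adl", fesi = "fesi", hads = "hads",
            gses = "gses", ses = "ses_total")
  leaf_source <- c(
    musculoskeletal_deterioration = "sarcf", activity_radius = "sarcf",
    postural_transition = "adl", ambulation = "adl", toileting = "adl",
    dressing = "adl", feeding = "adl", bathing = "adl", grooming = "adl",
    sports_anxiety = "fesi", social_engagement = "hads",
    self_efficacy = "gses", familial_support = "ses",
    financial_capacity = "ses"
  )
  vals <- list()
  for (inst in names(need)) {
    v <- instruments[[need[[inst]]]]
    if (is.null(v) || is.na(v)) {
      leaves <- names(leaf_source)[leaf_source == inst]
      stop_sarco(paste0("instrument '", need[[inst]],
                        "' is missing; cannot rate: ",
                        paste(leaves, collapse = ", ")),
                 "sarcostage_rating_error")
    }
    rng <- instrument_ranges()[[inst]]
    if (v < rng[1] || v > rng[2]) {
      stop_validation(paste0("instrument '", need[[inst]], "' value ", v,
                             " outside range [", rng[1], ", ", rng[2], "]"))
    }
    vals[[inst]] <- v
  }
  reverse <- c("adl", "gses", "ses")
  ratings <- vapply(names(leaf_source), function(leaf) {
    inst <- leaf_source[[leaf]]
    if (inst %in% reverse) {
      rating_down(vals[[inst]], cutpoints[[inst]])
    } else {
      rating_up(vals[[inst]], cutpoints[[inst]])
    }
  }, integer(1))
  ratings
}

#' Map a total intervention score to a grade
#'
#' Grade I for scores below 2, Grade II for scores from 2 to 3.2
#' (inclusive at both ends), Grade III above 3.2. A small numeric
#' tolerance absorbs floating-point round-off at the cut-offs, so a
#' profile whose exact score is a boundary value always receives the
#' boundary's inclusive grade.
#'
#' @param score numeric total intervention score(s) in `[1, 4]`.
#' @param eps numeric tolerance at the two cut-offs (default 1e-9).
#' @return Character vector `"I"`, `"II"` or `"III"`.
#' @export
grade_of_score <- function(score, eps = 1e-9) {
  ifelse(score < 2 - eps, "I", ifelse(score <= 3.2 + eps, "II", "III"))
}

#' Total intervention score and grade
#'
#' Computes `sum(rating * composite weight)` over the 14 leaf indicators,
#' using the un-rounded stage-specific composite weights, and maps the
#' total to an intervention grade.
#'
#' @param ratings named integer vector of 14 ratings in 1..4 (as from
#'   [rate_indicators()]), optionally carrying a `stage` attribute.
#' @param weights a `composite_weights` data frame for the participant's
#'   stage (see [compose_stage_weights()]).
#' @return List of class `intervention_result`: `stage`, `total_score`,
#'   `grade`.
#' @export
#' @examples
#' cw <- compose_stage_weights("A")
#' r <- setNames(rep(2L, 14), cw$leaf)
#' intervention_score(r, cw) # total 2.0, Grade II
intervention_score <- function(ratings, weights) {
  if (!inherits(weights, "composite_weights")) {
    stop_validation("weights must come from compose_stage_weights()")
  }
  rstage <- attr(ratings, "stage")
  wstage <- attr(weights, "stage")
  if (!is.null(rstage) && !identical(rstage, wstage)) {
    stop_validation(paste0("ratings were made for stage ", rstage,
                           " but weights are for stage ", wstage))
  }
  if (is.null(names(ratings)) || !setequal(names(ratings), weights$leaf)) {
    stop_validation("ratings must be named by the 14 leaf indicators")
  }
  r <- ratings[weights$leaf]
  if (anyNA(r) || !all(r %in% 1:4)) {
    stop_validation("every rating must be an integer in 1..4")
  }
  total <- sum(as.numeric(r) * weights$composite)
  structure(list(stage = wstage, total_score = total,
                 grade = grade_of_score(total)),
            class = "intervention_result")
}

#' @export
print.intervention_result <- function(x, ...) {
  cat(sprintf("stage %s: total intervention score %.3f -> Grade %s\n",
              x$stage, x$total_score, x$grade))
  invisible(x)
}

#' Stratify staged participants into intervention grades
#'
#' Vectorized pipeline step: rates each participant's indicators from their
#' instrument scores and computes the stage-weighted intervention score and
#' grade.
#'
#' @param data data frame with columns `id`, `stage`, `sarcf`, `adl`,
#'   `fesi`, `hads`, `gses`, `ses_total`.
#' @param cutpoints rating cut-points, see [default_rating_cutpoints()].
#' @param locals local weights, see [canonical_local_weights()].
#' @return Data frame with `id`, `stage`, `total_score`, `grade`.
#' @export
stratify_cohort <- function(data, cutpoints = default_rating_cutpoints(),
                            locals = canonical_local_weights()) {
  cw <- lapply(setNames(nm = stage_labels()),
               compose_stage_weights, locals = locals)
  out <- vapply(seq_len(nrow(data)), function(i) {
    ratings <- rate_indicators(data[i, ], cutpoints)
    intervention_score(ratings, cw[[data$stage[i]]])$total_score
  }, numeric(1))
  data.frame(id = data$id, stage = data$stage, total_score = out,
             grade = grade_of_score(out), stringsAsFactors = FALSE)
}
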