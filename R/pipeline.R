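# End-to-end orchestration: simulate -> screen -> score -> stage ->
# stratify, with machine-readable reports and a reproducibility manifest.

# One top-level seed is fanned out to per-stage child seeds with a MINSTD-
# style multiplicative step, so each stage is independently reproducible
# and every derived seed stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

#' Run the full stratification pipeline
#'
#' Executes the five stages in order on a synthetic cohort: generation,
#' screening funnel, questionnaire scoring and psychometrics, progression
#' staging with SES grouping and triangulation, and intervention
#' stratification. Writes `cohort.csv` (+ config sidecar), `scores.csv`,
#' `funnel.json`, `psychometrics.json`, `staging.csv`,
#' `stratification.csv`, `triangulation.json` and `manifest.json` into
#' `out_dir`. Identical configuration and seed produce byte-identical
#' outputs; on any stage failure the partial outputs are removed.
#'
#' @param config a [sim_config()]; its seed is replaced by one derived from
#'   `seed` when `seed` is given.
#' @param out_dir output directory (created if needed).
#' @param seed optional top-level integer seed fanned out to the stages.
#' @param quiet suppress the one-line-per-stage progress log.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         quiet = TRUE) {
  config <- validate_sim_config(config)
  if (config$n_total == 0) {
    stop_config("pipeline requires a non-empty cohort (n_total > 0)")
  }
  if (!is.null(seed)) config$seed <- derive_seed(seed, 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name) {
    written <<- c(written, file.path(out_dir, name))
    file.path(out_dir, name)
  }
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }

  tryCatch({
    cohort <- generate_cohort(config)
    write_cohort(cohort, emit("cohort.csv"))
    written <- c(written, file.path(out_dir, "cohort.csv.config.json"))
    say("simulate", nrow(cohort), " participants")

    funnel <- run_funnel(cohort)
    jsonlite::write_json(
      c(as.list(funnel_counts(funnel)),
        list(comorbidity_breakdown = as.data.frame(funnel$comorbidity_breakdown))),
      emit("funnel.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("screen", funnel$n_final, " of ", funnel$n_surveyed, " pass")

    scores <- score_cohort(cohort)
    write.csv(scores, emit("scores.csv"), row.names = FALSE, na = "")
    psy <- psychometrics_report(cohort)
    jsonlite::write_json(psy, emit("psychometrics.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("score", "alpha = ", round(psy$alpha_overall, 3))

    pass_ids <- funnel$statuses$id[funnel$statuses$status == "pass"]
    passers <- cohort[cohort$id %in% pass_ids, ]
    pass_scores <- scores[scores$id %in% pass_ids, ]
    ses <- ses_score(passers$ses_income_band, passers$ses_education_band,
                     passers$ses_occupation_band)
    staging <- data.frame(
      id = passers$id,
      stage = assign_stage(pass_scores$band, passers$adl_independence),
      ses_total = ses$total, ses_group = ses$group,
      stringsAsFactors = FALSE
    )
    write.csv(staging, emit("staging.csv"), row.names = FALSE)
    say("stage", nrow(staging), " participants staged")

    tri <- pipeline_triangulation(passers, staging,
                                  seed = derive_seed(config$seed, 2L))
    jsonlite::write_json(
      if (is.null(tri)) list(available = FALSE) else
        list(available = TRUE, n = tri$n,
             agreement_overall = tri$agreement_overall,
             agreement_by_group = as.list(tri$agreement_by_group)),
      emit("triangulation.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)

    strat_in <- data.frame(
      id = passers$id, stage = staging$stage, sarcf = passers$sarcf,
      adl = passers$adl_independence, fesi = passers$fesi,
      hads = passers$hads, gses = passers$gses, ses_total = ses$total,
      stringsAsFactors = FALSE
    )
    strat <- stratify_cohort(strat_in)
    write.csv(strat, emit("stratification.csv"), row.names = FALSE)
    say("stratify", "grades: ",
        paste(names(table(strat$grade)), table(strat$grade),
              sep = "=", collapse = " "))

    manifest <- list(
      package_version = as.character(packageVersion("sarcostage")),
      seed = config$seed,
      n_total = config$n_total,
      counts = as.list(funnel_counts(funnel)),
      n_staged = nrow(staging),
      n_stratified = nrow(strat),
      files = lapply(
        setNames(nm = sort(basename(written))),
        function(f) unname(tools::md5sum(file.path(out_dir, f)))
      )
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

# Select up to `per_group` staged participants per SES group and compare
# the questionnaire-derived stage with SARC-F- and DXA-derived stages.
pipeline_triangulation <- function(passers, staging, per_group = 5,
                                   seed = NULL) {
  pick <- function(ids) {
    if (length(ids) <= per_group) return(ids)
    sample(ids, per_group)
  }
  choose <- function() {
    ids <- unlist(lapply(c("Low", "Medium", "High"), function(g) {
      pick(staging$id[staging$ses_group == g])
    }))
    if (length(ids) == 0) return(NULL)
    sub <- passers[match(ids, passers$id), ]
    stg <- staging[match(ids, staging$id), ]
    triangulate(data.frame(
      id = ids, ses_group = stg$ses_group, stage_self = stg$stage,
      stage_sarcf = stage_from_sarcf(sub$sarcf),
      stage_dxa = stage_from_dxa(sub$almi, sub$gender),
      stringsAsFactors = FALSE
    ), per_group = per_group, strict = FALSE)
  }
  if (!is.null(seed)) withr::with_seed(seed, choose()) else choose()
}
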