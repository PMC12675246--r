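# Synthetic cohort generator: reproduces the statistical shape the pipeline
# assumes (age-stratified demographics, a graded item-response model on a
# shared latent severity, comorbidity flags, instrument scores, missingness)
# so every downstream stage is testable without survey microdata.

age_band_levels <- function() {
  c("<=30", "31-40", "41-50", "51-60", "61-70", "71-80", ">=81")
}

age_band_ranges <- function() {
  list("<=30" = c(18, 30), "31-40" = c(31, 40), "41-50" = c(41, 50),
       "51-60" = c(51, 60), "61-70" = c(61, 70), "71-80" = c(71, 80),
       ">=81" = c(81, 95))
}

insurance_levels <- function() c("EmpIns", "ResIns", "NRCMS", "StuIns", "NoIns")

# Screening-phase row per age band of the published baseline table.
default_demographics <- function() {
  d <- function(male, n_band, edu_m, edu_s, ins, inc_m, inc_s) {
    list(gender_male = male, education_mean = edu_m, education_sd = edu_s,
         insurance = ins, income_mean = inc_m, income_sd = inc_s,
         n_band = n_band)
  }
  list(
    "<=30"  = d(145 / 281, 281, 13.5, 3.5,
                c(StuIns = 0.65, EmpIns = 0.25, ResIns = 0.10), 2500, 1800),
    "31-40" = d(89 / 171, 171, 14.2, 2.8,
                c(EmpIns = 0.78, ResIns = 0.19, NoIns = 0.03), 12800, 4500),
    "41-50" = d(152 / 274, 274, 12.1, 3.1,
                c(EmpIns = 0.75, ResIns = 0.23, NoIns = 0.02), 11200, 4000),
    "51-60" = d(188 / 344, 344, 10.3, 3.4,
                c(EmpIns = 0.65, ResIns = 0.25, NRCMS = 0.08, NoIns = 0.02),
                8500, 3000),
    "61-70" = d(241 / 447, 447, 8.7, 3.8,
                c(EmpIns = 0.48, ResIns = 0.35, NRCMS = 0.15, NoIns = 0.02),
                5500, 2000),
    "71-80" = d(63 / 103, 103, 6.5, 4.1,
                c(EmpIns = 0.30, ResIns = 0.45, NRCMS = 0.23, NoIns = 0.02),
                3500, 1200),
    ">=81"  = d(24 / 63, 63, 5.1, 4.3,
                c(EmpIns = 0.85, NRCMS = 0.15), 2800, 800)
  )
}

# Confounding-pathology category totals (confirmed, symptomatic-undiagnosed)
# of the published exclusion table, out of the 1,683-person analytic sample.
default_comorbidity_table <- function() {
  data.frame(
    category = exclusion_categories(),
    confirmed = c(380, 126, 76, 66, 39, 43, 11, 15, 9),
    symptomatic = c(95, 35, 15, 14, 7, 0, 10, 2, 7),
    stringsAsFactors = FALSE
  )
}

#' Expected total score at a given latent severity
#'
#' Under the graded item-response model, the probability of scoring at
#' least k on an item is `plogis((theta - tau_k) / s)`; the expected
#' 12-item total is therefore `12 * sum_k plogis((theta - tau_k)/s)`.
#'
#' @param theta latent severity value(s) in `[0, 1]`.
#' @param item_model list with `tau` (increasing thresholds in (0,1)) and
#'   `s` (noise scale).
#' @return Expected total score(s) on the 0-36 scale.
#' @export
expected_total_at_theta <- function(theta, item_model = default_item_model()) {
  vapply(theta, function(th) {
    12 * sum(plogis((th - item_model$tau) / item_model$s))
  }, numeric(1))
}

default_item_model <- function() list(tau = c(0.25, 0.50, 0.75), s = 0.08)

# Solve for the latent severity whose expected total equals `target`.
theta_for_total <- function(target, item_model = default_item_model()) {
  uniroot(function(th) expected_total_at_theta(th, item_model) - target,
          c(1e-6, 1 - 1e-6), tol = 1e-10)$root
}

# Band theta means are solved so the expected total sits at the midpoint of
# each band's score range (4, 12.5, 20.5, 30.5): a banded participant's
# scores then concentrate inside their band rather than at its edges.
default_theta_model <- function(item_model = default_item_model()) {
  midpoints <- c(Healthy = 4, PreSarcopeniaCompensation = 12.5,
                 HighRisk = 20.5, DisablingDegeneration = 30.5)
  list(
    means = vapply(midpoints, theta_for_total, numeric(1),
                   item_model = item_model),
    concentration = 100
  )
}

# Expected total when theta is Beta-distributed with given mean (integrates
# the item model over the Beta density on a fixed grid).
expected_total_for_band <- function(mean, concentration, item_model) {
  th <- seq(1e-4, 1 - 1e-4, length.out = 801)
  dens <- stats::dbeta(th, mean * concentration, (1 - mean) * concentration)
  dens <- dens / sum(dens)
  sum(dens * expected_total_at_theta(th, item_model))
}

# Default latent-band mixture per age band. The 31-40 mixture is solved so
# the expected mean total equals 8.2; the 51-60 mixture is the reported
# tripartite split. Other bands follow the qualitative age-profile
# narrative (all 61-70 above the pre-sarcopenia threshold, and so on).
default_band_mixture <- function(item_model = default_item_model(),
                                 theta_model = default_theta_model(item_model)) {
  bands <- risk_bands()
  mix <- function(p) setNames(p, bands)
  e_h <- expected_total_for_band(theta_model$means[[1]],
                                 theta_model$concentration, item_model)
  e_p <- expected_total_for_band(theta_model$means[[2]],
                                 theta_model$concentration, item_model)
  p_pre <- (8.2 - e_h) / (e_p - e_h)
  if (p_pre < 0 || p_pre > 1) {
    stop_config("cannot calibrate the 31-40 mixture to a mean total of 8.2")
  }
  list(
    "<=30"  = mix(c(1, 0, 0, 0)),
    "31-40" = mix(c(1 - p_pre, p_pre, 0, 0)),
    "41-50" = mix(c(0.55, 0.35, 0.10, 0)),
    "51-60" = mix(c(0.429, 0.286, 0.285, 0)),
    "61-70" = mix(c(0, 0.55, 0.40, 0.05)),
    "71-80" = mix(c(0, 0.10, 0.55, 0.35)),
    ">=81"  = mix(c(0, 0.15, 0.45, 0.40))
  )
}

# Instrument means conditional on latent band (Healthy, PreSarc, HighRisk,
# Disabling), with truncation ranges; ALMI is sex-specific.
default_instrument_model <- function() {
  list(
    sarcf = list(means = c(1, 3, 5, 8), sd = 1.2, range = c(0, 10),
                 digits = 0),
    adl   = list(means = c(100, 90, 70, 45), sd = 8, range = c(0, 100),
                 digits = 0, step = 5),
    fesi  = list(means = c(20, 30, 42, 54), sd = 5, range = c(16, 64),
                 digits = 0),
    hads  = list(means = c(6, 12, 20, 28), sd = 4, range = c(0, 42),
                 digits = 0),
    gses  = list(means = c(34, 28, 22, 16), sd = 4, range = c(10, 40),
                 digits = 0),
    almi  = list(means_male = c(8.2, 7.3, 6.5, 5.5),
                 means_female = c(6.6, 5.8, 5.1, 4.4),
                 sd = 0.35, digits = 2)
  )
}

# Item-level missing rate solved from the participant-level missing-data
# count (45 of 1,728 with at least one of 12 items missing).
default_missing_rate <- function(participants_missing = 45 / 1728) {
  1 - (1 - participants_missing)^(1 / 12)
}

# Category rates scaled so the expected share with any (independent) flag
# equals the published comorbidity-excluded share 950/1683.
default_comorbidity_rates <- function(target_any = 950 / 1683) {
  tab <- default_comorbidity_table()
  total <- tab$confirmed + tab$symptomatic
  p0 <- total / 1683
  f <- uniroot(function(f) 1 - prod(1 - f * p0) - target_any,
               c(0.5, 1 / max(p0) - 1e-6), tol = 1e-12)$root
  data.frame(category = tab$category, rate = f * p0,
             confirmed_share = ifelse(total > 0, tab$confirmed / total, 1),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic cohort
#' generator. All defaults are calibrated to the published study structure:
#' the age-band mix and per-band demographics follow the baseline
#' characteristics table; the 31-40 latent mixture is solved so the
#' expected mean total equals 8.2; the 51-60 mixture is the reported
#' 42.9/28.6/28.5 split; the item-level missing rate implies about 45 of
#' 1,728 participants with a missing item; comorbidity rates are scaled so
#' the expected any-flag share matches 950/1,683.
#'
#' @param n_total number of invited participants (0 allowed).
#' @param seed integer random seed (NULL to use the current RNG state).
#' @param missing_rate item-level missing probability.
#' @param age_band_mix named probability vector over the seven age bands.
#' @param band_mixture named list: per age band, a probability vector over
#'   the four latent risk bands.
#' @param comorbidity data frame with `category`, `rate`,
#'   `confirmed_share`.
#' @param item_model list with `tau` (three increasing thresholds in (0,1))
#'   and `s` (noise scale).
#' @param theta_model list with `means` (per latent band) and
#'   `concentration` of the Beta severity distributions.
#' @param instrument_model per-instrument conditional means and noise SDs.
#' @param demographics per-age-band demographic parameters.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_total = 1728, seed = 1L,
                       missing_rate = default_missing_rate(),
                       age_band_mix = NULL,
                       band_mixture = NULL,
                       comorbidity = default_comorbidity_rates(),
                       item_model = default_item_model(),
                       theta_model = NULL,
                       instrument_model = default_instrument_model(),
                       demographics = default_demographics()) {
  if (is.null(age_band_mix)) {
    n_band <- vapply(demographics, `[[`, numeric(1), "n_band")
    age_band_mix <- setNames(n_band / sum(n_band), names(demographics))
  }
  if (is.null(theta_model)) theta_model <- default_theta_model(item_model)
  if (is.null(band_mixture)) {
    band_mixture <- default_band_mixture(item_model, theta_model)
  }
  config <- structure(list(
    n_total = n_total, seed = seed, missing_rate = missing_rate,
    age_band_mix = age_band_mix, band_mixture = band_mixture,
    comorbidity = comorbidity, item_model = item_model,
    theta_model = theta_model, instrument_model = instrument_model,
    demographics = demographics
  ), class = "sim_config")
  validate_sim_config(config)
}

#' @rdname sim_config
#' @param config a `sim_config` candidate.
#' @export
validate_sim_config <- function(config) {
  if (!is.numeric(config$n_total) || length(config$n_total) != 1 ||
      is.na(config$n_total) || config$n_total < 0 ||
      config$n_total != as.integer(config$n_total)) {
    stop_config("n_total must be a single non-negative integer")
  }
  if (!is.numeric(config$missing_rate) || config$missing_rate < 0 ||
      config$missing_rate > 1) {
    stop_config("missing_rate must be a probability in [0, 1]")
  }
  if (!is_prob_vector(unlist(config$age_band_mix)) ||
      !setequal(names(config$age_band_mix), age_band_levels())) {
    stop_config("age_band_mix must be a probability vector over the seven age bands")
  }
  for (band in names(config$band_mixture)) {
    p <- unlist(config$band_mixture[[band]])
    if (!is_prob_vector(p) || !setequal(names(p), risk_bands())) {
      stop_config(paste0("band_mixture for age band '", band,
                         "' must be a probability vector over the four risk bands"))
    }
  }
  tau <- config$item_model$tau
  if (length(tau) != 3 || is.unsorted(tau, strictly = TRUE) ||
      any(tau <= 0 | tau >= 1)) {
    stop_config("item_model$tau must be three strictly increasing thresholds in (0, 1)")
  }
  if (!is.numeric(config$item_model$s) || any(config$item_model$s <= 0)) {
    stop_config("item_model$s must be a positive noise scale")
  }
  if (any(config$comorbidity$rate < 0 | config$comorbidity$rate > 1)) {
    stop_config("comorbidity rates must be probabilities")
  }
  bad <- setdiff(config$comorbidity$category, exclusion_categories())
  if (length(bad) > 0) {
    stop_config(paste("comorbidity contains unknown categories:",
                      paste(bad, collapse = ", ")))
  }
  th <- config$theta_model
  if (!setequal(names(th$means), risk_bands()) ||
      any(th$means <= 0 | th$means >= 1) || th$concentration <= 0) {
    stop_config("theta_model must give per-band means in (0, 1) and a positive concentration")
  }
  for (band in names(config$demographics)) {
    ins <- config$demographics[[band]]$insurance
    if (!is_prob_vector(ins) ||
        length(setdiff(names(ins), insurance_levels())) > 0) {
      stop_config(paste0("demographics for '", band,
                         "': insurance must be a probability vector over known categories"))
    }
  }
  config
}

# Graded item draw: one uniform per item; score = number of thresholds whose
# cumulative exceedance probability the uniform falls below. Monotone in
# theta for a fixed uniform draw.
draw_items <- function(theta, item_model) {
  n <- length(theta)
  items <- matrix(0L, n, 12)
  for (j in 1:12) {
    u <- runif(n)
    score <- integer(n)
    for (k in 1:3) {
      score <- score +
        as.integer(u < plogis((theta - item_model$tau[k]) / item_model$s))
    }
    items[, j] <- score
  }
  colnames(items) <- paste0("item_", 1:12)
  items
}

draw_instrument <- function(spec, band_idx) {
  x <- rtruncnorm(length(band_idx), spec$means[band_idx], spec$sd,
                  spec$range[1], spec$range[2])
  if (!is.null(spec$step)) {
    x <- pmin(pmax(round(x / spec$step) * spec$step, spec$range[1]),
              spec$range[2])
  } else {
    x <- round(x, spec$digits)
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws `n_total` participants: an age band, demographics conditional on
#' the band, a latent risk band from the band's mixture, a latent severity
#' from the band's Beta distribution, 12 graded item responses, clinical
#' instrument scores conditional on the latent band, independent
#' comorbidity flags, SES bands, and item-level missingness. Identical
#' configuration (including seed) yields an identical cohort.
#'
#' @param config a [sim_config()].
#' @return Data frame of class `sarco_cohort`, one row per participant,
#'   with the configuration attached as attribute `sim_config`.
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  if (!is.null(config$seed)) {
    return(withr::with_seed(config$seed, generate_cohort_impl(config)))
  }
  generate_cohort_impl(config)
}

generate_cohort_impl <- function(config) {
  n <- config$n_total
  empty <- data.frame(
    id = integer(), age_years = integer(), age_band = character(),
    gender = character(), education_years = numeric(),
    insurance = character(), monthly_income_cny = numeric(),
    comorbidities = character(), stringsAsFactors = FALSE
  )
  if (n == 0) {
    items <- matrix(integer(), 0, 12,
                    dimnames = list(NULL, paste0("item_", 1:12)))
    out <- cbind(empty, as.data.frame(items))
    attr(out, "sim_config") <- config
    class(out) <- c("sarco_cohort", "data.frame")
    return(out)
  }

  bands <- sample(age_band_levels(), n, replace = TRUE,
                  prob = config$age_band_mix[age_band_levels()])

  age <- integer(n)
  gender <- character(n)
  education <- numeric(n)
  insurance <- character(n)
  income <- numeric(n)
  latent_band <- character(n)
  for (b in age_band_levels()) {
    idx <- which(bands == b)
    if (length(idx) == 0) next
    dem <- config$demographics[[b]]
    rng <- age_band_ranges()[[b]]
    age[idx] <- sample(rng[1]:rng[2], length(idx), replace = TRUE)
    gender[idx] <- ifelse(runif(length(idx)) < dem$gender_male,
                          "male", "female")
    education[idx] <- round(rtruncnorm(length(idx), dem$education_mean,
                                       dem$education_sd, 0, 22))
    insurance[idx] <- sample(names(dem$insurance), length(idx),
                             replace = TRUE, prob = dem$insurance)
    income[idx] <- round(rtruncnorm(length(idx), dem$income_mean,
                                    dem$income_sd, 0, Inf) / 50) * 50
    mixture <- config$band_mixture[[b]][risk_bands()]
    latent_band[idx] <- sample(risk_bands(), length(idx), replace = TRUE,
                               prob = mixture)
  }

  band_idx <- match(latent_band, risk_bands())
  th <- config$theta_model
  theta <- rbeta(n, th$means[band_idx] * th$concentration,
                 (1 - th$means[band_idx]) * th$concentration)

  items <- draw_items(theta, config$item_model)
  if (config$missing_rate > 0) {
    mask <- matrix(runif(n * 12) < config$missing_rate, n, 12)
    items[mask] <- NA_integer_
  }

  com <- config$comorbidity
  flags <- character(n)
  for (ci in seq_len(nrow(com))) {
    hit <- runif(n) < com$rate[ci]
    if (!any(hit)) next
    status <- ifelse(runif(sum(hit)) < com$confirmed_share[ci],
                     "confirmed", "symptomatic_undiagnosed")
    piece <- paste(com$category[ci], status, sep = "/")
    flags[hit] <- ifelse(nzchar(flags[hit]),
                         paste(flags[hit], piece, sep = ";"), piece)
  }

  inst <- config$instrument_model
  sarcf <- draw_instrument(inst$sarcf, band_idx)
  adl <- draw_instrument(inst$adl, band_idx)
  fesi <- draw_instrument(inst$fesi, band_idx)
  hads <- draw_instrument(inst$hads, band_idx)
  gses <- draw_instrument(inst$gses, band_idx)
  almi_mean <- ifelse(gender == "male",
                      inst$almi$means_male[band_idx],
                      inst$almi$means_female[band_idx])
  almi <- round(rtruncnorm(n, almi_mean, inst$almi$sd, 1, Inf),
                inst$almi$digits)

  ses_income <- findInterval(income, c(4000, 9000)) + 1L
  ses_education <- findInterval(education, c(6.5, 12.5)) + 1L
  shift <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  ses_occupation <- pmin(pmax(ses_education + shift, 1L), 3L)

  out <- data.frame(
    id = seq_len(n), age_years = age, age_band = bands, gender = gender,
    education_years = education, insurance = insurance,
    monthly_income_cny = income, comorbidities = flags,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(items))
  out$sarcf <- sarcf
  out$adl_independence <- adl
  out$fesi <- fesi
  out$hads <- hads
  out$gses <- gses
  out$almi <- almi
  out$ses_income_band <- ses_income
  out$ses_education_band <- ses_education
  out$ses_occupation_band <- ses_occupation
  out$latent_severity <- theta
  out$latent_band <- latent_band
  attr(out, "sim_config") <- config
  class(out) <- c("sarco_cohort", "data.frame")
  out
}

#' Calibration report for a synthetic cohort
#'
#' Summarizes, per age band, the mean observed total score (complete
#' responders), the latent band mixture, and the comorbidity prevalence.
#' Requires generator ground truth, so it refuses non-synthetic cohorts.
#'
#' @param cohort a cohort with latent fields (`latent_band`,
#'   `latent_severity`).
#' @return Data frame, one row per age band present in the cohort.
#' @export
calibration_report <- function(cohort) {
  if (!all(c("latent_band", "latent_severity") %in% names(cohort))) {
    stop_validation("calibration_report needs a synthetic cohort with latent fields")
  }
  totals <- rowSums(cohort_items(cohort))
  split_idx <- split(seq_len(nrow(cohort)),
                     factor(cohort$age_band, levels = age_band_levels()))
  rows <- lapply(names(split_idx), function(b) {
    idx <- split_idx[[b]]
    if (length(idx) == 0) return(NULL)
    shares <- prop.table(table(factor(cohort$latent_band[idx],
                                      levels = risk_bands())))
    data.frame(
      age_band = b, n = length(idx),
      mean_total = mean(totals[idx], na.rm = TRUE),
      share_healthy = shares[[1]], share_presarc = shares[[2]],
      share_highrisk = shares[[3]], share_disabling = shares[[4]],
      comorbidity_prev = mean(nzchar(cohort$comorbidities[idx])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write / read a cohort CSV with its configuration sidecar
#'
#' The cohort is written as plain CSV (missing items as empty cells); the
#' generating configuration is stored next to it as `<path>.config.json`
#' and re-attached on read when present.
#'
#' @param cohort a cohort data frame.
#' @param path CSV file path.
#' @return `write_cohort()`: `path`, invisibly. `read_cohort()`: the cohort
#'   data frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  config <- attr(cohort, "sim_config")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(comorbidities = "character"))
  out$comorbidities[is.na(out$comorbidities)] <- ""
  class(out) <- c("sarco_cohort", "data.frame")
  sidecar <- paste0(path, ".config.json")
  if (file.exists(sidecar)) {
    attr(out, "sim_config") <- jsonlite::read_json(sidecar,
                                                   simplifyVector = TRUE)
  }
  out
}
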