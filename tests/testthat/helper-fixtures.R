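# Fixtures built in code: small cohorts and matrices used across tests.

band_names <- function() {
  c("<=30", "31-40", "41-50", "51-60", "61-70", "71-80", ">=81")
}

single_band_mix <- function(band) {
  setNames(as.numeric(band_names() == band), band_names())
}

# Minimal cohort data frame from an item-response matrix.
cohort_from_items <- function(items, comorbidities = NULL) {
  items <- as.matrix(items)
  colnames(items) <- paste0("item_", 1:12)
  out <- data.frame(id = seq_len(nrow(items)), items)
  out$comorbidities <- if (is.null(comorbidities)) "" else comorbidities
  out
}

# Cohort with exactly the published screening-funnel marginals:
# 1,728 surveyed; 45 with a missing item; 950 comorbid (category and
# diagnostic-status counts as printed); 83 of the remainder below the
# 9-point threshold; 650 passing.
published_funnel_cohort <- function() {
  counts <- data.frame(
    category = exclusion_categories(),
    confirmed = c(380, 126, 76, 66, 39, 43, 11, 15, 9),
    symptomatic = c(95, 35, 15, 14, 7, 0, 10, 2, 7)
  )
  items <- matrix(1L, 1728, 12)
  items[1:45, 1] <- NA_integer_              # 45 missing-data exclusions
  items[996:1078, ] <- 0L                    # 83 below-threshold (total 0)
  flags <- rep("", 1728)
  labels <- unlist(lapply(seq_len(nrow(counts)), function(i) {
    c(rep(paste0(counts$category[i], "/confirmed"), counts$confirmed[i]),
      rep(paste0(counts$category[i], "/symptomatic_undiagnosed"),
          counts$symptomatic[i]))
  }))
  stopifnot(length(labels) == 950)
  flags[46:995] <- labels
  cohort_from_items(items, flags)
}

# Data whose sample correlation matrix is exactly the identity: Helmert
# contrast columns are integer, mean-zero and mutually orthogonal.
orthogonal_items <- function(k = 5) {
  stats::contr.helmert(k + 1)
}

# Single-common-factor item data (loading `loading` on a shared factor).
one_factor_items <- function(n = 500, k = 12, loading = 0.9, seed = 42) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    sapply(seq_len(k), function(j) {
      loading * f + sqrt(1 - loading^2) * rnorm(n)
    })
  })
}

# Seeded random reciprocal judgment matrix of order n.
random_reciprocal <- function(n, seed) {
  withr::with_seed(seed, {
    m <- diag(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- exp(rnorm(1, sd = 0.8))
      m[j, i] <- 1 / m[i, j]
    }
    m
  })
}

# A consistent matrix a_ij = w_i / w_j has priority vector w exactly.
consistent_matrix <- function(w) outer(w, w, `/`)

full_ratings <- function(value = 1L) {
  setNames(rep(as.integer(value), 14), leaf_indicators()$leaf)
}

best_instruments <- function() {
  list(sarcf = 0, adl = 100, fesi = 16, hads = 0, gses = 40, ses_total = 9)
}

worst_instruments <- function() {
  list(sarcf = 10, adl = 0, fesi = 64, hads = 42, gses = 10, ses_total = 3)
}
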