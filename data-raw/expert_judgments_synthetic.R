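# Build synthetic expert judgment matrices: snap consistent ratios of the
# published-structure local weights to the Saaty scale, perturb per expert.
library(sarcostage)

saaty <- c(1/(9:2), 1:9)
snap <- function(r, shift = 0) {
  i <- which.min(abs(log(saaty) - log(r)))
  saaty[max(1, min(length(saaty), i + shift))]
}

make_matrix <- function(w, expert) {
  n <- length(w)
  m <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # deterministic mild disagreement pattern per expert; lighter for
    # small matrices where one Saaty step moves CR more
    shift <- if (n <= 3) {
      switch(expert, `1` = 0,
             `2` = as.integer(i == 1 && j == 2),
             `3` = -as.integer(i == 2 && j == 3))
    } else {
      switch(expert, `1` = 0, `2` = (i + j) %% 2, `3` = -((i + j + 1) %% 2))
    }
    m[i, j] <- snap(w[i] / w[j], shift)
    m[j, i] <- 1 / m[i, j]
  }
  m
}

loc <- canonical_local_weights()
levels <- list(
  dimensions    = list(labels = c("physiological", "psychological", "external"),
                       w = c(0.70, 0.20, 0.10)),
  physiological = list(labels = c("musculoskeletal_deterioration", "activity_radius", "self_care"),
                       w = c(loc$physiological[["musculoskeletal_deterioration"]],
                             loc$physiological[["activity_radius"]],
                             sum(loc$physiological[3:9]))),
  self_care     = list(labels = names(loc$physiological)[3:9],
                       w = unname(loc$physiological[3:9])),
  psychological = list(labels = names(loc$psychological), w = unname(loc$psychological)),
  external      = list(labels = names(loc$external), w = unname(loc$external))
)

out <- list(levels = list(), note = paste(
  "SYNTHETIC fixture data: pairwise-comparison matrices constructed from the",
  "published weight structure as stand-ins for the study's expert panel",
  "judgments, which are not publicly deposited. Not survey data."))
for (nm in names(levels)) {
  lv <- levels[[nm]]
  experts <- lapply(1:3, function(e) make_matrix(lv$w, as.character(e)))
  crs <- sapply(experts, consistency_ratio)
  agg <- ahp_aggregate(experts)
  pr <- ahp_priority(agg)
  cat(sprintf("%-14s expert CRs: %s | agg CR %.4f | weights %s\n", nm,
              paste(sprintf("%.4f", crs), collapse = " "), pr$cr,
              paste(sprintf("%.3f", pr$weights), collapse = " ")))
  out$levels[[nm]] <- list(labels = lv$labels, experts = experts)
}
jsonlite::write_json(out, "inst/extdata/expert_judgments_synthetic.json",
                     digits = NA, auto_unbox = TRUE, pretty = TRUE)
cat("written\n")
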