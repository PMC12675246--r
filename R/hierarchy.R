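# Indicator hierarchy: three primary dimensions, secondary indicators, and
# the seven self-care tertiary leaves; local weights compose down each path.

#' Build an indicator hierarchy
#'
#' A hierarchy is a nested list of nodes; each node has a `name`, and either
#' no `children` (a leaf) or a list of child nodes. Sibling local weights
#' come either from an explicit `local_weight` on every child, or from a
#' `judgment_matrix` on the parent (priorities derived with
#' [ahp_priority()], rows matched to children in order). Can also read the
#' same structure from a JSON or YAML file.
#'
#' @param x a nested list, or path to a JSON/YAML file encoding one.
#' @return The hierarchy with derived local weights filled in, class
#'   `sarco_hierarchy`.
#' @export
ahp_hierarchy <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- if (grepl("\\.ya?ml$", x)) {
      yaml::read_yaml(x)
    } else {
      jsonlite::read_json(x, simplifyVector = FALSE)
    }
  }
  if (is.null(x$name)) stop_validation("hierarchy root must have a name")
  structure(resolve_node(x), class = "sarco_hierarchy")
}

resolve_node <- function(node) {
  if (is.null(node$children) || length(node$children) == 0) return(node)
  kids <- node$children
  if (!is.null(node$judgment_matrix)) {
    m <- do.call(rbind, lapply(node$judgment_matrix, unlist))
    if (nrow(m) != length(kids)) {
      stop_validation(paste0("node '", node$name, "': judgment matrix order ",
                             nrow(m), " does not match ", length(kids),
                             " children"))
    }
    w <- ahp_priority(ahp_matrix(m))$weights
    for (i in seq_along(kids)) kids[[i]]$local_weight <- unname(w[i])
  }
  locals <- vapply(kids, function(k) {
    if (is.null(k$local_weight)) NA_real_ else as.numeric(k$local_weight)
  }, numeric(1))
  if (anyNA(locals)) {
    stop_validation(paste0("node '", node$name,
                           "': every child needs a local_weight or the node a judgment_matrix"))
  }
  if (abs(sum(locals) - 1) > 1e-9) {
    stop_validation(paste0("node '", node$name, "': sibling local weights sum to ",
                           format(sum(locals)), ", expected 1"))
  }
  node$children <- lapply(kids, resolve_node)
  node
}

#' Compose within-dimension leaf weights
#'
#' For each leaf under each primary dimension, multiplies the local weights
#' along the path below the dimension node. Leaf weights within each
#' dimension sum to 1.
#'
#' @param h a `sarco_hierarchy` (the root's children are the dimensions).
#' @return Data frame with columns `dimension`, `leaf`, `weight`.
#' @export
compose_hierarchy <- function(h) {
  if (!inherits(h, "sarco_hierarchy")) h <- ahp_hierarchy(h)
  rows <- list()
  walk <- function(node, dimension, acc) {
    if (is.null(node$children) || length(node$children) == 0) {
      rows[[length(rows) + 1]] <<- data.frame(
        dimension = dimension, leaf = node$name, weight = acc,
        stringsAsFactors = FALSE)
      return(invisible())
    }
    for (k in node$children) walk(k, dimension, acc * k$local_weight)
  }
  for (dim_node in h$children) walk(dim_node, dim_node$name, 1)
  do.call(rbind, rows)
}

#' Load the synthetic expert judgment fixtures
#'
#' Reads the repository's fixture pairwise-comparison matrices (synthetic
#' stand-ins for the study's unavailable expert panel, constructed from the
#' published weight structure and labelled as such). One entry per hierarchy
#' level, each holding the sibling labels and one matrix per expert.
#'
#' @param path JSON file; defaults to the fixture shipped with the package.
#' @return Named list of levels, each with `labels` and `experts` (list of
#'   numeric matrices).
#' @export
load_expert_judgments <- function(path = system.file("extdata",
                                                     "expert_judgments_synthetic.json",
                                                     package = "sarcostage")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw$levels, function(lv) {
    experts <- lapply(seq_len(dim(lv$experts)[1]), function(i) {
      m <- lv$experts[i, , ]
      dimnames(m) <- list(lv$labels, lv$labels)
      m
    })
    list(labels = lv$labels, experts = experts)
  })
}

#' Aggregate the expert fixtures into per-level priorities
#'
#' For each hierarchy level, aggregates the expert matrices by geometric
#' mean and derives the priority vector and consistency ratio.
#'
#' @param judgments as returned by [load_expert_judgments()].
#' @return Named list per level with `weights`, `cr`, `cr_experts` (per-
#'   expert CRs), `aggregate` (the aggregated matrix).
#' @export
aggregate_expert_levels <- function(judgments = load_expert_judgments()) {
  lapply(judgments, function(lv) {
    agg <- ahp_aggregate(lv$experts)
    pr <- ahp_priority(agg)
    list(weights = pr$weights, cr = pr$cr,
         cr_experts = vapply(lv$experts, consistency_ratio, numeric(1)),
         aggregate = agg)
  })
}
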