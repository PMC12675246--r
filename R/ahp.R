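# Analytic Hierarchy Process core: reciprocal judgment matrices, principal-
# eigenvector priorities, consistency diagnostics, and expert aggregation.

#' Saaty random consistency index
#'
#' The standard random-index table used to scale the consistency index into
#' the consistency ratio, for matrix orders 1..10.
#'
#' @return Numeric vector `RI[n]` for n = 1..10.
#' @export
saaty_random_index <- function() {
  c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
}

#' Validate a pairwise-comparison judgment matrix
#'
#' Checks that the matrix is square with order 2..10, strictly positive,
#' has a unit diagonal, and is reciprocal (`a_ji = 1/a_ij`) within a
#' relative tolerance.
#'
#' @param m numeric matrix.
#' @param tol relative reciprocity tolerance (default 1e-9).
#' @return The matrix with class `judgment_matrix`.
#' @export
#' @examples
#' ahp_matrix(matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1), 3, byrow = TRUE))
ahp_matrix <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != ncol(m)) {
    stop_validation("judgment matrix must be a square numeric matrix")
  }
  n <- nrow(m)
  if (n < 2 || n > 10) {
    stop_validation(paste0("judgment matrix order must be 2..10, got ", n))
  }
  if (anyNA(m) || any(m <= 0)) {
    bad <- which(is.na(m) | m <= 0, arr.ind = TRUE)[1, ]
    stop_validation(paste0("entry [", bad[1], ",", bad[2],
                           "] must be a positive number"))
  }
  if (any(abs(diag(m) - 1) > tol)) {
    i <- which(abs(diag(m) - 1) > tol)[1]
    stop_validation(paste0("diagonal entry [", i, ",", i, "] must equal 1"))
  }
  recip_err <- abs(m * t(m) - 1)
  if (any(recip_err > tol)) {
    bad <- which(recip_err > tol, arr.ind = TRUE)[1, ]
    stop_validation(paste0("reciprocity violated at [", bad[1], ",", bad[2],
                           "]: a_ji must equal 1/a_ij"))
  }
  structure(m, class = c("judgment_matrix", "matrix", "array"))
}

#' Priority vector and consistency diagnostics
#'
#' Derives the principal right eigenvector of a reciprocal judgment matrix
#' by power iteration, normalized to sum 1, along with the principal
#' eigenvalue `lambda_max`, the consistency index
#' `CI = (lambda_max - n)/(n - 1)` (defined 0 for n <= 2) and the
#' consistency ratio `CR = CI / RI(n)` (0 when `RI(n) = 0`). A CR below 0.1
#' is conventionally acceptable.
#'
#' @param m judgment matrix (validated with [ahp_matrix()] if not already).
#' @param tol convergence tolerance on the max relative change of the
#'   weight vector (default 1e-12).
#' @param max_iter maximum power iterations (default 10000).
#' @return List of class `ahp_priority`: `weights`, `lambda_max`, `ci`,
#'   `cr`, `iterations`.
#' @export
ahp_priority <- function(m, tol = 1e-12, max_iter = 10000) {
  if (!inherits(m, "judgment_matrix")) m <- ahp_matrix(m)
  n <- nrow(m)
  w <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    v <- as.vector(m %*% w)
    w_new <- v / sum(v)
    delta <- max(abs(w_new - w) / pmax(w_new, .Machine$double.eps))
    w <- w_new
    if (delta < tol) break
    if (iter >= max_iter) {
      stop_sarco(paste0("power iteration did not converge in ", max_iter,
                        " iterations (residual ", format(delta), ")"),
                 "sarcostage_convergence_error")
    }
  }
  lambda <- mean(as.vector(m %*% w) / w)
  ci <- if (n <= 2) 0 else (lambda - n) / (n - 1)
  ri <- saaty_random_index()[n]
  cr <- if (ri == 0) 0 else ci / ri
  structure(list(
    weights = setNames(w, rownames(m)),
    lambda_max = lambda, ci = ci, cr = cr, iterations = iter
  ), class = "ahp_priority")
}

#' @export
print.ahp_priority <- function(x, ...) {
  cat("AHP priorities (lambda_max =", format(x$lambda_max, digits = 6),
      ", CR =", format(x$cr, digits = 4), "):\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Aggregate expert judgment matrices by geometric mean
#'
#' Entry-wise geometric mean of one or more reciprocal matrices of equal
#' order; the aggregate is reciprocal by construction.
#'
#' @param matrices list of judgment matrices (validated individually).
#' @return Aggregated `judgment_matrix`.
#' @export
ahp_aggregate <- function(matrices) {
  if (length(matrices) < 1) stop_validation("need at least one matrix")
  matrices <- lapply(matrices, ahp_matrix)
  orders <- vapply(matrices, nrow, integer(1))
  if (length(unique(orders)) != 1) {
    stop_validation("all expert matrices must have the same order")
  }
  logs <- Reduce(`+`, lapply(matrices, log))
  ahp_matrix(exp(logs / length(matrices)))
}

#' Consistency ratio of a judgment matrix
#'
#' Convenience accessor for `ahp_priority(m)$cr`.
#'
#' @inheritParams ahp_priority
#' @return Numeric scalar CR.
#' @export
consistency_ratio <- function(m) ahp_priority(m)$cr
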