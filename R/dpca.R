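# Differential PCA: SVD decomposition of the between-condition difference
# matrix D = B V + E, and element scores from the leading components.

#' Differential principal component analysis of a difference matrix
#'
#' Decomposes the G x M difference matrix `D` (elements by marks) by
#' singular value decomposition into element coordinates `B = U S` (G x R)
#' and mark loadings `V` (R x M, orthonormal rows), with R = min(G, M).
#' Each component captures one pattern of coordinated between-condition
#' change across marks; `variance_explained[r]` is the share of squared
#' Frobenius norm carried by component r.
#'
#' Component signs are stabilized so that the largest-magnitude loading of
#' every component is positive; downstream scores use absolute values and
#' are sign-agnostic regardless.
#'
#' @param D Numeric matrix of between-condition mean differences
#'   ([difference_matrix()]); G >= 2 rows.
#' @param center Column-center D before decomposing (default `FALSE`: rows
#'   of D are already differences, and magnitude itself is the signal).
#' @param k Number of components retained for the residual `E = D - B_k V_k`
#'   (default `min(2, R)`).
#' @return Object of class `dpca_result` with components `B`, `V`,
#'   `singular_values`, `variance_explained`, `residual`, `k`,
#'   `element_ids`, `marks`.
#' @export
dpca <- function(D, center = FALSE, k = NULL) {
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop("non-finite entries in difference matrix",
                               call. = FALSE)
  if (nrow(D) < 2L) stop("need at least 2 elements", call. = FALSE)
  if (is.null(rownames(D))) rownames(D) <- as.character(seq_len(nrow(D)))
  if (is.null(colnames(D))) colnames(D) <- paste0("mark", seq_len(ncol(D)))
  Dc <- if (center) scale(D, center = TRUE, scale = FALSE) else D
  s <- svd(Dc)
  R <- length(s$d)
  B <- s$u %*% diag(s$d, R, R)
  V <- t(s$v)
  for (r in seq_len(R)) {
    j <- which.max(abs(V[r, ]))
    if (V[r, j] < 0) {
      V[r, ] <- -V[r, ]
      B[, r] <- -B[, r]
    }
  }
  tot <- sum(s$d^2)
  if (tot > 0) {
    ve <- s$d^2 / tot
  } else {
    warning("all-zero difference matrix: variance explained reported as 0")
    ve <- rep(0, R)
  }
  if (is.null(k)) k <- min(2L, R)
  stopifnot(k >= 1L, k <= R)
  comp <- paste0("dPC", seq_len(R))
  dimnames(B) <- list(rownames(D), comp)
  dimnames(V) <- list(comp, colnames(D))
  structure(list(
    B = B, V = V,
    singular_values = s$d,
    variance_explained = ve,
    residual = D - B[, seq_len(k), drop = FALSE] %*%
      V[seq_len(k), , drop = FALSE],
    k = k,
    element_ids = rownames(D),
    marks = colnames(D)), class = "dpca_result")
}

#' @export
print.dpca_result <- function(x, ...) {
  cat(sprintf("dpca_result: %d elements, %d marks, %d components\n",
              nrow(x$B), length(x$marks), length(x$singular_values)))
  cat("variance explained:",
      paste(sprintf("%.3f", x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Element scores from the leading differential components
#'
#' The score of element g is the sum of absolute coordinates along the
#' first `k` components, `sum_r |B[g, r]|`. With the default `k = 2` this
#' captures coordinated change of both activating and repressive marks,
#' which typically separate onto the first two components.
#'
#' @param result A [dpca()] result.
#' @param k Number of components summed (default 2).
#' @return Named nonnegative numeric vector, one score per element.
#' @export
element_scores <- function(result, k = 2L) {
  stopifnot(inherits(result, "dpca_result"))
  R <- length(result$singular_values)
  if (k < 1L || k > R) stop("k must be between 1 and ", R, call. = FALSE)
  rowSums(abs(result$B[, seq_len(k), drop = FALSE]))
}

#' Tabulate component loadings over marks
#'
#' Long-format table for inspecting whether activating and repressive marks
#' separate onto distinct components.
#'
#' @param result A [dpca()] result.
#' @return Data frame with columns `component`, `mark`, `loading`,
#'   `variance_explained`.
#' @export
loadings_report <- function(result) {
  stopifnot(inherits(result, "dpca_result"))
  R <- nrow(result$V)
  M <- ncol(result$V)
  data.frame(
    component = rep(rownames(result$V), times = M),
    mark = rep(colnames(result$V), each = R),
    loading = as.vector(result$V),
    variance_explained = rep(result$variance_explained, times = M),
    stringsAsFactors = FALSE)
}
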