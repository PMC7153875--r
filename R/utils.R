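#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed report values here use
#' the conventional half-up rule instead. Internal computations always keep
#' full precision -- this is applied only when a number is formatted for a
#' report.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# All unordered dyads of a universe, in row-major upper-triangle order.
# Returns a 2-column character matrix (i < j by universe position).
dyad_pairs <- function(universe) {
  n <- length(universe)
  if (n < 2) stop("universe must contain at least 2 individuals", call. = FALSE)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cbind(universe[idx[, 1]], universe[idx[, 2]])
}

# Sum over the strict upper triangle of a square matrix.
upper_sum <- function(m) sum(m[upper.tri(m)])

# Validate a symmetric nonnegative zero-diagonal matrix with dimnames.
check_dyadic_matrix <- function(m, what = "matrix", tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop(what, " must have identical row and column names", call. = FALSE)
  if (any(!is.finite(m))) stop(what, " contains non-finite values", call. = FALSE)
  if (max(abs(m - t(m))) > tol) stop(what, " is not symmetric", call. = FALSE)
  if (any(diag(m) != 0)) stop(what, " must have a zero diagonal", call. = FALSE)
  if (any(m < 0)) stop(what, " contains negative values", call. = FALSE)
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
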