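#' Normalized dyadic index
#'
#' Divides each dyadic total by the grand total over all dyads for that
#' interaction type, so the weights over unordered dyads sum to 1. Puts
#' every interaction layer on the same scale regardless of how common the
#' behaviour is (grooming seconds vs rare agonism episodes).
#'
#' @param totals a `dyadic_totals` object with at least one positive total.
#' @return a `dyadic_index` object: list with `type`, `universe`, and the
#'   symmetric `weights` matrix summing to 1 over unordered dyads.
#' @export
dyadic_index <- function(totals) {
  m <- totals$matrix
  g <- upper_sum(m)
  if (g <= 0)
    stop("all dyadic totals are zero: index undefined for type '",
         totals$type, "'", call. = FALSE)
  structure(list(type = totals$type, universe = totals$universe,
                 weights = m / g),
            class = "dyadic_index")
}

#' Construct a dyadic index from a weight matrix
#'
#' @param m symmetric nonnegative matrix with ids as dimnames, zero
#'   diagonal, summing to 1 over unordered dyads (checked to 1e-8).
#' @param type interaction class label.
#' @return a `dyadic_index` object.
#' @export
as_dyadic_index <- function(m, type = "layer") {
  check_dyadic_matrix(m, "dyadic index")
  s <- upper_sum(m)
  if (abs(s - 1) > 1e-8)
    stop("dyadic index must sum to 1 over unordered dyads (got ", s, ")",
         call. = FALSE)
  structure(list(type = type, universe = rownames(m), weights = m),
            class = "dyadic_index")
}

#' @export
print.dyadic_index <- function(x, ...) {
  cat(sprintf("Dyadic index (%s): %d individuals, %d nonzero dyads, sum %.12f\n",
              x$type, length(x$universe),
              sum(x$weights[upper.tri(x$weights)] > 0),
              upper_sum(x$weights)))
  invisible(x)
}

#' Restrict totals or an index to a subset of individuals
#'
#' Drops the removed individuals and every dyad involving them from the
#' underlying totals. For a `dyadic_index` the reduced matrix is
#' re-normalized so it again sums to 1 -- the convention used when an
#' individual absent from one observation period is excluded and the
#' indices are recalculated without her.
#'
#' @param x a `dyadic_totals` or `dyadic_index` object.
#' @param keep character vector of ids to keep (subset of the universe,
#'   at least 2).
#' @return an object of the same class over the reduced universe.
#' @export
restrict_universe <- function(x, keep) UseMethod("restrict_universe")

restrict_matrix <- function(m, universe, keep) {
  if (!all(keep %in% universe))
    stop("keep contains ids outside the universe: ",
         paste(setdiff(keep, universe), collapse = ", "), call. = FALSE)
  if (length(keep) < 2)
    stop("restriction must keep at least 2 individuals", call. = FALSE)
  keep <- universe[universe %in% keep]  # preserve universe order
  m[keep, keep, drop = FALSE]
}

#' @export
restrict_universe.dyadic_totals <- function(x, keep) {
  m <- restrict_matrix(x$matrix, x$universe, keep)
  structure(list(type = x$type, universe = rownames(m), matrix = m),
            class = "dyadic_totals")
}

#' @export
restrict_universe.dyadic_index <- function(x, keep) {
  m <- restrict_matrix(x$weights, x$universe, keep)
  g <- upper_sum(m)
  if (g <= 0)
    stop("restriction leaves zero total interaction mass", call. = FALSE)
  structure(list(type = x$type, universe = rownames(m), weights = m / g),
            class = "dyadic_index")
}
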