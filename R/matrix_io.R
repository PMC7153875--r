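#' Read a symmetric dyadic matrix from CSV
#'
#' Dialect: square CSV with individual ids as the first row and first
#' column, symmetric values, zero diagonal.
#'
#' @param path path to the CSV file.
#' @return numeric matrix with ids as dimnames.
#' @export
read_dyadic_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  check_dyadic_matrix(m, paste0("matrix in ", basename(path)))
  m
}

#' Write a symmetric dyadic matrix to CSV
#'
#' @param m matrix with ids as dimnames (a `dyadic_totals` or
#'   `dyadic_index` object is also accepted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dyadic_matrix <- function(m, path) {
  if (inherits(m, "dyadic_totals")) m <- m$matrix
  if (inherits(m, "dyadic_index")) m <- m$weights
  df <- as.data.frame(m)
  utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
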