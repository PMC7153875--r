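#' Export a multiplex as an extended edge list
#'
#' MuxViz-compatible plain-text export: whitespace-separated lines
#' `node layer node layer weight` with 1-based indices, plus a node map
#' (`<prefix>_nodes.txt`: `node_index individual_id`) and a layer map
#' (`<prefix>_layers.txt`: `layer_index label`). Only intra-layer edges are
#' written; interlayer coupling is implied by the multiplex convention.
#'
#' @param net a `multiplex` object.
#' @param path_prefix files `<prefix>_edges.txt`, `<prefix>_nodes.txt`,
#'   `<prefix>_layers.txt` are written.
#' @return invisible character vector of the three paths.
#' @export
export_edge_list <- function(net, path_prefix) {
  u <- net$universe
  labs <- names(net$layers)
  lines <- character(0)
  for (l in seq_along(labs)) {
    m <- net$layers[[l]]
    idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      lines <- c(lines, sprintf("%d %d %d %d %.17g",
                                idx[, 1], l, idx[, 2], l,
                                m[idx]))
    }
  }
  paths <- paste0(path_prefix, c("_edges.txt", "_nodes.txt", "_layers.txt"))
  writeLines(lines, paths[1])
  writeLines(sprintf("%d %s", seq_along(u), u), paths[2])
  writeLines(sprintf("%d %s", seq_along(labs), labs), paths[3])
  invisible(paths)
}

#' Read a multiplex from an extended edge list
#'
#' Inverse of [export_edge_list()]; weights are restored exactly (they are
#' written with 17 significant digits).
#'
#' @param path_prefix prefix used at export time.
#' @param omega interlayer coupling weight of the rebuilt network.
#' @param couple_all presence-independent coupling flag.
#' @return a `multiplex` object.
#' @export
read_edge_list <- function(path_prefix, omega = 1, couple_all = FALSE) {
  paths <- paste0(path_prefix, c("_edges.txt", "_nodes.txt", "_layers.txt"))
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  nodes <- utils::read.table(paths[2], col.names = c("idx", "id"),
                             colClasses = c("integer", "character"))
  layers <- utils::read.table(paths[3], col.names = c("idx", "label"),
                              colClasses = c("integer", "character"))
  u <- nodes$id[order(nodes$idx)]
  labs <- layers$label[order(layers$idx)]
  n <- length(u)
  mats <- lapply(labs, function(l) {
    m <- matrix(0, n, n, dimnames = list(u, u)); m
  })
  names(mats) <- labs
  if (file.size(paths[1]) > 0) {
    e <- utils::read.table(paths[1],
                           col.names = c("n1", "l1", "n2", "l2", "w"))
    if (any(e$l1 != e$l2))
      stop("interlayer edges are not supported in this edge list",
           call. = FALSE)
    for (k in seq_len(nrow(e))) {
      l <- e$l1[k]
      mats[[l]][e$n1[k], e$n2[k]] <- e$w[k]
      mats[[l]][e$n2[k], e$n1[k]] <- e$w[k]
    }
  }
  build_multiplex(mats, labels = labs, omega = omega, couple_all = couple_all)
}
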