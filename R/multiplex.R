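#' Build a node-aligned multiplex network
#'
#' Assembles one weighted undirected multiplex network from a set of dyadic
#' index matrices (one per interaction type, or one per observation period).
#' All layers must share the same ordered universe; individuals with no
#' interactions in a layer remain in the matrix as isolates but are flagged
#' not-present there, reflecting that the set of active nodes can vary
#' across layers. Interlayer coupling is categorical (every pair of layers)
#' with a single weight `omega`, by default 1, attached only where an
#' individual is present in both layers.
#'
#' @param indices list of `dyadic_index` objects (or plain symmetric
#'   matrices with ids as dimnames) sharing one universe.
#' @param labels optional character vector of layer labels; defaults to the
#'   index types or list names.
#' @param omega positive interlayer coupling weight (default 1).
#' @param couple_all if `TRUE`, couple every individual between all layer
#'   pairs regardless of presence (sensitivity switch).
#' @return a `multiplex` object: list with `layers` (named list of
#'   adjacency matrices), `universe`, `presence` (individuals x layers
#'   logical matrix), `omega`, `couple_all`.
#' @export
build_multiplex <- function(indices, labels = NULL, omega = 1,
                            couple_all = FALSE) {
  if (!length(indices)) stop("need at least one layer", call. = FALSE)
  if (!is.finite(omega) || omega <= 0)
    stop("omega must be a positive real", call. = FALSE)
  mats <- lapply(indices, function(x) {
    if (inherits(x, "dyadic_index")) x$weights
    else if (inherits(x, "dyadic_totals")) x$matrix
    else check_dyadic_matrix(x, "layer adjacency")
  })
  if (is.null(labels)) {
    labels <- vapply(seq_along(indices), function(i) {
      x <- indices[[i]]
      if (is.list(x) && !is.null(x$type)) x$type
      else names(indices)[i] %||% paste0("layer", i)
    }, character(1))
  }
  if (length(labels) != length(mats) || anyDuplicated(labels))
    stop("labels must be unique, one per layer", call. = FALSE)
  u <- rownames(mats[[1]])
  for (i in seq_along(mats)) {
    ui <- rownames(mats[[i]])
    if (!identical(ui, u))
      stop("layer '", labels[i], "' universe differs: {",
           paste(setdiff(union(u, ui), intersect(u, ui)), collapse = ", "),
           "}", call. = FALSE)
  }
  names(mats) <- labels
  presence <- vapply(mats, function(m) rowSums(m) > 0, logical(length(u)))
  dimnames(presence) <- list(u, labels)
  structure(list(layers = mats, universe = u, presence = presence,
                 omega = omega, couple_all = isTRUE(couple_all)),
            class = "multiplex")
}

#' Number of layers of a multiplex
#' @param net a `multiplex` object.
#' @return integer layer count.
#' @export
n_layers <- function(net) length(net$layers)

#' Count intra-layer edges
#'
#' Unordered dyads with positive weight, summed over all layers.
#'
#' @param net a `multiplex` object.
#' @return integer edge count.
#' @export
intra_layer_edges <- function(net) {
  sum(vapply(net$layers, function(m) sum(m[upper.tri(m)] > 0), integer(1)))
}

# Leading nonnegative eigenvector by power iteration on the shifted matrix
# A + I (same Perron vector; the shift makes the dominant eigenvalue
# strictly dominant so iteration cannot cycle on bipartite structures).
# Starts from the uniform positive vector; converges when the max-norm
# change of the max-normalized iterate drops below tol.
power_iteration <- function(A, tol = 1e-12, max_iter = 1e5) {
  n <- nrow(A)
  if (all(A == 0)) stop("matrix has no edges", call. = FALSE)
  v <- rep(1, n)
  for (it in seq_len(max_iter)) {
    w <- as.vector(A %*% v) + v
    w <- w / max(w)
    delta <- max(abs(w - v))
    v <- w
    if (delta < tol) return(v)
  }
  stop(sprintf("power iteration did not converge in %d iterations (residual %.3e)",
               as.integer(max_iter), delta), call. = FALSE)
}

#' Eigenvector centrality of one layer
#'
#' Nonnegative leading eigenvector of the layer adjacency matrix,
#' normalized so the largest score is 1 (or to unit sum). On a layer with
#' several connected components only the component carrying the dominant
#' eigenvalue receives nonzero scores.
#'
#' @param layer a symmetric nonnegative adjacency matrix with ids as
#'   dimnames, or a `multiplex` plus `label`.
#' @param label layer label when `layer` is a `multiplex`.
#' @param normalization `"max"` (default, largest score 1) or `"sum"`.
#' @return named numeric vector of centrality scores.
#' @export
layer_centrality <- function(layer, label = NULL,
                             normalization = c("max", "sum")) {
  normalization <- match.arg(normalization)
  A <- if (inherits(layer, "multiplex")) {
    if (is.null(label) || !label %in% names(layer$layers))
      stop("unknown layer label", call. = FALSE)
    layer$layers[[label]]
  } else layer
  if (all(A == 0)) stop("layer has no edges", call. = FALSE)
  v <- power_iteration(A)
  v <- pmax(v, 0)
  v <- if (normalization == "max") v / max(v) else v / sum(v)
  stats::setNames(v, rownames(A))
}

#' Supra-adjacency matrix of a multiplex
#'
#' Block matrix of size (n*L) x (n*L): diagonal blocks are the layer
#' adjacencies; off-diagonal blocks carry `omega` on the (i,i) entries for
#' individuals present in both layers (all entries when `couple_all`).
#'
#' @param net a `multiplex` object.
#' @return symmetric numeric matrix with `id@layer` dimnames.
#' @export
supra_adjacency <- function(net) {
  n <- length(net$universe); L <- n_layers(net)
  S <- matrix(0, n * L, n * L)
  labs <- names(net$layers)
  nm <- as.vector(outer(net$universe, labs, paste, sep = "@"))
  dimnames(S) <- list(nm, nm)
  for (a in seq_len(L)) {
    ia <- (a - 1) * n + seq_len(n)
    S[ia, ia] <- net$layers[[a]]
    if (a < L) for (b in (a + 1):L) {
      ib <- (b - 1) * n + seq_len(n)
      coupled <- if (net$couple_all) rep(TRUE, n)
                 else net$presence[, a] & net$presence[, b]
      d <- ifelse(coupled, net$omega, 0)
      S[cbind(ia, ib)] <- d
      S[cbind(ib, ia)] <- d
    }
  }
  S
}

#' Multiplex eigenvector versatility
#'
#' The multiplex analogue of eigenvector centrality: the leading
#' nonnegative eigenvector of the supra-adjacency matrix, with each
#' individual's components summed across its layer copies, then normalized.
#' Captures the influence of an individual across all interaction types at
#' once.
#'
#' @param net a `multiplex` object.
#' @param normalization `"max"` (default) or `"sum"`.
#' @return named numeric vector of versatility scores per individual.
#' @export
versatility <- function(net, normalization = c("max", "sum")) {
  normalization <- match.arg(normalization)
  n <- length(net$universe); L <- n_layers(net)
  S <- supra_adjacency(net)
  if (all(S == 0)) stop("supra-adjacency has no nonzero entries", call. = FALSE)
  v <- power_iteration(S)
  comp <- rowSums(matrix(v, nrow = n, ncol = L))
  comp <- pmax(comp, 0)
  comp <- if (normalization == "max") comp / max(comp) else comp / sum(comp)
  stats::setNames(comp, net$universe)
}

#' Per-layer centrality and versatility report
#'
#' @param net a `multiplex` object.
#' @param normalization passed to [layer_centrality()] and [versatility()].
#' @return data frame: one row per individual, one column per layer's
#'   eigenvector centrality plus a `versatility` column; attribute
#'   `most_central` lists, per column, all individuals within 1e-9 of the
#'   maximum (tie-aware).
#' @export
centrality_report <- function(net, normalization = "max") {
  per_layer <- lapply(names(net$layers), function(l)
    layer_centrality(net, l, normalization))
  names(per_layer) <- names(net$layers)
  out <- data.frame(individual = net$universe, check.names = FALSE)
  for (l in names(per_layer)) out[[l]] <- per_layer[[l]][net$universe]
  out$versatility <- versatility(net, normalization)[net$universe]
  top <- lapply(c(names(per_layer), "versatility"), function(cn) {
    s <- out[[cn]]
    out$individual[s >= max(s) - 1e-9]
  })
  names(top) <- c(names(per_layer), "versatility")
  attr(out, "most_central") <- top
  out
}

#' Edge overlap between two layers
#'
#' `binary_jaccard`: shared positive dyads divided by the union of positive
#' dyads. `weighted_min`: sum over dyads of the minimum of the two weights,
#' meaningful when each layer's weights sum to 1 (dyadic index layers).
#'
#' @param a,b symmetric adjacency matrices over the same universe (or
#'   `dyadic_index` objects).
#' @param method `"binary_jaccard"` or `"weighted_min"`.
#' @return overlap value in `[0, 1]`.
#' @export
edge_overlap <- function(a, b, method = c("binary_jaccard", "weighted_min")) {
  method <- match.arg(method)
  if (inherits(a, "dyadic_index")) a <- a$weights
  if (inherits(b, "dyadic_index")) b <- b$weights
  if (!identical(rownames(a), rownames(b)))
    stop("layers must share one universe", call. = FALSE)
  ua <- a[upper.tri(a)]; ub <- b[upper.tri(b)]
  if (all(ua == 0) && all(ub == 0))
    stop("both layers are edgeless", call. = FALSE)
  if (method == "binary_jaccard") {
    inter <- sum(ua > 0 & ub > 0)
    uni <- sum(ua > 0 | ub > 0)
    inter / uni
  } else {
    sum(pmin(ua, ub))
  }
}

#' Global edge overlap of a multiplex
#'
#' `mean_pairwise`: mean of [edge_overlap()] over all layer pairs (with the
#' chosen `pair_method`). `all_layers_weighted`: sum over dyads of the
#' minimum weight across ALL layers.
#'
#' @param net a `multiplex` object with at least 2 layers.
#' @param method `"mean_pairwise"` or `"all_layers_weighted"`.
#' @param pair_method pairwise method used under `mean_pairwise`.
#' @return list with `fraction` and `percent` (= 100 * fraction).
#' @export
global_edge_overlap <- function(net,
                                method = c("mean_pairwise",
                                           "all_layers_weighted"),
                                pair_method = "weighted_min") {
  method <- match.arg(method)
  L <- n_layers(net)
  if (L < 2) stop("global overlap needs at least 2 layers", call. = FALSE)
  f <- if (method == "mean_pairwise") {
    pairs <- utils::combn(names(net$layers), 2)
    mean(apply(pairs, 2, function(p)
      edge_overlap(net$layers[[p[1]]], net$layers[[p[2]]],
                   pair_method)))
  } else {
    mins <- Reduce(pmin, lapply(net$layers, function(m) m[upper.tri(m)]))
    sum(mins)
  }
  list(fraction = f, percent = 100 * f)
}

#' Pairwise overlap table for all layer pairs
#'
#' @param net a `multiplex` object.
#' @param method passed to [edge_overlap()].
#' @return data frame with columns `layer_a`, `layer_b`, `overlap`.
#' @export
overlap_table <- function(net, method = "weighted_min") {
  if (n_layers(net) < 2) stop("need at least 2 layers", call. = FALSE)
  pairs <- utils::combn(names(net$layers), 2)
  data.frame(layer_a = pairs[1, ], layer_b = pairs[2, ],
             overlap = apply(pairs, 2, function(p)
               edge_overlap(net$layers[[p[1]]], net$layers[[p[2]]], method)))
}

#' @export
print.multiplex <- function(x, ...) {
  cat(sprintf("Multiplex network: %d individuals, %d layers (%s), omega = %g\n",
              length(x$universe), n_layers(x),
              paste(names(x$layers), collapse = ", "), x$omega))
  cat(sprintf("  intra-layer edges: %d\n", intra_layer_edges(x)))
  invisible(x)
}

#' @export
summary.multiplex <- function(object, ...) {
  edges <- vapply(object$layers, function(m) sum(m[upper.tri(m)] > 0),
                  integer(1))
  present <- colSums(object$presence)
  out <- list(
    n_individuals = length(object$universe),
    n_layers = n_layers(object),
    omega = object$omega,
    edges_per_layer = edges,
    present_per_layer = present,
    total_edges = sum(edges)
  )
  class(out) <- "summary.multiplex"
  out
}

#' @export
print.summary.multiplex <- function(x, ...) {
  cat(sprintf("Multiplex: %d individuals, %d layers, omega = %g\n",
              x$n_individuals, x$n_layers, x$omega))
  for (l in names(x$edges_per_layer))
    cat(sprintf("  %-14s %3d edges, %d individuals present\n",
                l, x$edges_per_layer[[l]], x$present_per_layer[[l]]))
  cat(sprintf("  total intra-layer edges: %d\n", x$total_edges))
  invisible(x)
}

#' Minimal graph-description export
#'
#' Writes the data behind a layered network drawing: one node table (node
#' size = versatility) and one edge table (edge width = weight), without
#' any styling.
#'
#' @param net a `multiplex` object.
#' @param path_prefix files `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`
#'   are written.
#' @return invisible character vector of the two paths.
#' @export
export_graph_description <- function(net, path_prefix) {
  v <- versatility(net)
  nodes <- data.frame(individual = net$universe, size = v[net$universe])
  edges <- do.call(rbind, lapply(names(net$layers), function(l) {
    m <- net$layers[[l]]
    p <- dyad_pairs(rownames(m))
    w <- m[cbind(p[, 1], p[, 2])]
    keep <- w > 0
    data.frame(layer = l, from = p[keep, 1], to = p[keep, 2],
               width = w[keep])
  }))
  paths <- paste0(path_prefix, c("_nodes.tsv", "_edges.tsv"))
  utils::write.table(nodes, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(edges, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
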