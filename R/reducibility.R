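#' Laplacian density matrix of a layer
#'
#' The graph analogue of a quantum density matrix: the combinatorial
#' Laplacian L = D - A rescaled to unit trace, rho = L / tr(L). It is
#' positive semidefinite with trace 1, so its eigenvalues form a
#' probability distribution and support an entropy.
#'
#' @param A symmetric nonnegative adjacency matrix with at least one
#'   positive edge weight (zero diagonal).
#' @return `density_matrix` object: the rho matrix with attribute `label`.
#' @param label optional source-layer label.
#' @export
density_matrix <- function(A, label = NULL) {
  if (inherits(A, "dyadic_index")) { label <- label %||% A$type; A <- A$weights }
  if (all(A == 0)) stop("all-zero adjacency: density matrix undefined",
                        call. = FALSE)
  L <- diag(rowSums(A)) - A
  rho <- L / sum(diag(L))
  structure(rho, label = label, class = c("density_matrix", "matrix"))
}

# Eigenvalues of a density matrix, clipped to [0, 1]; values below the
# floor are treated as exact zeros.
density_spectrum <- function(rho, floor = 1e-12) {
  ev <- eigen(unclass(rho), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("density matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  ev <- pmax(ev, 0)
  ev[ev < floor] <- 0
  ev
}

#' Von Neumann entropy of a density matrix
#'
#' h(rho) = -sum lambda_i log2 lambda_i over the eigenvalues of rho, with
#' 0 log 0 = 0. Base-2 logarithms, so the Jensen-Shannon distance built on
#' it lies in `[0, 1]`.
#'
#' @param rho a `density_matrix` (or any symmetric PSD trace-1 matrix).
#' @return nonnegative entropy in bits.
#' @export
von_neumann_entropy <- function(rho) {
  ev <- density_spectrum(rho)
  ev <- ev[ev > 0]
  -sum(ev * log2(ev))
}

#' Jensen-Shannon distance between two density matrices
#'
#' D(a, b) = sqrt( h((a+b)/2) - (h(a) + h(b))/2 ) with base-2 entropies;
#' 0 means identical structure, 1 maximal dissimilarity. A slightly
#' negative radicand from rounding (>= -1e-10) is clipped to 0.
#'
#' @param rho_a,rho_b density matrices of equal dimension.
#' @return distance in `[0, 1]`.
#' @export
jensen_shannon_distance <- function(rho_a, rho_b) {
  if (!all(dim(rho_a) == dim(rho_b)))
    stop("density matrices must have the same dimension", call. = FALSE)
  mix <- (unclass(rho_a) + unclass(rho_b)) / 2
  class(mix) <- c("density_matrix", "matrix")
  rad <- von_neumann_entropy(mix) -
    (von_neumann_entropy(rho_a) + von_neumann_entropy(rho_b)) / 2
  if (rad < -1e-10)
    stop("negative Jensen-Shannon radicand beyond tolerance: ", rad,
         call. = FALSE)
  sqrt(max(rad, 0))
}

#' Jensen-Shannon distance matrix of a multiplex
#'
#' Pairwise distances between the per-layer density matrices (intralayer
#' adjacency only; interlayer coupling plays no role here).
#'
#' @param net a `multiplex` object whose layers all have at least one edge.
#' @return symmetric matrix with layer labels as dimnames, zero diagonal.
#' @export
jsd_matrix <- function(net) {
  labs <- names(net$layers)
  empty <- labs[vapply(net$layers, function(m) all(m == 0), logical(1))]
  if (length(empty))
    stop("edgeless layer(s): ", paste(empty, collapse = ", "), call. = FALSE)
  rhos <- lapply(net$layers, density_matrix)
  M <- length(labs)
  D <- matrix(0, M, M, dimnames = list(labs, labs))
  if (M > 1) for (a in 1:(M - 1)) for (b in (a + 1):M) {
    D[a, b] <- D[b, a] <- jensen_shannon_distance(rhos[[a]], rhos[[b]])
  }
  D
}

#' Ward agglomeration of a layer distance matrix
#'
#' Agglomerative hierarchical clustering of the layers under Ward linkage,
#' run via the Lance-Williams update. The default `"d2"` convention applies
#' the update to squared distances (the Ward.D2 convention); `"d1"` applies
#' it to the distances as given (the historical Ward.D convention). Merges
#' are deterministic: ties on the minimum are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its sorted
#' member set).
#'
#' @param jsd symmetric distance matrix with layer labels as dimnames.
#' @param variant `"d2"` (default) or `"d1"`.
#' @return list of merge steps; each step is a list with `step`, `pair`
#'   (a list of the two merged clusters as character vectors of original
#'   labels), and `height` (the linkage distance at the merge).
#' @export
ward_merges <- function(jsd, variant = c("d2", "d1")) {
  variant <- match.arg(variant)
  if (any(!is.finite(jsd))) stop("non-finite distances", call. = FALSE)
  labs <- rownames(jsd)
  M <- length(labs)
  if (M < 2) stop("need at least 2 layers", call. = FALSE)
  # work on squared distances for d2, raw for d1
  d <- if (variant == "d2") jsd^2 else jsd
  clusters <- lapply(labs, function(l) l)   # member sets
  sizes <- rep(1, M)
  active <- rep(TRUE, M)
  key <- function(cl) paste(sort(cl), collapse = "\r")
  merges <- vector("list", M - 1)
  for (step in seq_len(M - 1)) {
    # find minimum over active pairs, lexicographic tie-break
    best <- NULL
    for (i in seq_len(M - 1)) if (active[i]) for (j in (i + 1):M) if (active[j]) {
      cand <- list(i = i, j = j, v = d[i, j],
                   k = paste(key(clusters[[i]]), key(clusters[[j]])))
      if (is.null(best) || cand$v < best$v - 1e-15 ||
          (abs(cand$v - best$v) <= 1e-15 && cand$k < best$k))
        best <- cand
    }
    i <- best$i; j <- best$j
    height <- if (variant == "d2") sqrt(best$v) else best$v
    merges[[step]] <- list(step = step,
                           pair = list(sort(clusters[[i]]),
                                       sort(clusters[[j]])),
                           height = height)
    # Lance-Williams Ward update into slot i
    ni <- sizes[i]; nj <- sizes[j]
    for (k in seq_len(M)) if (active[k] && k != i && k != j) {
      nk <- sizes[k]
      dn <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
      d[i, k] <- d[k, i] <- dn
    }
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    sizes[i] <- ni + nj
    active[j] <- FALSE
  }
  merges
}

# Partition of original labels after applying the first m merge steps.
partition_after <- function(labels, merges, m) {
  groups <- lapply(labels, function(l) l)
  if (m > 0) for (s in seq_len(m)) {
    pr <- merges[[s]]$pair
    ia <- which(vapply(groups, function(g) setequal(g, pr[[1]]), logical(1)))
    ib <- which(vapply(groups, function(g) setequal(g, pr[[2]]), logical(1)))
    groups[[ia]] <- sort(c(groups[[ia]], groups[[ib]]))
    groups <- groups[-ib]
  }
  groups
}

#' Aggregate layers of a multiplex by a partition
#'
#' Each group of layer labels becomes one layer whose adjacency is the
#' element-wise sum of its members' adjacencies (no re-normalization: the
#' density matrix is scale-invariant).
#'
#' @param net a `multiplex` object.
#' @param grouping list of character vectors partitioning the layer labels.
#' @return a `multiplex` with one layer per group, labelled by joined
#'   member names.
#' @export
aggregate_layers <- function(net, grouping) {
  labs <- names(net$layers)
  flat <- unlist(grouping)
  if (anyDuplicated(flat) || !setequal(flat, labs))
    stop("grouping is not a partition of the layer labels", call. = FALSE)
  mats <- lapply(grouping, function(g) Reduce(`+`, net$layers[g]))
  build_multiplex(mats,
                  labels = vapply(grouping, function(g)
                    paste(sort(g), collapse = "+"), character(1)),
                  omega = net$omega, couple_all = net$couple_all)
}

#' Relative von Neumann entropy curve along an aggregation path
#'
#' For each aggregation step m (0 = all layers separate), the first m
#' merges define a partition C_m; its quality is
#' q(C_m) = 1 - Hbar(C_m) / h_agg, where Hbar is the mean entropy of the
#' groups' summed adjacencies and h_agg is the entropy of the fully
#' aggregated network. High q means the partition is still highly
#' distinguishable from the single-layer aggregate, i.e. keeps
#' non-redundant structure. The final step always has q = 0.
#'
#' @param net a `multiplex` object.
#' @param merges merge list from [ward_merges()] on this network's
#'   [jsd_matrix()].
#' @return numeric vector of length M (steps 0 .. M-1).
#' @export
relative_entropy_curve <- function(net, merges) {
  labs <- names(net$layers)
  M <- length(labs)
  agg <- Reduce(`+`, net$layers)
  h_agg <- von_neumann_entropy(density_matrix(agg))
  if (h_agg <= 0) stop("degenerate aggregate: zero entropy", call. = FALSE)
  vapply(0:(M - 1), function(m) {
    groups <- partition_after(labs, merges, m)
    hbar <- mean(vapply(groups, function(g) {
      von_neumann_entropy(density_matrix(Reduce(`+`, net$layers[g])))
    }, numeric(1)))
    1 - hbar / h_agg
  }, numeric(1))
}

#' Structural reducibility of a multiplex
#'
#' Decides which layers can be aggregated without losing non-redundant
#' structural information: computes the Jensen-Shannon distance matrix
#' between layers, clusters it with the Ward method, aggregates the most
#' similar layers one step at a time, and scores every step with the
#' relative von Neumann entropy q. The step where q is maximal is the
#' configuration preserving the most structure; ties resolve to the
#' smallest step (the least-reduced network).
#'
#' @param net a `multiplex` object with >= 2 layers, all non-empty.
#' @param ward `"d2"` or `"d1"` Ward convention.
#' @return a `reducibility` object: list with `jsd` (distance matrix),
#'   `merges`, `q` (relative entropy per step, index 1 = step 0),
#'   `best_step` (0-based), `partitions` (the partition at each step).
#' @export
reduce_multiplex <- function(net, ward = "d2") {
  if (n_layers(net) < 2) stop("need at least 2 layers", call. = FALSE)
  D <- jsd_matrix(net)
  merges <- ward_merges(D, ward)
  q <- relative_entropy_curve(net, merges)
  labs <- names(net$layers)
  parts <- lapply(0:(length(labs) - 1), function(m)
    partition_after(labs, merges, m))
  structure(list(jsd = D, merges = merges, q = q,
                 best_step = which.max(q) - 1L,
                 partitions = parts),
            class = "reducibility")
}

#' @export
print.reducibility <- function(x, ...) {
  M <- nrow(x$jsd)
  cat("Structural reducibility,", M, "layers\n")
  cat("Jensen-Shannon distances:\n")
  print(round(x$jsd, 4))
  for (m in x$merges)
    cat(sprintf("  step %d: merge {%s} + {%s} at height %.4f\n", m$step,
                paste(m$pair[[1]], collapse = ","),
                paste(m$pair[[2]], collapse = ","), m$height))
  cat("Relative entropy q per step:",
      paste(sprintf("%.4f", x$q), collapse = ", "), "\n")
  part <- x$partitions[[x$best_step + 1]]
  cat(sprintf("Best step: %d (%s)\n", x$best_step,
              if (x$best_step == 0) "all layers kept separate"
              else paste(vapply(part, paste, character(1), collapse = "+"),
                         collapse = " | ")))
  invisible(x)
}

#' @export
plot.reducibility <- function(x, ...) {
  steps <- seq_along(x$q) - 1
  graphics::plot(steps, x$q, type = "b", pch = 19,
                 xlab = "aggregation step", ylab = "relative entropy q",
                 ...)
  graphics::abline(v = x$best_step, lty = 2)
  invisible(x)
}
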