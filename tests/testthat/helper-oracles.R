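# Independent oracles and small generators used across the suite.
# Every oracle recomputes a quantity by a route different from the
# package implementation (dense eigendecomposition, stats::hclust,
# exhaustive enumeration, line-by-line accumulation).

# Leading eigenvector via a full dense eigendecomposition (base eigen),
# max-normalized; sign fixed to the nonnegative orientation.
eig_centrality_oracle <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (sum(v) < 0) v <- -v
  v <- abs(v)
  stats::setNames(v / max(v), rownames(A))
}

# Von Neumann entropy recomputed directly from the Laplacian spectrum.
vn_entropy_oracle <- function(A) {
  L <- diag(rowSums(A)) - A
  ev <- eigen(L / sum(diag(L)), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12]
  -sum(ev * log2(ev))
}

# Jensen-Shannon distance recomputed from scratch out of three spectra.
jsd_oracle <- function(A, B) {
  rho <- function(M) { L <- diag(rowSums(M)) - M; L / sum(diag(L)) }
  h <- function(R) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > 1e-12]
    -sum(ev * log2(ev))
  }
  ra <- rho(A); rb <- rho(B)
  sqrt(max(h((ra + rb) / 2) - (h(ra) + h(rb)) / 2, 0))
}

# All set partitions of a character vector (Bell-number enumeration by
# recursive placement); used as the exhaustive reducibility oracle.
set_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- set_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(items[1], q[[k]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(items[1]), p)
  }
  out
}

# q value of an explicit partition of a multiplex's layers.
partition_q <- function(net, partition) {
  agg <- Reduce(`+`, net$layers)
  h_agg <- vn_entropy_oracle(agg)
  hbar <- mean(vapply(partition, function(g)
    vn_entropy_oracle(Reduce(`+`, net$layers[g])), numeric(1)))
  1 - hbar / h_agg
}

# Random symmetric nonnegative layer over ids, with approximate edge
# density `p`; always at least one edge.
random_layer <- function(ids, p = 0.7) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- upper.tri(m)
  w <- ifelse(stats::runif(sum(ut)) < p, stats::runif(sum(ut)), 0)
  if (all(w == 0)) w[1] <- stats::runif(1)
  m[ut] <- w
  m + t(m)
}

# Random index layer (weights sum to 1 over unordered dyads).
random_index_layer <- function(ids, p = 0.7) {
  m <- random_layer(ids, p)
  m / sum(m[upper.tri(m)])
}

# Symmetric dyadic totals with exactly k positive dyads summing to `total`
# over n individuals; used to reconstruct descriptive summaries from
# printed grand totals.
totals_with <- function(n, k_observed, total, type = "grooming") {
  ids <- sprintf("I%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  pr <- which(upper.tri(m), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  stopifnot(k_observed <= nrow(pr))
  if (k_observed > 0) {
    w <- seq_len(k_observed)
    w <- w / sum(w) * total
    sel <- pr[seq_len(k_observed), , drop = FALSE]
    m[sel] <- w
    m <- m + t(m) - diag(diag(m))
  }
  as_dyadic_totals(m, type)
}

# One focal record row, with defaults for brevity.
rec <- function(focal, actor, recipient, behavior = "groom", dur = 60,
                session = "S1", period = "P1") {
  data.frame(session_id = session, period_id = period, focal_id = focal,
             behavior = behavior, actor_id = actor,
             recipient_id = recipient, duration_s = dur,
             stringsAsFactors = FALSE)
}
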