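ids4 <- letters[1:4]
k4 <- matrix(1, 4, 4, dimnames = list(ids4, ids4)); diag(k4) <- 0
star4 <- matrix(0, 4, 4, dimnames = list(ids4, ids4))
star4["a", c("b", "c", "d")] <- star4[c("b", "c", "d"), "a"] <- 1

test_that("density matrices have the closed-form Laplacian spectra", {
  two <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ev <- sort(eigen(unclass(density_matrix(two)), symmetric = TRUE)$values)
  expect_equal(ev, c(0, 1), tolerance = 1e-12)

  # K4: Laplacian spectrum {0,4,4,4}, trace 12 -> {0, 1/3, 1/3, 1/3}
  evk <- sort(eigen(unclass(density_matrix(k4)), symmetric = TRUE)$values)
  expect_equal(evk, c(0, 1 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)

  # trace 1, PSD
  rho <- density_matrix(star4)
  expect_equal(sum(diag(rho)), 1, tolerance = 1e-12)
  expect_gte(min(eigen(unclass(rho), symmetric = TRUE)$values), -1e-10)

  # padding with isolated nodes keeps the nonzero spectrum
  pad <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  pad[1:4, 1:4] <- k4
  evp <- eigen(unclass(density_matrix(pad)), symmetric = TRUE)$values
  expect_equal(sort(evp[evp > 1e-10]), rep(1 / 3, 3), tolerance = 1e-10)

  expect_error(density_matrix(pad * 0), "all-zero")
})

test_that("von Neumann entropy matches closed forms", {
  two <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(von_neumann_entropy(density_matrix(two)), 0, tolerance = 1e-12)
  expect_equal(von_neumann_entropy(density_matrix(k4)), log2(3),
               tolerance = 1e-9)
  # star: Laplacian spectrum {0,1,1,4}/6
  h_star <- -(2 * (1 / 6) * log2(1 / 6) + (2 / 3) * log2(2 / 3))
  expect_equal(von_neumann_entropy(density_matrix(star4)), h_star,
               tolerance = 1e-9)

  # invariance under isolated-node padding and uniform scaling
  pad <- matrix(0, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
  pad[1:4, 1:4] <- star4
  expect_equal(von_neumann_entropy(density_matrix(pad)), h_star,
               tolerance = 1e-10)
  expect_equal(von_neumann_entropy(density_matrix(star4 * 17.3)), h_star,
               tolerance = 1e-10)
})

test_that("Jensen-Shannon distance is a bounded symmetric divergence", {
  rk <- density_matrix(k4); rs <- density_matrix(star4)
  expect_equal(jensen_shannon_distance(rk, rk), 0)
  expect_equal(jensen_shannon_distance(rk, rs), jsd_oracle(k4, star4),
               tolerance = 1e-10)

  set.seed(31)
  for (r in 1:10) {
    A <- random_layer(letters[1:5]); B <- random_layer(letters[1:5])
    d <- jensen_shannon_distance(density_matrix(A), density_matrix(B))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, jensen_shannon_distance(density_matrix(B),
                                            density_matrix(A)))
    expect_equal(d, jsd_oracle(A, B), tolerance = 1e-10)
  }
  expect_error(jensen_shannon_distance(rk, density_matrix(
    matrix(c(0, 1, 1, 0), 2, dimnames = list(1:2, 1:2)))), "dimension")
})

test_that("jsd_matrix composes pairwise distances over layers", {
  set.seed(32)
  ids <- sprintf("I%d", 1:6)
  net <- build_multiplex(lapply(1:3, function(i) random_index_layer(ids)),
                         labels = c("a", "b", "c"))
  D <- jsd_matrix(net)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), stats::setNames(rep(0, 3), c("a", "b", "c")))
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_equal(D[p[1], p[2]],
                 jsd_oracle(net$layers[[p[1]]], net$layers[[p[2]]]),
                 tolerance = 1e-10)

  dup <- make_fixture("duplicated_pair")
  expect_equal(jsd_matrix(dup)["twin1", "twin2"], 0, tolerance = 1e-7)

  bad <- build_multiplex(list(a = net$layers$a,
                              b = net$layers$b * 0))
  expect_error(jsd_matrix(bad), "edgeless layer.*b")
})

test_that("Ward merges follow the Lance-Williams recursion of hclust", {
  # M = 2: one merge
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  m <- ward_merges(d2)
  expect_length(m, 1)
  expect_equal(m[[1]]$height, 0.4)

  # zero-distance pair merges first
  d3 <- matrix(c(0, 0, .8, 0, 0, .8, .8, .8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_setequal(unlist(ward_merges(d3)[[1]]$pair), c("A", "B"))

  # random matrices against stats::hclust for both conventions
  set.seed(33)
  for (r in 1:8) {
    M <- sample(3:6, 1)
    labs <- LETTERS[seq_len(M)]
    d <- matrix(0, M, M, dimnames = list(labs, labs))
    d[upper.tri(d)] <- stats::runif(M * (M - 1) / 2, 0.1, 1)
    d <- d + t(d)
    for (variant in c("d2", "d1")) {
      hc <- stats::hclust(stats::as.dist(d),
                          method = if (variant == "d2") "ward.D2" else "ward.D")
      mine <- ward_merges(d, variant)
      expect_equal(vapply(mine, `[[`, numeric(1), "height"),
                   hc$height, tolerance = 1e-10)
      # same clusters at every cut
      for (step in seq_len(M - 1)) {
        hcl <- stats::cutree(hc, k = M - step)
        groups_hc <- split(labs, hcl)
        groups_me <- lapply(seq_len(M - step), function(i) i)
        # rebuild partition from merge list
        part <- lapply(labs, identity)
        for (s in seq_len(step)) {
          pr <- mine[[s]]$pair
          ia <- which(vapply(part, function(g) setequal(g, pr[[1]]),
                             logical(1)))
          ib <- which(vapply(part, function(g) setequal(g, pr[[2]]),
                             logical(1)))
          part[[ia]] <- sort(c(part[[ia]], part[[ib]]))
          part <- part[-ib]
        }
        key <- function(p) sort(vapply(p, function(g)
          paste(sort(g), collapse = ","), character(1)))
        expect_equal(key(part), key(unname(groups_hc)))
      }
    }
  }
  expect_error(ward_merges(matrix(c(0, NA, NA, 0), 2,
    dimnames = list(1:2, 1:2))), "non-finite")
})

test_that("layer aggregation sums adjacencies and preserves rho under duplication", {
  set.seed(34)
  ids <- sprintf("I%d", 1:5)
  net <- build_multiplex(lapply(1:3, function(i) random_index_layer(ids)),
                         labels = c("a", "b", "c"))
  same <- aggregate_layers(net, list("a", "b", "c"))
  expect_equal(same$layers[[1]], net$layers$a)
  expect_equal(n_layers(same), 3)

  # duplicate merged with itself: adjacency doubles, density matrix unchanged
  dup <- build_multiplex(list(a = net$layers$a, a2 = net$layers$a))
  agg <- aggregate_layers(dup, list(c("a", "a2")))
  expect_equal(agg$layers[[1]], 2 * net$layers$a)
  expect_equal(unclass(density_matrix(agg$layers[[1]])),
               unclass(density_matrix(net$layers$a)), tolerance = 1e-12)

  all_in <- aggregate_layers(net, list(c("a", "b", "c")))
  expect_equal(all_in$layers[[1]],
               net$layers$a + net$layers$b + net$layers$c)
  expect_error(aggregate_layers(net, list(c("a", "b"))), "partition")
  expect_error(aggregate_layers(net, list(c("a", "b"), c("b", "c"))),
               "partition")
})

test_that("relative entropy curve ends at zero and is null for identical layers", {
  set.seed(35)
  ids <- sprintf("I%d", 1:6)
  A <- random_index_layer(ids)
  same <- build_multiplex(list(a = A, b = A, c = A))
  red <- reduce_multiplex(same)
  expect_equal(red$q, rep(0, 3), tolerance = 1e-9)
  expect_equal(red$best_step, 0)   # ties resolve to the least-reduced step

  tri <- make_fixture("independent_trio")
  q <- relative_entropy_curve(tri, ward_merges(jsd_matrix(tri)))
  expect_equal(q[length(q)], 0, tolerance = 1e-12)
  expect_true(all(is.finite(q)))
})

test_that("greedy dendrogram optimum is bounded by the exhaustive partition optimum", {
  set.seed(36)
  mismatches <- 0
  for (r in 1:6) {
    M <- sample(3:4, 1)
    ids <- sprintf("I%d", 1:6)
    net <- build_multiplex(lapply(seq_len(M), function(i)
      random_index_layer(ids)), labels = LETTERS[seq_len(M)])
    red <- reduce_multiplex(net)
    all_q <- vapply(set_partitions(LETTERS[seq_len(M)]), partition_q,
                    numeric(1), net = net)
    best_exhaustive <- max(all_q)
    # the greedy path can never beat the exhaustive optimum
    expect_lte(max(red$q), best_exhaustive + 1e-9)
    # if the exhaustive optimum partition lies on the dendrogram path the
    # greedy result attains it
    key <- function(p) paste(sort(vapply(p, function(g)
      paste(sort(g), collapse = ","), character(1))), collapse = "|")
    path_keys <- vapply(red$partitions, key, character(1))
    opt <- set_partitions(LETTERS[seq_len(M)])[[which.max(all_q)]]
    if (key(opt) %in% path_keys) {
      expect_equal(max(red$q), best_exhaustive, tolerance = 1e-9)
    } else {
      mismatches <- mismatches + 1
    }
  }
  if (mismatches > 0)
    message(mismatches, " instance(s) had the exhaustive optimum off the greedy path")
})

test_that("reduce_multiplex recovers engineered structure", {
  set.seed(37)
  ids <- sprintf("I%d", 1:6)
  # two independent dense random layers: keeping them separate is best
  twod <- build_multiplex(list(a = random_index_layer(ids, 1),
                               b = random_index_layer(ids, 1)))
  expect_equal(reduce_multiplex(twod)$best_step, 0)

  # a layer plus its exact copy: q identically zero, best step 0 by ties
  A <- random_index_layer(ids)
  copy <- build_multiplex(list(a = A, b = A))
  redc <- reduce_multiplex(copy)
  expect_equal(redc$q, c(0, 0), tolerance = 1e-9)
  expect_equal(redc$best_step, 0)

  # twins merge first when a third distinct layer is present
  dup <- make_fixture("duplicated_pair")
  red <- reduce_multiplex(dup)
  expect_setequal(unlist(red$merges[[1]]$pair), c("twin1", "twin2"))

  expect_error(reduce_multiplex(build_multiplex(list(a = A))), "2 layers")
})
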