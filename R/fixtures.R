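#' Deterministic multiplex fixtures
#'
#' Small, fully deterministic multiplex networks used to pin down the
#' spectral machinery against closed forms and to check structure
#' recovery:
#' \describe{
#'   \item{`k4_vs_star`}{two 4-node layers with unit weights: the complete
#'     graph K4 (entropy log2 3) and a star (entropy from the closed-form
#'     Laplacian spectrum \{0, 1, 1, 4\}/6).}
#'   \item{`duplicated_pair`}{three 5-node layers, the first two exactly
#'     identical -- their Jensen-Shannon distance is 0 and they must merge
#'     first.}
#'   \item{`independent_trio`}{three structurally unrelated dense 6-node
#'     layers; aggregating any pair loses structure, so the best
#'     reducibility step is 0.}
#'   \item{`study_shape`}{6 individuals, three index layers with 7, 10 and
#'     15 positive dyads (32 intra-layer edges in total), mimicking the
#'     shape of a one-period mandrill multiplex: sparse concentrated
#'     grooming, mid-density proximity, complete agonism.}
#' }
#'
#' @param name fixture name.
#' @return a `multiplex` object.
#' @export
make_fixture <- function(name = c("k4_vs_star", "duplicated_pair",
                                  "independent_trio", "study_shape")) {
  name <- match.arg(name)
  sym <- function(ids, edges) {
    # edges: data.frame i, j, w
    n <- length(ids)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (k in seq_len(nrow(edges))) {
      m[edges$i[k], edges$j[k]] <- m[edges$j[k], edges$i[k]] <- edges$w[k]
    }
    m
  }
  if (name == "k4_vs_star") {
    ids <- c("a", "b", "c", "d")
    k4 <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(k4) <- 0
    star <- sym(ids, data.frame(i = "a", j = c("b", "c", "d"), w = 1))
    return(build_multiplex(list(k4 = k4, star = star)))
  }
  if (name == "duplicated_pair") {
    ids <- letters[1:5]
    ring <- sym(ids, data.frame(i = ids, j = ids[c(2:5, 1)],
                                w = c(1, 2, 1, 2, 1) / 7))
    hub <- sym(ids, data.frame(i = "a", j = ids[2:5],
                               w = c(4, 3, 2, 1) / 10))
    return(build_multiplex(list(twin1 = ring, twin2 = ring, other = hub)))
  }
  if (name == "independent_trio") {
    ids <- sprintf("F%02d", 1:6)
    pr <- dyad_pairs(ids)
    nd <- nrow(pr)
    mk <- function(w) {
      m <- matrix(0, 6, 6, dimnames = list(ids, ids))
      m[cbind(pr[, 1], pr[, 2])] <- w
      m + t(m)
    }
    # three dense layers with unrelated weight patterns
    w1 <- (seq_len(nd) %% 5 + 1)               # sawtooth
    w2 <- rev(seq_len(nd))                     # descending ramp
    w3 <- ((seq_len(nd) * 7) %% 11) + 0.5      # scrambled residues
    return(build_multiplex(list(alpha = mk(w1 / sum(w1)),
                                beta = mk(w2 / sum(w2)),
                                gamma = mk(w3 / sum(w3)))))
  }
  # study_shape
  ids <- sprintf("F%02d", 1:6)
  pr <- dyad_pairs(ids)
  groom_dyads <- c(1, 2, 5, 6, 9, 12, 15)          # 7 dyads
  prox_dyads <- c(1, 2, 3, 5, 7, 8, 10, 11, 13, 14) # 10 dyads
  mk <- function(sel, w) {
    m <- matrix(0, 6, 6, dimnames = list(ids, ids))
    m[cbind(pr[sel, 1], pr[sel, 2])] <- w / sum(w)
    m + t(m)
  }
  grooming <- mk(groom_dyads, c(30, 8, 14, 3, 22, 5, 18))
  proximity <- mk(prox_dyads, c(9, 4, 6, 2, 8, 3, 5, 7, 1, 10))
  agonism <- mk(seq_len(15), ((seq_len(15) * 3) %% 7) + 1)
  build_multiplex(list(grooming = grooming, proximity = proximity,
                       agonism = agonism))
}
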