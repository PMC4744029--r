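#' Generate a weighted benchmark graph with planted weight-similarity
#' correlation
#'
#' Builds an unweighted backbone, then assigns each link (i, j) a weight
#' `w = exp(b * cn(i, j) + e)`, where `cn(i, j)` is the number of common
#' neighbours of the endpoints in the backbone, `e ~ Normal(0, noise_sd)`,
#' and `b = +beta`, `-beta` or `0` for `weight_mode` `"positive"`,
#' `"negative"` or `"iid"`. Positive mode plants weights that grow with
#' endpoint structural similarity (weights read as affinities, the regime
#' where strong ties are informative); negative mode plants the opposite
#' (weights read as dissimilarities, the regime where weak ties carry the
#' signal); iid weights carry no structural information. The exponential
#' link keeps every weight strictly positive for any noise draw.
#'
#' The planted correlation is a property of the ground-truth network:
#' `cn` is computed on the full backbone before any train/probe split.
#'
#' @param n number of nodes (at least 10).
#' @param mean_degree target mean degree (at least 2, below `n`); for the
#'   small-world and scale-free backbones it should be even.
#' @param backbone `"small-world"` (ring lattice plus rewiring),
#'   `"scale-free"` (preferential attachment), or `"random"`
#'   (Erdos-Renyi at the target density).
#' @param rewire rewiring probability of the small-world backbone
#'   (ignored otherwise).
#' @param weight_mode `"positive"`, `"negative"`, or `"iid"`.
#' @param beta magnitude of the weight-similarity slope.
#' @param noise_sd standard deviation of the log-weight noise (>= 0).
#' @param seed integer seed; the same seed reproduces the same graph.
#' @return a [wgraph] with nodes named `"1"` ... `"n"`.
#' @export
generate_weighted_network <- function(n = 300, mean_degree = 8,
                                      backbone = c("small-world", "scale-free", "random"),
                                      rewire = 0.1,
                                      weight_mode = c("iid", "positive", "negative"),
                                      beta = 0.5, noise_sd = 0.3, seed = 1) {
  backbone <- match.arg(backbone)
  weight_mode <- match.arg(weight_mode)
  stopifnot(n >= 10, mean_degree >= 2, noise_sd >= 0, beta >= 0)
  if (mean_degree >= n) stop("mean_degree must be smaller than n")
  with_seed(seed, {
    bb <- switch(backbone,
      "small-world" = igraph::sample_smallworld(1, n, max(1, round(mean_degree / 2)),
                                                rewire),
      "scale-free" = igraph::sample_pa(n, power = 1,
                                       m = max(1, round(mean_degree / 2)),
                                       directed = FALSE),
      "random" = igraph::sample_gnm(n, round(n * mean_degree / 2)))
    bb <- igraph::simplify(bb)
    igraph::V(bb)$name <- as.character(seq_len(n))
    m <- igraph::ecount(bb)
    A <- igraph::as_adjacency_matrix(bb, sparse = TRUE)
    ends <- igraph::ends(bb, igraph::E(bb), names = FALSE)
    cn <- (A %*% A)[ends]
    b <- switch(weight_mode, positive = beta, negative = -beta, iid = 0)
    igraph::E(bb)$weight <- exp(b * cn + stats::rnorm(m, 0, noise_sd))
    as_wgraph(bb)
  })
}

#' Deterministic unit-test fixture graphs
#'
#' Small named graphs used throughout the test suite:
#' * `triangle`: 3-clique (every node has one connected neighbour pair).
#' * `star3`: a centre with three leaves and no leaf-leaf links.
#' * `square4`: the 4-cycle a-b-c-d-a.
#' * `wmi4`: the 4-node worked example for the mutual-information score:
#'   links a-c (1), b-c (2), a-d (1), b-d (1), c-d (3); with the whole
#'   graph as training set, s_ab = 2 log2(4/5) under raw smoothing and
#'   the alpha = 1 WMI-WCN score is 5 log2(4/5).
#' * `cliques45`: disjoint union of a 4-clique and a 5-clique (every
#'   neighbourhood is a clique, so C_z = 1 everywhere and the
#'   mutual-information ranking degenerates to common-neighbour counting).
#'
#' @return named list of [wgraph] objects.
#' @export
fixture_suite <- function() {
  ef <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    wgraph(data.frame(from = m[, 1], to = m[, 2],
                      weight = as.numeric(m[, 3])))
  }
  cl45 <- {
    p4 <- t(utils::combn(paste0("p", 1:4), 2))
    p5 <- t(utils::combn(paste0("q", 1:5), 2))
    wgraph(data.frame(from = c(p4[, 1], p5[, 1]), to = c(p4[, 2], p5[, 2]),
                      weight = 1))
  }
  list(
    triangle = ef("a", "b", 1, "b", "c", 1, "a", "c", 1),
    star3 = ef("hub", "l1", 1, "hub", "l2", 2, "hub", "l3", 3),
    square4 = ef("a", "b", 1, "b", "c", 1, "c", "d", 1, "d", "a", 1),
    wmi4 = ef("a", "c", 1, "b", "c", 2, "a", "d", 1, "b", "d", 1, "c", "d", 3),
    cliques45 = cl45
  )
}
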