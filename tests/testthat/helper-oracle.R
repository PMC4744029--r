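# Brute-force oracle: literal, loop-based reimplementation of every score
# on a plain edge data frame (from, to, weight). Deliberately independent
# of the package internals -- only base R, sets enumerated element by
# element, C_z recomputed by scanning all node pairs.

o_nodes <- function(ed, extra = NULL) sort(unique(c(ed$from, ed$to, extra)))

o_neigh <- function(ed, x) {
  sort(unique(c(ed$to[ed$from == x], ed$from[ed$to == x])))
}

o_has_edge <- function(ed, x, y) {
  any((ed$from == x & ed$to == y) | (ed$from == y & ed$to == x))
}

o_weight <- function(ed, x, y) {
  ed$weight[(ed$from == x & ed$to == y) | (ed$from == y & ed$to == x)][1]
}

o_strength <- function(ed, z, alpha = 1) {
  nb <- o_neigh(ed, z)
  if (length(nb) == 0) return(0)
  sum(vapply(nb, function(u) o_weight(ed, z, u)^alpha, numeric(1)))
}

# N_triangle / N_wedge for node z by scanning every unordered node pair.
o_pair_counts <- function(ed, z, nodes) {
  others <- setdiff(nodes, z)
  ncon <- ndis <- 0
  if (length(others) >= 2) {
    for (a in seq_len(length(others) - 1)) {
      for (b in seq.int(a + 1, length(others))) {
        u <- others[a]; v <- others[b]
        if (o_has_edge(ed, z, u) && o_has_edge(ed, z, v)) {
          if (o_has_edge(ed, u, v)) ncon <- ncon + 1 else ndis <- ndis + 1
        }
      }
    }
  }
  c(ncon = ncon, ndis = ndis)
}

o_info <- function(ed, z, nodes, smoothing = "laplace", base = 2) {
  n <- length(nodes)
  prior <- -log(nrow(ed) / (n * (n - 1) / 2), base = base)
  ct <- o_pair_counts(ed, z, nodes)
  cz <- if (smoothing == "laplace") {
    (ct[["ncon"]] + 1) / (ct[["ncon"]] + ct[["ndis"]] + 2)
  } else {
    ct[["ncon"]] / (ct[["ncon"]] + ct[["ndis"]])
  }
  if (cz == 0) -1e9 else prior + log(cz, base = base)
}

o_score <- function(ed, x, y, family = "cn", weighted = TRUE, mi = FALSE,
                    alpha = 1, smoothing = "laplace", base = 2,
                    plain_strength = FALSE, nodes = NULL) {
  nodes <- o_nodes(ed, nodes)
  O <- intersect(o_neigh(ed, x), o_neigh(ed, y))
  total <- 0
  for (z in O) {
    if (family == "mi") {
      term <- 1
    } else {
      kern <- if (weighted) {
        o_weight(ed, x, z)^alpha + o_weight(ed, z, y)^alpha
      } else 1
      den <- if (family == "cn") {
        1
      } else {
        s <- if (weighted) {
          o_strength(ed, z, if (plain_strength) 1 else alpha)
        } else {
          length(o_neigh(ed, z))
        }
        if (family == "aa") log(1 + s) else s
      }
      term <- kern / den
    }
    if (mi || family == "mi") {
      term <- term * o_info(ed, z, nodes, smoothing, base)
    }
    total <- total + term
  }
  total
}

# Seeded random edge table on n nodes (labels shuffled letters so nothing
# depends on lexicographic-order accidents).
rand_edge_table <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    labels <- sample(paste0("n", sample(100, n)))
    pairs <- t(combn(labels, 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample(nrow(pairs), 2)] <- TRUE
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
               weight = exp(stats::rnorm(sum(keep), 0, 0.8)),
               stringsAsFactors = FALSE)
  })
}

rand_wgraph <- function(n, p = 0.4, seed = 1) {
  wgraph(rand_edge_table(n, p, seed))
}

# unordered-pair key for partition checks
tkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
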