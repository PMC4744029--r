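#' Undirected weighted graphs for link prediction
#'
#' A `wgraph` is an undirected simple graph G(V, E, W) with a strictly
#' positive weight on every link, stored as an [igraph::igraph] object with
#' named vertices and a `weight` edge attribute. Self-loops and multiple
#' links are not allowed; weights are symmetric by construction (each
#' unordered pair carries one weight).
#'
#' @param edges a data frame (or 3-column matrix) with columns `from`, `to`,
#'   `weight`. Node identifiers are coerced to character; they are opaque
#'   labels, not indices.
#' @param nodes optional character vector of node identifiers; must contain
#'   every endpoint in `edges`. Use it to declare isolated nodes.
#' @return a `wgraph` object.
#' @examples
#' g <- wgraph(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                        weight = c(2, 3)))
#' graph_neighbors(g, "b")
#' @export
wgraph <- function(edges, nodes = NULL) {
  if (is.matrix(edges)) {
    edges <- data.frame(from = edges[, 1], to = edges[, 2],
                        weight = as.numeric(edges[, 3]))
  }
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("from", "to", "weight") %in% names(edges))) {
    names(edges)[1:3] <- c("from", "to", "weight")
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- as.numeric(edges$weight)
  if (any(from == to)) {
    stop("self-loops are not allowed: ", paste(unique(from[from == to]), collapse = ", "))
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("all link weights must be finite and strictly positive")
  }
  key <- pair_key(from, to)
  if (anyDuplicated(key)) {
    stop("duplicate links: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  nodes <- if (is.null(nodes)) sort(unique(c(from, to))) else as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  missing <- setdiff(unique(c(from, to)), nodes)
  if (length(missing) > 0) {
    stop("edge endpoints absent from `nodes`: ", paste(missing, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  as_wgraph(g)
}

#' Coerce an igraph object to a validated `wgraph`
#'
#' @param g an undirected [igraph::igraph] with a strictly positive `weight`
#'   edge attribute (a missing attribute is filled with unit weights) and,
#'   ideally, vertex names; unnamed vertices are labelled by their index.
#' @return a `wgraph` object.
#' @export
as_wgraph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  if (is.null(igraph::E(g)$weight) && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- 1
  }
  if (!inherits(g, "wgraph")) class(g) <- c("wgraph", class(g))
  validate_wgraph(g)
  g
}

#' Validate the weighted-graph invariants
#'
#' Checks that the graph is undirected and simple (no self-loops, no
#' multiple links), that every vertex is named, and that every weight is
#' finite and strictly positive.
#'
#' @param g a `wgraph`.
#' @return `g`, invisibly; errors on the first violated invariant.
#' @export
validate_wgraph <- function(g) {
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (any(igraph::which_loop(g))) stop("self-loops are not allowed")
  if (any(igraph::which_multiple(g))) stop("multiple links are not allowed")
  if (is.null(igraph::V(g)$name) || anyDuplicated(igraph::V(g)$name)) {
    stop("vertices must carry unique names")
  }
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    if (is.null(w)) stop("edges must carry a `weight` attribute")
    if (any(!is.finite(w)) || any(w <= 0)) {
      stop("all link weights must be finite and strictly positive")
    }
  }
  invisible(g)
}

#' @export
#' @rdname wgraph
is_wgraph <- function(x) inherits(x, "wgraph")

#' @export
print.wgraph <- function(x, ...) {
  cat(sprintf("<wgraph> %d nodes, %d weighted links\n",
              igraph::vcount(x), igraph::ecount(x)))
  if (igraph::ecount(x) > 0) {
    w <- igraph::E(x)$weight
    cat(sprintf("  weights: min %.4g, median %.4g, max %.4g\n",
                min(w), stats::median(w), max(w)))
  }
  invisible(x)
}

#' Node identifiers of a graph
#' @param g a `wgraph`.
#' @return character vector of node names.
#' @export
graph_nodes <- function(g) igraph::V(g)$name

#' Edge table of a graph
#' @param g a `wgraph`.
#' @return data frame with columns `from`, `to`, `weight`; each unordered
#'   pair appears once with `from < to` lexicographically.
#' @export
graph_edges <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  lo <- pmin(ends[, 1], ends[, 2])
  hi <- pmax(ends[, 1], ends[, 2])
  data.frame(from = lo, to = hi, weight = igraph::E(g)$weight,
             stringsAsFactors = FALSE)
}

#' Number of possible node pairs
#'
#' The candidate-pair universe size M = |V| (|V| - 1) / 2, computable from
#' the node set alone.
#'
#' @param g a `wgraph`.
#' @return integer-valued numeric.
#' @export
n_possible_pairs <- function(g) {
  n <- igraph::vcount(g)
  n * (n - 1) / 2
}

.check_node <- function(g, v) {
  bad <- setdiff(v, graph_nodes(g))
  if (length(bad) > 0) stop("unknown node(s): ", paste(bad, collapse = ", "))
}

#' Neighbourhood of a node
#'
#' Gamma(x), the set of nodes adjacent to `x`. Never contains `x` itself.
#'
#' @param g a `wgraph`.
#' @param x a node identifier.
#' @return character vector of neighbour names (possibly empty).
#' @export
graph_neighbors <- function(g, x) {
  .check_node(g, x)
  igraph::neighbors(g, x)$name
}

#' Common neighbours of a node pair
#'
#' O_xy = Gamma(x) intersect Gamma(y). The endpoints themselves are never
#' members (the graph has no self-loops).
#'
#' @param g a `wgraph`.
#' @param x,y distinct node identifiers.
#' @return character vector of common neighbour names (possibly empty).
#' @export
common_neighbors <- function(g, x, y) {
  .check_node(g, c(x, y))
  if (x == y) stop("x and y must be distinct")
  intersect(igraph::neighbors(g, x)$name, igraph::neighbors(g, y)$name)
}

#' Link weight of an existing edge
#' @param g a `wgraph`.
#' @param x,y node identifiers joined by a link.
#' @return the weight W_xy.
#' @export
edge_weight <- function(g, x, y) {
  .check_node(g, c(x, y))
  eid <- igraph::get_edge_ids(g, c(x, y))
  if (eid == 0) stop("no link between ", x, " and ", y)
  igraph::E(g)$weight[eid]
}

#' Node strength with a weak-tie exponent
#'
#' S_z = sum over neighbours z' of W_zz'^alpha. `alpha = 1` gives the plain
#' strength (sum of incident weights); `alpha = 0` gives the degree.
#'
#' @param g a `wgraph`.
#' @param z a node identifier.
#' @param alpha finite real exponent applied to each incident weight.
#' @return non-negative real; 0 for an isolated node.
#' @export
node_strength <- function(g, z, alpha = 1) {
  .check_node(g, z)
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha))
  eid <- igraph::incident(g, z)
  if (length(eid) == 0) return(0)
  sum(igraph::E(g)$weight[as.integer(eid)]^alpha)
}

# Sparse adjacency (binary) and weight matrices, general Csparse form so the
# scoring engine can take element-wise powers of the @x slot directly.
wg_matrices <- function(g) {
  n <- igraph::vcount(g)
  nm <- graph_nodes(g)
  ed <- graph_edges(g)
  i <- match(ed$from, nm)
  j <- match(ed$to, nm)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(ed$weight, 2),
                            dims = c(n, n), dimnames = list(nm, nm))
  A <- W
  if (length(A@x) > 0) A@x[] <- 1
  list(A = A, W = W, names = nm)
}

# Unordered-pair keys; "\r" never occurs in node identifiers read from the
# line-oriented formats.
pair_key <- function(x, y) {
  paste(pmin(x, y), pmax(x, y), sep = "\r")
}

#' All node pairs not linked in a graph
#'
#' The candidate universe for link prediction: every unordered pair of
#' distinct nodes without a link, over the full node set (nodes isolated in
#' the graph are included).
#'
#' @param g a `wgraph`.
#' @return data frame with columns `from`, `to`.
#' @export
all_nonedges <- function(g) {
  nm <- graph_nodes(g)
  n <- length(nm)
  A <- wg_matrices(g)$A
  Ad <- as.matrix(A) != 0
  idx <- which(upper.tri(Ad) & !Ad, arr.ind = TRUE)
  data.frame(from = nm[idx[, 1]], to = nm[idx[, 2]], stringsAsFactors = FALSE)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so exported functions are pure in their `seed` argument.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
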