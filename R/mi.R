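# Finite stand-in for -Inf when smoothing = "raw" meets C_z = 0: keeps the
# matrix algebra NaN-free while still ranking any affected pair below every
# finite-scored pair. Value is in score units (typical |info| is tens).
MI_SENTINEL <- -1e9

#' Mutual-information context of a training graph
#'
#' Precomputes, once per training graph, everything the mutual-information
#' score needs: the pair universe size M = |V|(|V|-1)/2, the number of
#' training links M^T, and for every node z the counts of connected
#' (N_tri) and disconnected (N_wedge) unordered pairs among its
#' neighbours. From these come the clustering coefficient
#' C_z = N_tri / (N_tri + N_wedge) -- the estimate of the conditional
#' connection probability p(L1 | z) -- and the per-neighbour information
#' contribution I(L1; z) = -log(M^T / M) + log(C_z).
#'
#' Counts are global per node, computed on the training graph only, and
#' never adjusted per scored pair (the pair being scored is itself one of
#' the disconnected pairs counted in N_wedge).
#'
#' @param g_train a non-empty [wgraph]: the training graph.
#' @param smoothing `"laplace"` (default) uses C_z = (N_tri + 1) /
#'   (N_tri + N_wedge + 2), which keeps every contribution finite;
#'   `"raw"` uses the bare ratio, in which case C_z = 0 yields a large
#'   negative sentinel contribution (such pairs rank below all
#'   finite-scored pairs).
#' @param log_base base for all logarithms (default 2: bits).
#' @return an `mi_context` with fields `m_total`, `m_train`, `n_conn`,
#'   `n_disc`, `c_z` (named per node), `prior` and `info` (named vector of
#'   I(L1; z)).
#' @export
mi_context <- function(g_train, smoothing = c("laplace", "raw"), log_base = 2) {
  smoothing <- match.arg(smoothing)
  stopifnot(is_wgraph(g_train))
  if (igraph::vcount(g_train) < 2) stop("training graph needs at least 2 nodes")
  mats <- wg_matrices(g_train)
  A <- mats$A
  n <- nrow(A)
  d <- Matrix::rowSums(A)
  m_total <- n * (n - 1) / 2
  m_train <- igraph::ecount(g_train)
  if (m_train == 0) stop("training graph has no links: prior information undefined")
  npairs <- d * (d - 1) / 2
  # edges among the neighbours of z = triangles through z = diag(A^3)/2
  tri <- Matrix::rowSums(A * (A %*% A)) / 2
  c_z <- if (smoothing == "laplace") {
    (tri + 1) / (npairs + 2)
  } else {
    ifelse(npairs > 0, tri / npairs, NA_real_)
  }
  prior <- -log(m_train / m_total, base = log_base)
  info <- prior + log(c_z, base = log_base)
  info[!is.finite(info) & !is.na(c_z) & c_z == 0] <- MI_SENTINEL
  info[d < 2] <- 0  # such nodes can never be common neighbours
  names(info) <- names(c_z) <- mats$names
  structure(list(m_total = m_total, m_train = m_train,
                 n_conn = stats::setNames(tri, mats$names),
                 n_disc = stats::setNames(npairs - tri, mats$names),
                 c_z = c_z, smoothing = smoothing, log_base = log_base,
                 prior = prior, info = info),
            class = "mi_context")
}

#' @export
print.mi_context <- function(x, ...) {
  cat(sprintf(
    "<mi_context> M=%g, M^T=%d, prior I(L1)=%.4g (base %g), smoothing=%s\n",
    x$m_total, x$m_train, x$prior, x$log_base, x$smoothing))
  invisible(x)
}

#' Prior self-information of a link
#'
#' I(L1) = -log(M^T / M): the information content of the event that a
#' uniformly chosen node pair is linked in the training graph. Always
#' non-negative.
#'
#' @param ctx an [mi_context()].
#' @return a single non-negative numeric, in units of `ctx$log_base`.
#' @export
prior_information <- function(ctx) {
  stopifnot(inherits(ctx, "mi_context"))
  if (ctx$m_train == 0) stop("no training links: prior undefined")
  ctx$prior
}

#' Conditional self-information given a common neighbour
#'
#' I(L1 | z) = -log(C_z), the uncertainty that a pair is linked given that
#' z is one of its common neighbours, estimated through z's clustering
#' coefficient. Under `smoothing = "raw"` a node with no linked neighbour
#' pairs (C_z = 0) yields `Inf`; callers map it to a finite sentinel.
#'
#' @param ctx an [mi_context()].
#' @param z a node identifier with degree >= 2 in the training graph (a
#'   node of smaller degree can never be a common neighbour).
#' @return a single non-negative numeric (possibly `Inf` under raw
#'   smoothing).
#' @export
conditional_information <- function(ctx, z) {
  stopifnot(inherits(ctx, "mi_context"))
  if (!z %in% names(ctx$c_z)) stop("unknown node: ", z)
  if (ctx$n_conn[[z]] + ctx$n_disc[[z]] < 1) {
    stop("node ", z, " has degree < 2 in the training graph")
  }
  -log(ctx$c_z[[z]], base = ctx$log_base)
}

#' Mutual-information score of a node pair
#'
#' s_xy = sum over common neighbours z of I(L1; z), with
#' I(L1; z) = I(L1) - I(L1 | z) = -log(M^T/M) + log(C_z). A pair without
#' common neighbours scores 0.
#'
#' @param g_train a [wgraph]: the training graph.
#' @param x,y distinct node identifiers.
#' @param ctx an [mi_context()] built on `g_train`; built on the fly if
#'   omitted.
#' @return an `mi_score`: list with `value` (the score) and `per_neighbor`
#'   (named vector of I(L1; z) contributions, summing exactly to `value`).
#' @export
mi_score <- function(g_train, x, y, ctx = NULL) {
  if (is.null(ctx)) ctx <- mi_context(g_train)
  O <- common_neighbors(g_train, x, y)
  per <- if (length(O) > 0) ctx$info[O] else stats::setNames(numeric(0), character(0))
  structure(list(value = sum(per), per_neighbor = per, x = x, y = y),
            class = "mi_score")
}

#' @export
print.mi_score <- function(x, ...) {
  cat(sprintf("<mi_score> s(%s,%s) = %.6g over %d common neighbour(s)\n",
              x$x, x$y, x$value, length(x$per_neighbor)))
  invisible(x)
}

#' Weight-fused mutual-information score of a node pair
#'
#' s_xy = sum over common neighbours z of f(W_xz, W_zy) I(L1; z), where f
#' is the per-neighbour kernel of the configured family at exponent alpha
#' (see [index_config()]). With `alpha = 1` these are the pure WMI-WCN /
#' WMI-WAA / WMI-WRA indices.
#'
#' @param g_train a [wgraph]: the training graph.
#' @param x,y distinct node identifiers.
#' @param ctx an [mi_context()] built on `g_train`; built on the fly if
#'   omitted.
#' @param cfg an [index_config()] with `mi = TRUE`.
#' @return a single numeric score.
#' @export
wmi_score <- function(g_train, x, y, ctx = NULL, cfg = index_config("cn", mi = TRUE)) {
  stopifnot(inherits(cfg, "index_config"))
  if (!cfg$mi) stop("wmi_score requires an mi-fused index_config (mi = TRUE)")
  score_pair(g_train, x, y, cfg, ctx = ctx)
}
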