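#' Configure a local similarity index
#'
#' Selects one member of the index families implemented here:
#'
#' * `family = "cn"`, `"aa"`, `"ra"` with `weighted = FALSE`: the classical
#'   unweighted indices. CN counts common neighbours |O_xy|; AA sums
#'   1/log(1 + d_z) and RA sums 1/d_z over common neighbours z (the
#'   alpha = 0 limit of the weighted forms, divided by 2).
#' * `weighted = TRUE`: the weighted, weak-tie-parameterised forms
#'   WCN_a = sum (W_xz^a + W_zy^a), WAA_a with denominator log(1 + S_z),
#'   WRA_a with denominator S_z, where S_z = sum W_zz'^a is the
#'   alpha-powered strength. `alpha = 1` gives the plainly weighted
#'   indices; `alpha = 0` recovers the unweighted rankings.
#' * `mi = TRUE` fuses the family's per-neighbour weight kernel f(W_xz,
#'   W_zy) with the mutual-information contribution I(L1;z) of each common
#'   neighbour (the WMI family); `alpha = 1` gives the pure WMI indices.
#' * `family = "mi"`: the bare mutual-information score, no weight kernel.
#'
#' @param family `"cn"`, `"aa"`, `"ra"`, or `"mi"`.
#' @param weighted use link weights (ignored for `family = "mi"`).
#' @param mi fuse with the mutual-information contribution of each common
#'   neighbour; requires `weighted = TRUE`.
#' @param alpha finite weak-tie exponent applied to each link weight;
#'   `alpha < 1` amplifies weak ties, `alpha > 1` suppresses them.
#' @param smoothing estimator for the clustering coefficient C_z feeding
#'   the conditional information (see [mi_context()]): `"laplace"`
#'   (default, add-one) or `"raw"`.
#' @param log_base base of all logarithms in the information terms; the
#'   induced rankings are base-invariant, so this is presentation only.
#' @param plain_strength if `TRUE`, S_z in the AA/RA denominators is the
#'   plain (alpha = 1) strength rather than the alpha-powered strength;
#'   reproduces the literal typography of the parameterised WMI-WAA /
#'   WMI-WRA definitions.
#' @return an `index_config` object.
#' @export
index_config <- function(family = c("cn", "aa", "ra", "mi"), weighted = TRUE,
                         mi = FALSE, alpha = 1,
                         smoothing = c("laplace", "raw"), log_base = 2,
                         plain_strength = FALSE) {
  family <- match.arg(family)
  smoothing <- match.arg(smoothing)
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(log_base), length(log_base) == 1, log_base > 0,
            log_base != 1)
  if (family == "mi") {
    weighted <- FALSE
    mi <- TRUE
  }
  if (mi && family != "mi" && !weighted) {
    stop("mi-fused indices require weighted = TRUE (use family = \"mi\" for the bare score)")
  }
  structure(list(family = family, weighted = isTRUE(weighted),
                 mi = isTRUE(mi), alpha = alpha, smoothing = smoothing,
                 log_base = log_base, plain_strength = isTRUE(plain_strength)),
            class = "index_config")
}

#' @export
print.index_config <- function(x, ...) {
  label <- if (x$family == "mi") {
    "MI"
  } else {
    paste0(if (x$mi) "WMI-" else "", if (x$weighted) "W" else "",
           toupper(x$family), if (x$weighted) sprintf("(alpha=%g)", x$alpha))
  }
  cat("<index_config>", label,
      if (x$mi) sprintf("[smoothing=%s, log base %g]", x$smoothing, x$log_base),
      "\n")
  invisible(x)
}

# Label used in CLI/JSON output.
config_label <- function(cfg) {
  if (cfg$family == "mi") return("mi")
  paste0(if (cfg$mi) "wmi-" else "", if (cfg$weighted) "w" else "",
         cfg$family, if (cfg$weighted) sprintf("_alpha=%g", cfg$alpha))
}

.needs_ctx <- function(cfg) isTRUE(cfg$mi) || cfg$family == "mi"

#' Score a single node pair
#'
#' Reference per-pair implementation: enumerates the common neighbours of
#' the pair and accumulates the configured per-neighbour term. The bulk
#' scorer [score_candidates()] uses an algebraically identical sparse
#' matrix formulation; the two are tested against each other.
#'
#' Scoring an existing link is permitted (useful for diagnostics); an empty
#' common-neighbour set gives score 0 for every configuration.
#'
#' @param g a [wgraph] (the training graph: all structural quantities,
#'   including the mutual-information context, come from it alone).
#' @param x,y distinct node identifiers.
#' @param cfg an [index_config()].
#' @param ctx optional [mi_context()] built on `g`; computed on the fly when
#'   needed and not supplied.
#' @return a single numeric score s_xy.
#' @export
score_pair <- function(g, x, y, cfg, ctx = NULL) {
  stopifnot(inherits(cfg, "index_config"))
  O <- common_neighbors(g, x, y)
  if (length(O) == 0) return(0)
  if (.needs_ctx(cfg) && is.null(ctx)) {
    ctx <- mi_context(g, smoothing = cfg$smoothing, log_base = cfg$log_base)
  }
  info <- if (.needs_ctx(cfg)) unname(ctx$info[O]) else rep(1, length(O))
  if (cfg$family == "mi") return(sum(info))
  kern <- if (cfg$weighted) {
    wxz <- vapply(O, function(z) edge_weight(g, x, z), numeric(1))
    wzy <- vapply(O, function(z) edge_weight(g, z, y), numeric(1))
    wxz^cfg$alpha + wzy^cfg$alpha
  } else rep(1, length(O))
  denom <- switch(cfg$family,
    cn = rep(1, length(O)),
    aa = {
      s <- vapply(O, function(z) {
        if (cfg$weighted) {
          node_strength(g, z, if (cfg$plain_strength) 1 else cfg$alpha)
        } else length(graph_neighbors(g, z))
      }, numeric(1))
      log(1 + s)
    },
    ra = vapply(O, function(z) {
      if (cfg$weighted) {
        node_strength(g, z, if (cfg$plain_strength) 1 else cfg$alpha)
      } else length(graph_neighbors(g, z))
    }, numeric(1)))
  sum(kern / denom * info)
}

# Full score matrix over all node pairs, dense, via sparse matrix algebra.
# For the weighted families the per-neighbour term splits as
#   (W_xz^a + W_zy^a) g_z i_z = W_xz^a (g i)_z A_zy + A_xz (g i)_z W_zy^a,
# so the score matrix is Wa D A + A D Wa with D = diag(g_z i_z); the
# unweighted families and the bare MI score are A D A.
score_matrix <- function(g, cfg, ctx = NULL, mats = NULL) {
  stopifnot(inherits(cfg, "index_config"))
  if (is.null(mats)) mats <- wg_matrices(g)
  A <- mats$A
  n <- nrow(A)
  d <- Matrix::rowSums(A)
  if (.needs_ctx(cfg)) {
    if (is.null(ctx)) {
      ctx <- mi_context(g, smoothing = cfg$smoothing, log_base = cfg$log_base)
    }
    info <- unname(ctx$info[mats$names])
  } else {
    info <- rep(1, n)
  }
  if (cfg$family == "mi" || !cfg$weighted) {
    gz <- switch(cfg$family,
      mi = rep(1, n),
      cn = rep(1, n),
      aa = ifelse(d > 0, 1 / log(1 + d), 0),
      ra = ifelse(d > 0, 1 / d, 0))
    D <- Matrix::Diagonal(n, x = gz * info)
    S <- A %*% D %*% A
  } else {
    Wa <- mats$W
    if (length(Wa@x) > 0) Wa@x <- Wa@x^cfg$alpha
    Sv <- if (cfg$plain_strength) Matrix::rowSums(mats$W) else Matrix::rowSums(Wa)
    gz <- switch(cfg$family,
      cn = rep(1, n),
      aa = ifelse(d > 0, 1 / log(1 + Sv), 0),
      ra = ifelse(d > 0, 1 / Sv, 0))
    D <- Matrix::Diagonal(n, x = gz * info)
    S <- Wa %*% D %*% A + A %*% D %*% Wa
  }
  S <- as.matrix(S)
  diag(S) <- 0
  dimnames(S) <- list(mats$names, mats$names)
  S
}

#' Score a set of candidate node pairs
#'
#' Applies the configured index to each pair. Deterministic given its
#' inputs; identical to calling [score_pair()] on every pair, but computed
#' with one sparse-matrix pass.
#'
#' @param g a [wgraph] (training graph).
#' @param candidates data frame (or 2-column matrix) of node pairs; columns
#'   `from`, `to`. Typically [all_nonedges()] of the training graph.
#' @param cfg an [index_config()].
#' @param ctx optional [mi_context()] built on `g`.
#' @return `candidates` with a numeric `score` column appended.
#' @export
score_candidates <- function(g, candidates, cfg, ctx = NULL) {
  if (is.matrix(candidates)) {
    candidates <- data.frame(from = candidates[, 1], to = candidates[, 2],
                             stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0) {
    return(cbind(candidates, score = numeric(0)))
  }
  from <- as.character(candidates[[1]])
  to <- as.character(candidates[[2]])
  .check_node(g, unique(c(from, to)))
  if (any(from == to)) stop("candidate pairs must have distinct endpoints")
  S <- score_matrix(g, cfg, ctx)
  nm <- rownames(S)
  out <- data.frame(from = from, to = to,
                    score = S[cbind(match(from, nm), match(to, nm))],
                    stringsAsFactors = FALSE)
  out
}
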