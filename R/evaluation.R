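# Seeds for subsidiary RNG streams, drawn reproducibly from a master seed.
# Kept below 2^31 - 1 (R integers are 32-bit).
.draw_seeds <- function(seed, n, k) {
  with_seed(seed, matrix(sample.int(2147483646L, n * k), nrow = n, ncol = k))
}

#' Random division of links into training and probe sets
#'
#' Uniformly samples `round(probe_fraction * |E|)` links as the probe set
#' E^P; the remaining links, with their weights, form the training graph
#' E^T. The node set is unchanged (nodes isolated in training remain).
#' E^T and E^P partition E.
#'
#' @param g a [wgraph] with at least 2 links.
#' @param probe_fraction fraction of links to hide, strictly between 0
#'   and 1 (the standard protocol hides 10 percent).
#' @param seed integer seed making the split a pure function of its
#'   arguments; `NULL` uses the current RNG state.
#' @return a `link_split`: list with `train` (a [wgraph]), `probe` (data
#'   frame `from`, `to`, `weight`), `probe_fraction`, `seed`.
#' @export
random_split <- function(g, probe_fraction = 0.1, seed = NULL) {
  stopifnot(is_wgraph(g))
  m <- igraph::ecount(g)
  if (m < 2) stop("graph needs at least 2 links to split")
  if (!is.numeric(probe_fraction) || length(probe_fraction) != 1 ||
      probe_fraction <= 0 || probe_fraction >= 1) {
    stop("probe_fraction must lie strictly between 0 and 1")
  }
  n_probe <- round(probe_fraction * m)
  idx <- if (is.null(seed)) {
    sample.int(m, n_probe)
  } else {
    with_seed(seed, sample.int(m, n_probe))
  }
  ed <- graph_edges(g)
  train <- as_wgraph(igraph::delete_edges(g, idx))
  structure(list(train = train, probe = ed[sort(idx), , drop = FALSE],
                 probe_fraction = probe_fraction, seed = seed),
            class = "link_split")
}

#' @export
print.link_split <- function(x, ...) {
  cat(sprintf("<link_split> %d training links / %d probe links (fraction %g)\n",
              igraph::ecount(x$train), nrow(x$probe), x$probe_fraction))
  invisible(x)
}

# Three-way edge partition (training / validation / test) by a random
# permutation; sizes are round(p * m) with the last part absorbing the
# remainder.
.split3 <- function(g, proportions, seed) {
  m <- igraph::ecount(g)
  stopifnot(length(proportions) == 3, all(proportions > 0),
            abs(sum(proportions) - 1) < 1e-8)
  sizes <- round(proportions[1:2] * m)
  sizes <- c(sizes, m - sum(sizes))
  if (any(sizes < 1)) stop("graph too small for the requested proportions")
  perm <- with_seed(seed, sample.int(m))
  groups <- split(perm, rep(1:3, times = sizes))
  ed <- graph_edges(g)
  list(train = as_wgraph(igraph::delete_edges(g, c(groups[[2]], groups[[3]]))),
       fused = as_wgraph(igraph::delete_edges(g, groups[[3]])),
       validation = ed[sort(groups[[2]]), , drop = FALSE],
       test = ed[sort(groups[[3]]), , drop = FALSE])
}

#' Precision among the top-L ranked candidates
#'
#' Precision = L_r / L, where L_r is the number of probe links among the L
#' top-ranked candidate pairs.
#'
#' @param ranked data frame (or 2-column matrix) of node pairs sorted by
#'   descending score with ties already resolved.
#' @param probe data frame of probe pairs (`from`, `to`).
#' @param L number of top candidates treated as predicted links; `ranked`
#'   must contain at least L pairs.
#' @return precision in \[0, 1\].
#' @export
precision_at <- function(ranked, probe, L) {
  if (is.matrix(ranked)) ranked <- data.frame(from = ranked[, 1], to = ranked[, 2])
  stopifnot(is.data.frame(ranked), L >= 1)
  if (nrow(ranked) < L) {
    stop(sprintf("only %d ranked candidates for L = %d", nrow(ranked), L))
  }
  top <- pair_key(as.character(ranked[[1]][seq_len(L)]),
                  as.character(ranked[[2]][seq_len(L)]))
  hits <- top %in% pair_key(as.character(probe[[1]]), as.character(probe[[2]]))
  sum(hits) / L
}

#' Rank scored candidates, breaking ties at random
#'
#' Sorts by descending score. Pairs with exactly equal scores are permuted
#' uniformly at random (integer-valued indices such as CN produce large tie
#' groups; a deterministic tie order would bias precision).
#'
#' @param scored data frame with columns `from`, `to`, `score`
#'   (as returned by [score_candidates()]).
#' @param tie_seed integer seed for the tie permutation; `NULL` uses the
#'   current RNG state.
#' @return `scored`, reordered; the full ranking (truncation is the
#'   caller's choice).
#' @export
rank_candidates <- function(scored, tie_seed = NULL) {
  stopifnot(is.data.frame(scored), "score" %in% names(scored))
  n <- nrow(scored)
  if (n == 0) return(scored)
  tie_key <- if (is.null(tie_seed)) sample.int(n) else with_seed(tie_seed, sample.int(n))
  scored[order(-scored$score, tie_key), , drop = FALSE]
}

# One split evaluated for several index configurations with shared
# candidates and a shared tie permutation (paired design). Returns the
# precision vector, one entry per configuration.
.eval_run <- function(train, probe, cfgs, L, tie_seed) {
  mats <- wg_matrices(train)
  n <- length(mats$names)
  Alog <- as.matrix(mats$A) != 0
  cand <- which(upper.tri(Alog) & !Alog)
  if (length(cand) < L) {
    stop(sprintf("candidate universe (%d non-edges) smaller than L = %d",
                 length(cand), L))
  }
  if (nrow(probe) < L) {
    warning(sprintf("probe set (%d links) smaller than L = %d: precision is bounded by %.3f",
                    nrow(probe), L, nrow(probe) / L), call. = FALSE)
  }
  pi <- match(as.character(probe$from), mats$names)
  pj <- match(as.character(probe$to), mats$names)
  is_probe <- logical(n * n)
  is_probe[(pmax(pi, pj) - 1) * n + pmin(pi, pj)] <- TRUE
  hit <- is_probe[cand]
  tie_key <- with_seed(tie_seed, sample.int(length(cand)))
  ctxs <- list()
  vapply(cfgs, function(cfg) {
    ctx <- NULL
    if (.needs_ctx(cfg)) {
      key <- paste(cfg$smoothing, cfg$log_base)
      if (is.null(ctxs[[key]])) {
        ctxs[[key]] <<- mi_context(train, smoothing = cfg$smoothing,
                                   log_base = cfg$log_base)
      }
      ctx <- ctxs[[key]]
    }
    sc <- score_matrix(train, cfg, ctx, mats)[cand]
    ord <- order(-sc, tie_key)
    sum(hit[ord[seq_len(L)]]) / L
  }, numeric(1))
}

# Repeated-run engine: `runs` independent splits, every configuration
# evaluated on the same splits with the same tie permutations.
evaluate_configs <- function(g, cfgs, runs, L, probe_fraction, seed) {
  seeds <- .draw_seeds(seed, runs, 2)
  prec <- matrix(NA_real_, nrow = runs, ncol = length(cfgs))
  for (r in seq_len(runs)) {
    sp <- random_split(g, probe_fraction, seed = seeds[r, 1])
    prec[r, ] <- .eval_run(sp$train, sp$probe, cfgs, L, seeds[r, 2])
  }
  attr(prec, "run_seeds") <- seeds
  prec
}

#' Evaluate one index under the train/probe protocol
#'
#' For each run: hide a random probe fraction of links, score every
#' non-edge of the training graph, rank, and record the precision among
#' the top L. Fully reproducible from `seed`.
#'
#' @param g a [wgraph]: the full observed network.
#' @param cfg an [index_config()].
#' @param runs number of independent random divisions (the standard
#'   protocol averages 100).
#' @param L size of the predicted link set (standard: 100).
#' @param probe_fraction fraction of links hidden per run (standard: 0.1).
#' @param seed master integer seed.
#' @return an `eval_result`: list with `precision_per_run`,
#'   `mean_precision`, `L`, `runs`, `seed`, `probe_fraction`, `config`,
#'   and `run_seeds` (the per-run split/tie seeds actually used).
#' @export
evaluate_index <- function(g, cfg, runs = 100, L = 100, probe_fraction = 0.1,
                           seed = 1) {
  stopifnot(inherits(cfg, "index_config"), runs >= 1)
  prec <- evaluate_configs(g, list(cfg), runs, L, probe_fraction, seed)
  structure(list(precision_per_run = as.numeric(prec),
                 mean_precision = mean(prec), L = L, runs = runs,
                 seed = seed, probe_fraction = probe_fraction, config = cfg,
                 run_seeds = attr(prec, "run_seeds")),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: mean precision %.4f over %d run(s) (L=%d, probe %g%%)\n",
              config_label(x$config), x$mean_precision, x$runs, x$L,
              100 * x$probe_fraction))
  invisible(x)
}

#' Grid sweep over the weak-tie exponent
#'
#' Evaluates one index family at every alpha in `grid`, using identical
#' splits and tie permutations across alpha values (a paired design, so
#' differences between grid points are not masked by split noise), and
#' reports the alpha attaining the highest mean precision. Exact ties are
#' broken toward the smallest |alpha|, then the smallest alpha.
#'
#' @param g a [wgraph].
#' @param family `"cn"`, `"aa"`, or `"ra"`.
#' @param grid numeric vector of alpha values, e.g. `seq(-5, 5, 0.01)`
#'   (coarse grids such as `seq(-2, 3, 0.25)` are much faster and usually
#'   suffice to locate the optimum region).
#' @param runs,L,probe_fraction,seed as in [evaluate_index()].
#' @param mi if `TRUE`, sweep the mi-fused (WMI) form of the family.
#' @param smoothing,log_base,plain_strength passed to [index_config()].
#' @return an `alpha_sweep`: list with `grid`, `mean_precision` (named by
#'   alpha), `alpha_star`, `precision_per_run` (runs x grid matrix), and
#'   the evaluation parameters.
#' @export
alpha_sweep <- function(g, family = c("cn", "aa", "ra"), grid = seq(-2, 3, 0.25),
                        runs = 10, L = 100, probe_fraction = 0.1, seed = 1,
                        mi = FALSE, smoothing = "laplace", log_base = 2,
                        plain_strength = FALSE) {
  family <- match.arg(family)
  stopifnot(length(grid) >= 1)
  cfgs <- lapply(grid, function(a) {
    index_config(family, weighted = TRUE, mi = mi, alpha = a,
                 smoothing = smoothing, log_base = log_base,
                 plain_strength = plain_strength)
  })
  prec <- evaluate_configs(g, cfgs, runs, L, probe_fraction, seed)
  means <- colMeans(prec)
  best <- order(-means, abs(grid), grid)[1]
  structure(list(grid = grid,
                 mean_precision = stats::setNames(means, format(grid)),
                 alpha_star = grid[best], precision_per_run = prec,
                 family = family, mi = mi, runs = runs, L = L,
                 probe_fraction = probe_fraction, seed = seed),
            class = "alpha_sweep")
}

#' @export
print.alpha_sweep <- function(x, ...) {
  cat(sprintf("<alpha_sweep> %s%s: alpha* = %g (mean precision %.4f; %d grid points, %d runs)\n",
              if (x$mi) "wmi-w" else "w", x$family, x$alpha_star,
              max(x$mean_precision), length(x$grid), x$runs))
  invisible(x)
}

#' Select the weak-tie exponent on a validation set
#'
#' The three-way protocol: links are divided into training, validation and
#' test parts (standard proportions 80/10/10 percent). For each run the
#' exponent alpha-hat maximising validation precision (scoring with the
#' training graph alone) is selected; test precision is then computed at
#' alpha-hat, by default after re-fusing training + validation links into
#' a 90 percent scoring graph (`refit = FALSE` keeps the bare 80 percent
#' graph).
#'
#' @param g a [wgraph].
#' @param family `"cn"`, `"aa"`, or `"ra"`.
#' @param grid numeric vector of candidate alpha values.
#' @param proportions length-3 positive vector summing to 1:
#'   (train, validation, test).
#' @param runs number of independent three-way divisions.
#' @param L predicted-set size.
#' @param seed master integer seed.
#' @param refit re-fuse training + validation links for the test scoring.
#' @param mi,smoothing,log_base,plain_strength passed to [index_config()].
#' @return an `alpha_validation`: list with per-run `alpha_hat` and
#'   `test_precision`, their means, and the parameters.
#' @export
select_alpha_validated <- function(g, family = c("cn", "aa", "ra"),
                                   grid = seq(-2, 3, 0.25),
                                   proportions = c(0.8, 0.1, 0.1),
                                   runs = 10, L = 100, seed = 1, refit = TRUE,
                                   mi = FALSE, smoothing = "laplace",
                                   log_base = 2, plain_strength = FALSE) {
  family <- match.arg(family)
  stopifnot(length(grid) >= 1, runs >= 1)
  cfg_at <- function(a) index_config(family, weighted = TRUE, mi = mi, alpha = a,
                                     smoothing = smoothing, log_base = log_base,
                                     plain_strength = plain_strength)
  cfgs <- lapply(grid, cfg_at)
  seeds <- .draw_seeds(seed, runs, 3)
  alpha_hat <- test_prec <- numeric(runs)
  for (r in seq_len(runs)) {
    parts <- .split3(g, proportions, seeds[r, 1])
    val_prec <- .eval_run(parts$train, parts$validation, cfgs, L, seeds[r, 2])
    alpha_hat[r] <- grid[order(-val_prec, abs(grid), grid)[1]]
    scoring_graph <- if (refit) parts$fused else parts$train
    test_prec[r] <- .eval_run(scoring_graph, parts$test,
                              list(cfg_at(alpha_hat[r])), L, seeds[r, 3])
  }
  structure(list(alpha_hat = alpha_hat, test_precision = test_prec,
                 mean_alpha_hat = mean(alpha_hat),
                 mean_test_precision = mean(test_prec),
                 family = family, mi = mi, grid = grid,
                 proportions = proportions, runs = runs, L = L, seed = seed,
                 refit = refit),
            class = "alpha_validation")
}

#' @export
print.alpha_validation <- function(x, ...) {
  cat(sprintf("<alpha_validation> %s%s: mean alpha-hat %.3g, mean test precision %.4f (%d runs)\n",
              if (x$mi) "wmi-w" else "w", x$family, x$mean_alpha_hat,
              x$mean_test_precision, x$runs))
  invisible(x)
}

#' Root-mean-square deviation between paired values
#'
#' `sqrt(mean((a - b)^2))`: used to compare precision under the
#' validation-estimated exponent with precision under the optimal exponent.
#'
#' @param a numeric vector, or a 2-column matrix / data frame of pairs.
#' @param b numeric vector paired with `a` (ignored when `a` is
#'   two-column).
#' @return a single non-negative numeric.
#' @export
rmsd <- function(a, b = NULL) {
  if (is.null(b)) {
    stopifnot(ncol(a) == 2)
    b <- a[, 2]
    a <- a[, 1]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  sqrt(mean((a - b)^2))
}
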