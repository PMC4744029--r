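test_that("neighbour-pair counts match hand enumeration", {
  fx <- fixture_suite()
  ctx <- mi_context(fx$triangle)
  for (z in c("a", "b", "c")) {
    expect_equal(ctx$n_conn[[z]], 1)
    expect_equal(ctx$n_disc[[z]], 0)
  }
  ctx <- mi_context(fx$star3)
  expect_equal(ctx$n_conn[["hub"]], 0)
  expect_equal(ctx$n_disc[["hub"]], 3)

  # c with neighbours {a, b, d}; (a,d) and (b,d) linked, (a,b) not
  g <- wgraph(data.frame(from = c("c", "c", "c", "a", "b"),
                         to = c("a", "b", "d", "d", "d"), weight = 1))
  ctx <- mi_context(g)
  expect_equal(ctx$n_conn[["c"]], 2)
  expect_equal(ctx$n_disc[["c"]], 1)
})

test_that("the counting identity holds on random graphs", {
  for (seed in 1:20) {
    g <- rand_wgraph(sample(5:12, 1), stats::runif(1, 0.2, 0.7), seed)
    ctx <- mi_context(g)
    for (z in graph_nodes(g)) {
      d <- length(graph_neighbors(g, z))
      expect_equal(ctx$n_conn[[z]] + ctx$n_disc[[z]], d * (d - 1) / 2)
    }
  }
})

test_that("prior information follows -log(M^T / M)", {
  # complete graph: every pair linked, no surprise left
  k4 <- wgraph(data.frame(from = t(combn(letters[1:4], 2))[, 1],
                          to = t(combn(letters[1:4], 2))[, 2], weight = 1))
  expect_equal(prior_information(mi_context(k4)), 0)
  # |V| = 4, M = 6, M^T = 3 -> 1 bit
  p3 <- wgraph(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"), weight = 1))
  expect_equal(prior_information(mi_context(p3)), 1)
  # |V| = 5, M = 10, M^T = 5 -> 1 bit
  c5 <- wgraph(data.frame(from = c("a", "b", "c", "d", "e"),
                          to = c("b", "c", "d", "e", "a"), weight = 1))
  expect_equal(prior_information(mi_context(c5)), 1)
  expect_equal(prior_information(mi_context(c5, log_base = exp(1))), log(2))
})

test_that("conditional information reflects the clustering coefficient", {
  fx <- fixture_suite()
  ctx <- mi_context(fx$triangle, smoothing = "raw")
  expect_equal(conditional_information(ctx, "a"), 0)
  g <- wgraph(data.frame(from = c("c", "c", "c", "a", "b"),
                         to = c("a", "b", "d", "d", "d"), weight = 1))
  expect_equal(conditional_information(mi_context(g, smoothing = "raw"), "c"),
               -log2(2 / 3))
  ctx <- mi_context(fx$star3, smoothing = "laplace")
  expect_equal(conditional_information(ctx, "hub"), -log2(1 / 5))
  expect_equal(conditional_information(mi_context(fx$star3, smoothing = "raw"), "hub"),
               Inf)
  expect_error(conditional_information(ctx, "l1"), "degree < 2")
})

test_that("the worked 4-node fixture reproduces its closed-form scores", {
  g <- fixture_suite()$wmi4
  ed <- graph_edges(g)
  ctx <- mi_context(g, smoothing = "raw")
  expected_mi <- 2 * log2(4 / 5)

  # brute-force oracle first
  expect_equal(o_score(ed, "a", "b", family = "mi", smoothing = "raw"),
               expected_mi, tolerance = 1e-12)
  s <- mi_score(g, "a", "b", ctx)
  expect_equal(s$value, expected_mi, tolerance = 1e-12)
  expect_setequal(names(s$per_neighbor), c("c", "d"))

  cfg <- index_config("cn", mi = TRUE, alpha = 1, smoothing = "raw")
  expected_wmi <- 5 * log2(4 / 5)
  expect_equal(o_score(ed, "a", "b", family = "cn", mi = TRUE, alpha = 1,
                       smoothing = "raw"), expected_wmi, tolerance = 1e-12)
  expect_equal(wmi_score(g, "a", "b", ctx, cfg), expected_wmi, tolerance = 1e-12)
})

test_that("mi_score decomposes into per-neighbour contributions and handles empty sets", {
  for (seed in 1:5) {
    g <- rand_wgraph(10, 0.4, seed)
    ctx <- mi_context(g)
    cand <- all_nonedges(g)
    for (r in seq_len(min(8, nrow(cand)))) {
      s <- mi_score(g, cand$from[r], cand$to[r], ctx)
      expect_identical(s$value, sum(s$per_neighbor))
    }
  }
  two <- wgraph(data.frame(from = c("a", "c"), to = c("b", "d"), weight = 1))
  expect_equal(mi_score(two, "a", "c")$value, 0)
})

test_that("mi and wmi scores match the brute-force oracle on random graphs", {
  for (seed in 1:8) {
    ed <- rand_edge_table(sample(6:12, 1), 0.45, seed)
    g <- wgraph(ed)
    cand <- all_nonedges(g)
    pick <- cand[withr::with_seed(seed, sample(nrow(cand), min(5, nrow(cand)))), ]
    for (sm in c("laplace", "raw")) {
      ctx <- mi_context(g, smoothing = sm)
      for (r in seq_len(nrow(pick))) {
        x <- pick$from[r]; y <- pick$to[r]
        expect_equal(mi_score(g, x, y, ctx)$value,
                     o_score(ed, x, y, family = "mi", smoothing = sm),
                     tolerance = 1e-9)
        for (fam in c("cn", "aa", "ra")) {
          cfg <- index_config(fam, mi = TRUE, alpha = 0.7, smoothing = sm)
          expect_equal(wmi_score(g, x, y, ctx, cfg),
                       o_score(ed, x, y, family = fam, mi = TRUE, alpha = 0.7,
                               smoothing = sm),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("clique neighbourhoods degenerate the MI ranking to CN", {
  g <- fixture_suite()$cliques45
  nodes <- graph_nodes(g)
  pairs <- as.data.frame(t(combn(nodes, 2)), stringsAsFactors = FALSE)
  names(pairs) <- c("from", "to")
  ctx <- mi_context(g, smoothing = "raw")
  mi <- score_candidates(g, pairs, index_config("mi", smoothing = "raw"), ctx)$score
  cn <- score_candidates(g, pairs, index_config("cn", weighted = FALSE))$score
  expect_equal(rank(mi), rank(cn))
  expect_equal(mi, cn * prior_information(ctx))
})

test_that("uniform weights make fused WMI rank-equal to the bare MI score", {
  ed <- rand_edge_table(11, 0.45, seed = 3)
  ed$weight <- 2.5
  g <- wgraph(ed)
  cand <- all_nonedges(g)
  ctx <- mi_context(g)
  base_rank <- rank(score_candidates(g, cand, index_config("mi"), ctx)$score)
  for (al in c(-1, 0, 0.5, 1, 2)) {
    fused <- score_candidates(g, cand, index_config("cn", mi = TRUE, alpha = al), ctx)$score
    expect_equal(rank(fused), base_rank)
  }
})

test_that("rankings are invariant to the logarithm base", {
  for (seed in 1:3) {
    g <- rand_wgraph(11, 0.45, seed)
    cand <- all_nonedges(g)
    ref <- NULL
    for (b in c(2, exp(1), 10)) {
      sc <- score_candidates(g, cand,
                             index_config("cn", mi = TRUE, alpha = 0.8, log_base = b))$score
      if (is.null(ref)) ref <- rank(sc) else expect_equal(rank(sc), ref)
    }
  }
})

test_that("raw smoothing sends C_z = 0 contributions below every finite score", {
  # hub's neighbourhood has no internal links (C_hub = 0); e-f share d,
  # whose neighbourhood does contain a link
  g <- wgraph(data.frame(
    from = c("hub", "hub", "hub", "d", "d", "e"),
    to = c("x", "y", "d", "e", "f", "f"), weight = 1))
  ctx_raw <- mi_context(g, smoothing = "raw")
  cfgm <- index_config("mi", smoothing = "raw")
  s_bad <- score_pair(g, "x", "y", cfgm, ctx_raw)   # only common neighbour: hub
  s_ok <- score_pair(g, "e", "f", cfgm, ctx_raw)    # only common neighbour: d
  expect_true(is.finite(s_bad))
  expect_lt(s_bad, -1e8)
  expect_gt(s_ok, s_bad)
  # laplace keeps everything finite and moderate
  ctx_lap <- mi_context(g)
  expect_gt(score_pair(g, "x", "y", index_config("mi"), ctx_lap), -100)
})
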