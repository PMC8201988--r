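# Graph construction, PageRank propagation, ranking, rewiring.

test_that("build_graph assembles vertices, weights, and collapsed edges", {
  tg <- make_test_graph(1, 2, rbind(c(1, 1), c(2, 1), c(2, 1)),
                        weights = c(2, 1, 1))
  expect_equal(igraph::vcount(tg$graph), 3)
  expect_equal(igraph::ecount(tg$graph), 2)  # duplicate collapsed
  expect_equal(igraph::V(tg$graph)$weight, c(2, 1, 1))
  expect_equal(sum(igraph::V(tg$graph)$type == "promoter"), 1)
  # PIR targeting two promoters has out-degree 2
  tg2 <- make_test_graph(2, 1, rbind(c(1, 1), c(1, 2)), weights = rep(1, 3))
  expect_equal(unname(igraph::degree(tg2$graph, "E1", mode = "out")), 2)
  # unknown endpoint is an error; missing score a warning
  prom <- data.frame(id = "P1", gene = "g1")
  pirs <- data.frame(id = "E1")
  expect_error(build_graph(prom, pirs,
                           data.frame(pir_id = "E9", promoter_id = "P1"),
                           c(P1 = 1, E1 = 1)), "unknown")
  expect_warning(g <- build_graph(prom, pirs,
                                  data.frame(pir_id = "E1",
                                             promoter_id = "P1"),
                                  c(P1 = 1)), "missing")
  expect_equal(igraph::V(g)$weight, c(1, 0))
})

test_that("pagerank matches hand-derivable fixed points", {
  # single weighted promoter holds all the mass
  tg <- make_test_graph(1, 0, NULL, weights = 5)
  gs <- pagerank_scores(tg$graph)
  expect_equal(unname(gs$gene["g1"]), 1)
  # two disconnected promoters split mass by weight, any damping
  tg2 <- make_test_graph(2, 0, NULL, weights = c(3, 1))
  for (d in c(0.3, 0.85, 0.99)) {
    gs2 <- pagerank_scores(tg2$graph, damping = d)
    expect_equal(unname(gs2$gene[c("g1", "g2")]), c(0.75, 0.25),
                 tolerance = 1e-9)
  }
  # star: two PIRs feeding one promoter; promoter accumulates most mass
  tg3 <- make_test_graph(1, 2, rbind(c(1, 1), c(2, 1)), weights = c(1, 2, 3))
  gs3 <- pagerank_scores(tg3$graph)
  expect_gt(gs3$gene["g1"], max(gs3$pagerank[c("E1", "E2")]))
  expect_error(pagerank_scores(tg3$graph, damping = 1.2), "damping")
  expect_warning(pagerank_scores(make_test_graph(1, 0, NULL, 0)$graph),
                 "zero")
})

test_that("pagerank matches the dense power-iteration oracle on small graphs", {
  set.seed(21)
  shapes <- expand.grid(n_prom = 1:3, n_pir = 0:3)
  for (si in seq_len(nrow(shapes))) {
    np <- shapes$n_prom[si]; ne <- shapes$n_pir[si]
    all_edges <- as.matrix(expand.grid(pir = seq_len(ne),
                                       prom = seq_len(np)))
    for (rep in 1:8) {
      keep <- if (nrow(all_edges)) which(runif(nrow(all_edges)) < 0.5) else
        integer()
      eidx <- all_edges[keep, , drop = FALSE]
      w <- sample(1:3, np + ne, replace = TRUE)
      tg <- make_test_graph(np, ne, eidx, w)
      gs <- pagerank_scores(tg$graph)
      oracle <- oracle_for(np, ne, eidx, w)
      expect_lt(max(abs(gs$pagerank[names(oracle)] - oracle)), 1e-9)
      expect_equal(sum(gs$pagerank), 1, tolerance = 1e-9)
    }
  }
})

test_that("zero-weight unconnected-to enhancers are neutral; weight is monotone", {
  eidx <- rbind(c(1, 1), c(2, 2))
  w0 <- c(2, 1, 1, 3)  # P1, P2, E1, E2
  base <- pagerank_scores(make_test_graph(2, 2, eidx, w0)$graph)
  # adding a zero-weight PIR feeding P1 leaves scores unchanged
  plus <- pagerank_scores(make_test_graph(2, 3, rbind(eidx, c(3, 1)),
                                          c(w0, 0))$graph)
  expect_lt(max(abs(plus$gene[c("g1", "g2")] - base$gene[c("g1", "g2")])),
            1e-9)
  # increasing one PIR's weight cannot decrease its target gene's score
  up <- pagerank_scores(make_test_graph(2, 2, eidx,
                                        c(2, 1, 5, 3))$graph)
  expect_gte(up$gene["g1"], base$gene["g1"])
})

test_that("rank_genes is descending with lexicographic tie-breaks", {
  r <- rank_genes(c(B = 0.3, A = 0.5))
  expect_equal(r$gene, c("A", "B"))
  expect_equal(r$rank, 1:2)
  r2 <- rank_genes(c(B = 0.4, A = 0.4))
  expect_equal(r2$gene, c("A", "B"))
  r3 <- rank_genes(c(B = 0.4, A = 0.5, C = 0.1) * 7)
  expect_equal(r3$gene, rank_genes(c(B = 0.4, A = 0.5, C = 0.1))$gene)
})

test_that("promoter-only ranking equals network ranking on edgeless graphs", {
  prom <- data.frame(id = paste0("P", 1:4), gene = paste0("g", 1:4))
  scores <- c(P1 = 4, P2 = 1, P3 = 3, P4 = 2)
  pr <- promoter_only_ranks(prom, scores)
  expect_equal(pr$gene, c("g1", "g3", "g4", "g2"))
  g <- build_graph(prom, data.frame(id = character()),
                   data.frame(pir_id = character(),
                              promoter_id = character()), scores)
  net <- rank_genes(pagerank_scores(g))
  expect_equal(net$gene, pr$gene)
  # edgeless PageRank reduces to the normalized personalization
  expect_equal(net$score, pr$score / sum(pr$score), tolerance = 1e-9)
  # a gene scoring 0 at the promoter but fed by a strong enhancer rises
  prom2 <- data.frame(id = c("P1", "P2"), gene = c("g1", "g2"))
  s2 <- c(P1 = 0, P2 = 0.5, E1 = 5)
  g2 <- build_graph(prom2, data.frame(id = "E1"),
                    data.frame(pir_id = "E1", promoter_id = "P1"), s2)
  net2 <- rank_genes(pagerank_scores(g2))
  pr2 <- promoter_only_ranks(prom2, s2[c("P1", "P2")])
  expect_equal(pr2$gene[1], "g2")
  expect_equal(net2$gene[1], "g1")
})

test_that("rewiring preserves both degree sequences and is seed-reproducible", {
  sim <- tiny_sim(n_genes = 25, seed = 4)
  res <- suppressMessages(epirank_run(sim))
  g <- res$graph
  rg <- rewire_degree_preserving(g, seed = 99)
  expect_equal(igraph::degree(rg, mode = "out"),
               igraph::degree(g, mode = "out"))
  expect_equal(igraph::degree(rg, mode = "in"),
               igraph::degree(g, mode = "in"))
  expect_equal(igraph::V(rg)$weight, igraph::V(g)$weight)
  rg2 <- rewire_degree_preserving(g, seed = 99)
  expect_identical(igraph::as_edgelist(rg), igraph::as_edgelist(rg2))
  # edges still run PIR -> promoter
  el <- igraph::as_edgelist(rg)
  type <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_true(all(type[el[, 1]] == "pir"))
  expect_true(all(type[el[, 2]] == "promoter"))
  small <- make_test_graph(1, 1, rbind(c(1, 1)), c(1, 1))$graph
  expect_warning(same <- rewire_degree_preserving(small), "unchanged")
  expect_equal(igraph::ecount(same), 1)
})
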