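path3 <- function() build_graph(data.frame(a = c("a", "b"), b = c("b", "c"),
                                           score = 0.9))
k4 <- function() {
  p <- t(combn(c("w", "x", "y", "z"), 2))
  build_graph(data.frame(a = p[, 1], b = p[, 2], score = 0.9))
}
star4 <- function() build_graph(data.frame(a = "x", b = c("l1", "l2", "l3"),
                                           score = 0.9))

test_that("graph construction restricts, merges and reports unconnected queries", {
  e <- data.frame(a = c("A", "A", "B"), b = c("C", "C", "A"),
                  score = c(0.5, 0.7, 0.6))
  net <- build_graph(e)
  expect_equal(igraph::ecount(net$graph), 2)  # duplicate A-C merged
  g_e <- igraph::as_data_frame(net$graph)
  expect_equal(max(g_e$score), 0.7)

  net2 <- build_graph(e, restrict_to = c("A", "B", "Q"))
  expect_equal(sort(igraph::V(net2$graph)$name), c("A", "B"))
  expect_equal(net2$unconnected, "Q")

  # restrict_to = {A,B}: edge (A,C) dropped
  net3 <- build_graph(data.frame(a = "A", b = "C", score = 0.9),
                      restrict_to = c("A", "B"))
  expect_equal(igraph::ecount(net3$graph), 0)
  expect_equal(net3$unconnected, c("A", "B"))

  empty <- build_graph(data.frame(a = character(0), b = character(0),
                                  score = numeric(0)))
  expect_equal(igraph::vcount(empty$graph), 0)
})

test_that("main component extraction is deterministic with lexicographic ties", {
  e <- data.frame(a = c("a", "b", "x"), b = c("b", "c", "y"),
                  score = 0.9)
  mc <- main_component(build_graph(e))
  expect_equal(sort(igraph::V(mc$graph)$name), c("a", "b", "c"))
  expect_equal(mc$excluded, c("x", "y"))

  # connected graph -> nothing excluded
  expect_equal(main_component(path3())$excluded, character(0))

  # equal-size components -> lexicographically smallest node set wins
  tie <- build_graph(data.frame(a = c("m", "a"), b = c("n", "b"),
                                score = 0.9))
  expect_equal(sort(igraph::V(main_component(tie)$graph)$name), c("a", "b"))
})

test_that("topology statistics match hand values", {
  # triangle: clustering 1, avg neighbors 2
  tri <- build_graph(data.frame(a = c("a", "b", "c"), b = c("b", "c", "a"),
                                score = 0.9))
  ts <- topology_stats(tri)
  expect_equal(ts$clustering_coefficient, 1.0)
  expect_equal(ts$avg_neighbors, 2.0)

  # path on 3 nodes: local coefficients all zero
  expect_equal(topology_stats(path3())$clustering_coefficient, 0.0)

  # 36 nodes, 51 edges -> average neighbors 2.833
  v <- sprintf("n%02d", 1:36)
  cyc <- data.frame(a = v, b = v[c(2:36, 1)])          # 36-cycle
  chords <- data.frame(a = v[1:15], b = v[3:17])       # 15 chords
  e <- rbind(cyc, chords)
  g <- build_graph(data.frame(a = e$a, b = e$b, score = 0.9))
  ts2 <- topology_stats(g)
  expect_equal(ts2$n_nodes, 36)
  expect_equal(ts2$n_edges, 51)
  expect_equal(round(ts2$avg_neighbors, 3), 2.833)
  expect_equal(ts2$avg_neighbors * ts2$n_nodes, 2 * ts2$n_edges)

  expect_error(topology_stats(build_graph(data.frame(a = character(0),
                                                     b = character(0),
                                                     score = numeric(0)))),
               "empty")
})

test_that("centralities match hand computations on canonical graphs", {
  # path a-b-c
  ct <- centralities(path3())
  r <- function(tab, n, col) tab[tab$node == n, col]
  expect_equal(r(ct, "b", "degree"), 2L)
  expect_equal(r(ct, "b", "closeness"), 2.0)
  expect_equal(r(ct, "a", "closeness"), 1.5)
  expect_equal(r(ct, "b", "betweenness"), 2)    # ordered pairs (a,c),(c,a)
  expect_equal(r(ct, "b", "mcc"), 2)            # 1! + 1!
  expect_equal(r(ct, "a", "mcc"), 1)

  # K4: single maximal clique, mcc = 3! everywhere, no intermediaries
  ck <- centralities(k4())
  expect_equal(ck$mcc, rep(6, 4))
  expect_equal(ck$betweenness, rep(0, 4))
  expect_equal(ck$degree_rank, rep(1L, 4))

  # star with 3 leaves
  cs <- centralities(star4())
  expect_equal(r(cs, "x", "betweenness"), 6)
  expect_equal(r(cs, "x", "mcc"), 3)
  expect_equal(r(cs, "x", "closeness"), 3)
})

test_that("centralities agree with brute-force oracles on enumerated graphs", {
  check_graph <- function(A) {
    ct <- centralities(graph_from_adj(A))
    idx <- match(rownames(A), ct$node)
    expect_equal(ct$degree[idx], unname(oracle_degree(A)),
                 ignore_attr = TRUE)
    expect_equal(ct$closeness[idx], oracle_harmonic(A), tolerance = 1e-10)
    expect_equal(ct$betweenness[idx], oracle_betweenness(A),
                 tolerance = 1e-10)
    expect_equal(ct$mcc[idx], oracle_mcc(A))
  }
  # exhaustive over all connected labeled graphs with up to 5 nodes
  for (n in 2:5) {
    graphs <- enumerate_connected_graphs(n)
    for (A in graphs) check_graph(A)
  }
  # fixed-seed random samples at 6 and 7 nodes
  set.seed(20)
  for (n in 6:7) for (i in 1:60) check_graph(random_connected_adj(n))
})

test_that("mcc equals degree when the neighborhood contains no edge", {
  # trees: every neighborhood is edgeless
  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    parents <- c(NA, sample(seq_len(n - 1), n - 1, replace = TRUE))
    parents <- pmin(parents, seq_len(n) - 1)
    e <- data.frame(a = paste0("v", 2:n), b = paste0("v", parents[-1]),
                    score = 0.9)
    ct <- centralities(build_graph(e))
    expect_equal(ct$mcc, as.numeric(ct$degree))
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(11)
  A <- random_connected_adj(7)
  perm <- sample(7)
  B <- A[perm, perm]
  ca <- centralities(graph_from_adj(A))
  cb <- centralities(graph_from_adj(B))
  for (m in c("degree", "closeness", "betweenness", "mcc")) {
    expect_equal(ca[[m]][match(rownames(A), ca$node)],
                 cb[[m]][match(rownames(A), cb$node)])
  }
})

test_that("essentiality requires rank 1 on all four metrics", {
  cs <- centralities(star4())
  ess <- rank_essential(cs)
  expect_equal(ess$essential, "x")
  expect_false(ess$split_first)

  # K4: full symmetry, everyone rank 1 everywhere -> all essential
  ek <- rank_essential(centralities(k4()))
  expect_equal(sort(ek$essential), c("w", "x", "y", "z"))

  # split first ranks -> empty essential set, flagged
  # b-a, b-c, plus d-e-f triangle with extra reach: construct a graph where
  # degree and betweenness leaders differ
  g <- build_graph(data.frame(
    a = c("h", "h", "h", "h", "u", "v"),
    b = c("u", "v", "w", "z", "v", "w"),
    score = 0.9))
  ct <- centralities(g)
  ct$betweenness_rank[ct$node == "h"] <- 2L  # simulate a split leader
  ct$betweenness_rank[ct$node == "u"] <- 1L
  es <- rank_essential(ct)
  expect_equal(es$essential, character(0))
  expect_true(es$split_first)
})

test_that("clique enumeration budget raises an explicit resource error", {
  expect_error(centralities(k4(), clique_budget = 0), "budget")
})

test_that("network augmentation joins connected nodes and reports the rest", {
  base <- main_component(path3())$graph
  edges <- data.frame(a = c("a", "b", "n1"), b = c("b", "c", "a"),
                      score = 0.9)
  aug <- augment_network(base, c("n1", "n2"), edges)
  expect_equal(aug$joined, "n1")
  expect_equal(aug$unconnected_new, "n2")

  # adding an existing node is a no-op for the node set
  aug2 <- augment_network(base, "a", edges)
  expect_equal(sort(igraph::V(aug2$graph)$name), c("a", "b", "c"))
  expect_equal(aug2$joined, "a")
})

test_that("graph export applies the 10x MCC size rule and round-trips", {
  d <- withr::local_tempdir()
  g <- star4()
  ct <- centralities(g)
  f <- file.path(d, "net.graphml")
  export_graph(g, ct, f, format = "graphml")
  back <- igraph::read_graph(f, format = "graphml")
  sz <- igraph::V(back)$size
  names(sz) <- igraph::V(back)$name
  expect_equal(unname(sz["x"]), 30)          # mcc 3 -> size 30
  expect_equal(unname(sz["l1"]), 10)         # mcc 1 -> size 10

  f2 <- file.path(d, "net.tsv")
  export_graph(g, ct, f2, format = "edgelist")
  re <- build_graph(read_string_edges(f2, threshold = 0))
  expect_true(igraph::isomorphic(re$graph, g$graph))
})
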