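net_fixture <- function() {
  build_network(corpus(list(
    make_record("1", genes = c("A", "B")),
    make_record("2", genes = c("A", "B")),
    make_record("3", genes = c("C", "D", "E")),
    make_record("4", genes = "F") # singleton node
  )))
}

test_that("build_network counts co-mentioning abstracts as edge weights", {
  net <- net_fixture()
  expect_setequal(igraph::V(net)$name, LETTERS[1:6])
  e <- igraph::as_data_frame(net)
  expect_equal(e$weight[e$from == "A" & e$to == "B"], 2)
  ## a 3-gene abstract yields C(3,2) = 3 unit edges
  expect_identical(nrow(e), 4L)
  expect_true(all(e$weight[e$from != "A"] == 1))
  ## weight identity: sum of weights = sum over records of C(|genes|, 2)
  expect_equal(sum(e$weight), 1 * 2 + choose(3, 2))
  ## no self-loops, undirected storage
  expect_false(any(e$from == e$to))
  ## a single-gene record contributes an isolated node
  expect_identical(igraph::degree(net)[["F"]], 0)
})

test_that("giant_component selects by nodes, then edges, then name", {
  net <- net_fixture()
  g <- giant_component(net)
  expect_setequal(igraph::V(g)$name, c("C", "D", "E"))
  ## tie on nodes: the denser component wins
  tie <- igraph::graph_from_data_frame(
    data.frame(
      from = c("a", "b", "x", "x", "y"),
      to = c("b", "c", "y", "z", "z"),
      weight = 1L
    ),
    directed = FALSE
  )
  expect_setequal(igraph::V(giant_component(tie))$name, c("x", "y", "z"))
  expect_error(giant_component(igraph::make_empty_graph(0)), "empty")
  ## fully connected graph: identity
  full <- build_network(corpus(list(make_record("1", genes = c("A", "B", "C")))))
  expect_equal(igraph::vcount(giant_component(full)), 3)
})

test_that("prune drops light edges then orphaned nodes; threshold keeps equality", {
  net <- build_network(corpus(c(
    lapply(1:10, function(i) make_record(paste0("s", i), genes = c("A", "B"))),
    lapply(1:9, function(i) make_record(paste0("t", i), genes = c("C", "D")))
  )))
  p <- prune_network(net, 10)
  expect_setequal(igraph::V(p)$name, c("A", "B")) # weight 10 survives "less than 10"
  expect_equal(igraph::ecount(p), 1)
  ## min_weight 1 keeps every edge, drops only isolated nodes
  p1 <- prune_network(net_fixture(), 1)
  expect_false("F" %in% igraph::V(p1)$name)
  expect_equal(igraph::ecount(p1), igraph::ecount(net_fixture()))
  ## all edges below threshold -> empty network
  expect_equal(igraph::vcount(prune_network(net_fixture(), 100)), 0)
  ## composition: prune(w2) o prune(w1) = prune(max(w1, w2))
  a <- igraph::as_data_frame(prune_network(prune_network(net, 3), 10))
  b <- igraph::as_data_frame(prune_network(net, 10))
  a <- a[order(a$from, a$to), ]
  b <- b[order(b$from, b$to), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("centralities match hand-worked small graphs", {
  path <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C"), weight = 1L),
    directed = FALSE
  )
  ct <- network_centralities(path)
  expect_identical(ct$betweenness[ct$gene == "B"], 1)
  expect_identical(ct$closeness[ct$gene == "B"], 1)
  expect_identical(ct$betweenness[ct$gene == "A"], 0)
  ## star: center carries every indirect pair, leaves none
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:5)
  cs <- network_centralities(star)
  expect_identical(cs$betweenness[cs$gene == "n1"], 1)
  expect_true(all(cs$betweenness[cs$gene != "n1"] == 0))
  ## complete graph: all betweenness zero
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("k", 1:4)
  expect_true(all(network_centralities(k4)$betweenness == 0))
  ## single node
  one <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(one)$name <- "solo"
  c1 <- network_centralities(one)
  expect_identical(c1$betweenness, 0)
  expect_identical(c1$closeness, 0)
})

test_that("centralities match the brute-force oracle on random graphs", {
  withr::with_seed(91, {
    for (rep in 1:12) {
      n <- sample(4:12, 1)
      adj <- matrix(0L, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (runif(1) < 0.35) adj[i, j] <- adj[j, i] <- 1L
        }
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
      igraph::E(g)$weight <- 1L
      got <- network_centralities(g)
      oracle <- brute_centralities(adj)
      expect_equal(got$betweenness, oracle$betweenness, tolerance = 1e-10)
      expect_equal(got$closeness, oracle$closeness, tolerance = 1e-10)
    }
  })
})

test_that("communities split cliques and are seed-deterministic", {
  ## two 4-cliques joined by one bridge edge
  edges <- rbind(
    t(combn(paste0("a", 1:4), 2)),
    t(combn(paste0("b", 1:4), 2)),
    c("a1", "b1")
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = 1L),
    directed = FALSE
  )
  cm <- network_communities(g, seed = 7)
  memb <- setNames(cm$membership$modularity_class, cm$membership$gene)
  expect_identical(length(unique(memb)), 2L)
  expect_identical(length(unique(memb[paste0("a", 1:4)])), 1L)
  expect_identical(length(unique(memb[paste0("b", 1:4)])), 1L)
  expect_gt(cm$modularity, 0.3)
  ## labels are 0-based contiguous
  expect_setequal(unique(memb), c(0L, 1L))
  ## same seed, same labels
  expect_identical(network_communities(g, seed = 7), cm)
  ## single clique: one community
  k <- igraph::make_full_graph(5)
  igraph::V(k)$name <- paste0("g", 1:5)
  igraph::E(k)$weight <- 1L
  expect_identical(
    unique(network_communities(k, seed = 1)$membership$modularity_class), 0L
  )
  ## edgeless graph: every node its own class, modularity 0
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("x", "y", "z")
  cl <- network_communities(lone, seed = 1)
  expect_identical(cl$membership$modularity_class, 0:2)
  expect_identical(cl$modularity, 0)
})

test_that("network_summary computes counts and recomputed percentages", {
  s <- network_summary(c(8400, 213894), c(7620, 213877), c(1089, 68153))
  expect_identical(s$node_pct, c(100, 90.71, 12.96))
  expect_identical(s$edge_pct[2], 99.99)
  ## pruned edge percentage is recomputed from the counts
  expect_identical(s$edge_pct[3], round(100 * 68153 / 213894, 2))
  ## identity stages
  s2 <- network_summary(c(10, 5), c(10, 5), c(10, 5))
  expect_true(all(s2$node_pct == 100) && all(s2$edge_pct == 100))
  expect_error(network_summary(c(5, 2), c(6, 2), c(1, 1)), "non-increasing")
})

test_that("network exports write edge lists and GraphML", {
  net <- net_fixture()
  el <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, el)
  tab <- read.delim(el, header = FALSE)
  expect_equal(nrow(tab), as.integer(igraph::ecount(net)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::vcount(back), igraph::vcount(net))
})
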