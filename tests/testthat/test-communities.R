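two_clique_graph <- function() {
  e1 <- t(combn(sprintf("a%d", 1:5), 2))
  e2 <- t(combn(sprintf("b%d", 1:5), 2))
  igraph::graph_from_data_frame(
    rbind(as.data.frame(e1), as.data.frame(e2),
          data.frame(V1 = "a1", V2 = "b1")), directed = FALSE)
}

test_that("Louvain recovers two cliques with the hand-computed modularity", {
  g <- two_clique_graph()
  part <- louvain_partition(g, seed = 1)
  mem <- part$membership
  expect_identical(length(unique(mem)), 2L)
  expect_identical(length(unique(mem[sprintf("a%d", 1:5)])), 1L)
  expect_identical(length(unique(mem[sprintf("b%d", 1:5)])), 1L)
  expect_equal(round(part$modularity, 5), 0.45238)
})

test_that("a single clique is one cluster and seeds are reproducible", {
  clique <- igraph::make_full_graph(6)
  igraph::V(clique)$name <- letters[1:6]
  expect_identical(length(unique(louvain_partition(clique, 3)$membership)), 1L)

  g <- two_clique_graph()
  expect_identical(louvain_partition(g, 42)$membership,
                   louvain_partition(g, 42)$membership)
})

test_that("reported modularity equals direct evaluation of Q", {
  d <- generate_dataset(synthetic_params(seed = 9, n_modules = 3L,
                                         genes_per_module = 12L,
                                         n_bridge_genes = 3L,
                                         n_peripheral_genes = 6L,
                                         n_background_genes = 5L))
  de <- select_differential(d$expression, d$design)
  mi <- mi_matrix(d$expression[de$probe_id[de$selected], , drop = FALSE])
  net <- threshold_network(clr_scores(mi), 1.5)
  part <- louvain_partition(net, seed = 2)
  expect_equal(part$modularity, modularity_direct(net, part$membership),
               tolerance = 1e-10)
})

test_that("planted two-block graphs are recovered almost always", {
  set.seed(17)
  hits <- 0L
  truth <- rep(1:2, each = 30)
  for (s in 1:20) {
    adj <- matrix(0L, 60, 60)
    p <- ifelse(outer(truth, truth, "=="), 0.4, 0.02)
    up <- upper.tri(adj)
    adj[up] <- rbinom(sum(up), 1L, p[up])
    adj <- adj + t(adj)
    dimnames(adj) <- list(sprintf("g%02d", 1:60), sprintf("g%02d", 1:60))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    part <- louvain_partition(g, seed = s)
    ari <- adjusted_rand(part$membership[sprintf("g%02d", 1:60)], truth)
    hits <- hits + (ari == 1)
  }
  expect_gte(hits, 19L)
})

test_that("hypergeometric enrichment is exact", {
  terms <- list(T1 = sprintf("g%d", 1:5))
  background <- sprintf("g%d", 1:10)
  res <- hypergeometric_enrichment(sprintf("g%d", c(1:4, 6)), terms, background)
  expect_equal(res$p_hyper, 26 / 252, tolerance = 1e-9)
  expect_identical(c(res$k, res$K, res$n, res$N), c(4L, 5L, 5L, 10L))

  # a term covering the whole background is never enriched
  res2 <- hypergeometric_enrichment(c("g1", "g2"), list(ALL = background), background)
  expect_equal(res2$p_hyper, 1)

  # zero overlap -> p = 1
  res3 <- hypergeometric_enrichment(c("g6", "g7"),
                                    list(T1 = c("g1", "g2")), background)
  expect_equal(res3$p_hyper, 1)

  expect_error(hypergeometric_enrichment("g1", terms, character(0)), "empty background")
})

test_that("upper and lower hypergeometric tails always sum to one", {
  for (N in c(5, 10, 15)) {
    for (K in c(1, floor(N / 2), N)) {
      for (n in c(1, floor(N / 2), N)) {
        for (k in 0:min(K, n)) {
          upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
          lower <- sum(dhyper(seq_len(k) - 1, K, N - K, n))
          expect_equal(upper + lower, 1, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the condensed graph encodes membership and linkage structure", {
  # two 12-node clusters joined through one bottleneck, plus a small cluster
  e <- rbind(t(combn(sprintf("a%02d", 1:12), 2)),
             t(combn(sprintf("b%02d", 1:12), 2)),
             t(combn(sprintf("c%02d", 1:4), 2)),
             cbind("a01", "b01"))
  net <- igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE)
  mem <- setNames(c(rep(1L, 12), rep(2L, 12), rep(3L, 4)),
                  c(sprintf("a%02d", 1:12), sprintf("b%02d", 1:12),
                    sprintf("c%02d", 1:4)))
  part <- list(membership = mem, modularity = NA_real_)
  b <- node_betweenness(net)
  ranking <- rank_bottlenecks(b, 0.05)   # the two inter-clique connectors
  expect_setequal(ranking$node[ranking$is_bottleneck], c("a01", "b01"))

  cg <- condense(net, part, ranking, enrich = NULL, min_cluster_size = 10)
  # the 4-node cluster is filtered out; nodes = bottlenecks + big clusters
  expect_setequal(igraph::V(cg)$name, c("a01", "b01", "cluster_1", "cluster_2"))
  et <- igraph::as_data_frame(cg, what = "edges")
  key <- function(d) paste(d$from, d$to, d$edge_type)
  expect_setequal(key(et), c("a01 cluster_1 membership", "a01 cluster_2 linkage",
                             "b01 cluster_2 membership", "b01 cluster_1 linkage"))

  # a bottleneck whose neighbors stay inside its own cluster: one edge only
  ranking2 <- data.frame(node = "a05", betweenness = 1, rank = 1L,
                         is_bottleneck = TRUE)
  cg2 <- condense(net, part, ranking2, enrich = NULL, min_cluster_size = 10)
  e2 <- igraph::as_data_frame(cg2, what = "edges")
  expect_identical(nrow(e2), 1L)
  expect_identical(e2$edge_type, "membership")
})
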