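test_that("bottleneck genes deduplicate probes and drop unannotated ones", {
  rk <- data.frame(node = c("p1", "p2", "p3", "p4"),
                   betweenness = c(9, 8, 7, 1), rank = 1:4,
                   is_bottleneck = c(TRUE, TRUE, TRUE, FALSE))
  annot <- c(p1 = "Ifit1", p2 = "Ifit1", p3 = "", p4 = "Oasl2")
  expect_message(genes <- bottleneck_genes(rk, annot), "unannotated")
  expect_identical(genes, "Ifit1")

  rk$is_bottleneck <- FALSE
  expect_identical(bottleneck_genes(rk, annot), character(0))
  expect_error(bottleneck_genes(data.frame(node = "p9", betweenness = 1,
                                           rank = 1L, is_bottleneck = TRUE),
                                annot), "absent")
})

test_that("conserved bottlenecks are the exact multi-set intersection", {
  expect_identical(conserved_bottlenecks(list(c("A", "B", "C"),
                                              c("B", "C", "D"),
                                              c("C", "E"))), "C")
  expect_identical(conserved_bottlenecks(list(c("A"), c("B"))), character(0))
  expect_identical(conserved_bottlenecks(list(c("A", "B"), c("B", "A"))),
                   c("A", "B"))
  expect_error(conserved_bottlenecks(list(c("A"))), "at least 2")
})

test_that("the permutation overlap p-value honors its contracts", {
  unis <- list(letters[1:10], letters[1:10], letters[1:10])
  expect_identical(overlap_pvalue(unis, c(2, 2, 2), 0, 100, seed = 1), 1)

  p1 <- overlap_pvalue(unis, c(2, 2, 2), 1, 2000, seed = 5)
  p2 <- overlap_pvalue(unis, c(2, 2, 2), 1, 2000, seed = 5)
  expect_identical(p1, p2)                       # bit-reproducible
  expect_gte(p1, 1 / 2001)                       # add-one floor

  # monotone in the observed overlap
  p_lo <- overlap_pvalue(unis, c(5, 5, 5), 1, 2000, seed = 9)
  p_hi <- overlap_pvalue(unis, c(5, 5, 5), 3, 2000, seed = 9)
  expect_gte(p_lo, p_hi)

  # drawing the whole universe is deterministic overlap
  expect_identical(overlap_pvalue(unis, c(10, 10, 10), 10, 200, seed = 2), 1)

  expect_error(overlap_pvalue(unis, c(2, 2, 2), -1, 100, 1), "observed")
  expect_error(overlap_pvalue(unis, c(11, 2, 2), 1, 100, 1), "universe")
})

test_that("the conserved report ties sets, intersection and significance together", {
  sets <- list(net1 = c("A", "B", "C", "D"), net2 = c("B", "C", "E"),
               net3 = c("C", "B", "F"))
  unis <- list(net1 = LETTERS[1:20], net2 = LETTERS[1:20], net3 = LETTERS[1:20])
  rep <- conserved_report(sets, unis, n_permutations = 2000, seed = 3)
  expect_identical(rep$intersection, c("B", "C"))
  expect_identical(rep$observed_overlap, 2L)
  expect_identical(rep$set_sizes, c(4L, 3L, 3L))
  expect_lt(rep$p_perm, 0.05)
})

test_that("shared-neighbor tables code first- and second-order neighbors", {
  # net X: f1 - n1 - n2 ; net Y: f1 - n1, f1 - n3
  netX <- igraph::graph_from_data_frame(
    data.frame(from = c("pf1", "pn1"), to = c("pn1", "pn2")), directed = FALSE)
  netY <- igraph::graph_from_data_frame(
    data.frame(from = c("pf1", "pf1"), to = c("pn1", "pn3")), directed = FALSE)
  annot <- c(pf1 = "Focal", pn1 = "G1", pn2 = "G2", pn3 = "G3")
  tab <- shared_neighbor_table(list(X = netX, Y = netY), annot, "Focal")
  expect_identical(tab$gene, c("G1", "G3", "G2"))  # G3 is first-order in one network, G2 in none
  expect_identical(tab$X[tab$gene == "G1"], 1L)
  expect_identical(tab$Y[tab$gene == "G1"], 1L)
  expect_identical(tab$X[tab$gene == "G2"], 2L)     # second order in X only
  expect_true(is.na(tab$Y[tab$gene == "G2"]))
  expect_identical(tab$Y[tab$gene == "G3"], 1L)

  # order-1 restriction removes all code-2 entries
  tab1 <- shared_neighbor_table(list(X = netX, Y = netY), annot, "Focal",
                                max_order = 1)
  expect_false(any(tab1[, c("X", "Y")] == 2L, na.rm = TRUE))

  # a gene coded 1 somewhere is never coded 2 in the same network
  expect_false(any(tab$X == 1L & tab$X == 2L, na.rm = TRUE))

  expect_error(shared_neighbor_table(list(X = netX), annot, "Missing"),
               "no probe node")
})
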