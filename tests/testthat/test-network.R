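edge_df <- function(a, b, s) data.frame(gene_a = a, gene_b = b,
                                        combined_score = s,
                                        stringsAsFactors = FALSE)

test_that("the median edge filter keeps strictly-above-median scores only", {
  e <- edge_df(paste0("a", 1:5), paste0("b", 1:5), 1:5)
  kept <- filter_edges_by_median(e)
  expect_setequal_sorted(kept$combined_score, c(4, 5))

  same <- edge_df(c("a", "b"), c("c", "d"), c(7, 7))
  expect_identical(nrow(filter_edges_by_median(same)), 0L)

  expect_error(filter_edges_by_median(edge_df(character(0), character(0),
                                              numeric(0))), "empty")
  expect_error(filter_edges_by_median(edge_df("x", "x", 5)), "self-loop")

  set.seed(77)
  scores <- sample(150:999, 1000, replace = TRUE)
  e2 <- edge_df(sprintf("u%04d", 1:1000), sprintf("v%04d", 1:1000), scores)
  kept2 <- filter_edges_by_median(e2)
  expect_setequal_sorted(kept2$combined_score, scores[scores > median(scores)])
  expect_lte(nrow(kept2), ceiling(nrow(e2) / 2))
})

test_that("network construction subsets to DEG pairs and deduplicates", {
  e <- edge_df(c("A", "B", "B", "X"), c("B", "A", "C", "A"),
               c(900, 800, 700, 600))
  net <- build_network(c("A", "B", "C"), e)
  expect_identical(nrow(net$edges), 2L)              # (A,B) collapsed, (X,A) dropped
  expect_true(all(c("A", "B", "C") %in% igraph::V(net$graph)$name))
  expect_lte(igraph::vcount(net$graph), 3)
})

test_that("centralities match hand-enumerable small graphs", {
  path3 <- build_network(c("A", "B", "C"),
                         edge_df(c("A", "B"), c("B", "C"), c(500, 500)))
  topo <- compute_topology(path3)
  topo <- topo[order(topo$gene_id), ]
  expect_equal(topo$degree, c(1, 2, 1))
  expect_equal(topo$betweenness, c(0, 1, 0))
  expect_equal(topo$closeness[2], 2 / 2)             # (nc-1)/sum(d) = 2/(1+1)

  k4 <- t(combn(LETTERS[1:4], 2))
  comp <- build_network(LETTERS[1:4], edge_df(k4[, 1], k4[, 2], 500))
  topo4 <- compute_topology(comp)
  expect_equal(topo4$betweenness, rep(0, 4))
  expect_length(unique(round(topo4$closeness, 12)), 1)

  # weighted degree sums combined scores
  wt <- compute_topology(path3, weighted_degree = TRUE)
  expect_equal(sort(wt$degree), c(500, 500, 1000))
})

test_that("betweenness agrees with brute-force shortest-path enumeration", {
  set.seed(19)
  for (i in 1:10) {
    g <- random_graph(sample(5:10, 1))
    if (!nrow(g$edges)) next
    net <- build_network(g$genes, g$edges)
    topo <- compute_topology(net)
    brute <- brute_betweenness(g$adj)
    names(brute) <- g$genes
    expect_equal(topo$betweenness, unname(brute[topo$gene_id]),
                 tolerance = 1e-9)
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(23)
  g <- random_graph(8, p = 0.4)
  net <- compute_topology(build_network(g$genes, g$edges))
  perm <- sample(g$genes)
  relabel <- stats::setNames(perm, g$genes)
  e2 <- g$edges
  e2$gene_a <- unname(relabel[e2$gene_a])
  e2$gene_b <- unname(relabel[e2$gene_b])
  net2 <- compute_topology(build_network(perm, e2))
  m1 <- net[order(net$gene_id), ]
  m2 <- net2[match(relabel[m1$gene_id], net2$gene_id), ]
  expect_equal(m1$degree, m2$degree)
  expect_equal(m1$closeness, m2$closeness)
  expect_equal(m1$betweenness, m2$betweenness)
})

test_that("major-gene selection requires all three features above their medians", {
  # every background node misses at least one median; only the hub clears all
  topo <- data.frame(gene_id = c("hub", paste0("bg", 1:6)),
                     degree = c(9, 1, 3, 2, 2, 1, 1),
                     closeness = c(0.9, 0.2, 0.2, 0.4, 0.3, 0.3, 0.5),
                     betweenness = c(12, 0, 2, 0, 1, 3, 0))
  expect_identical(select_major_genes(topo), "hub")

  flat <- data.frame(gene_id = c("a", "b"), degree = c(2, 2),
                     closeness = c(1, 1), betweenness = c(0, 0))
  expect_length(select_major_genes(flat), 0)

  set.seed(4)
  rand <- data.frame(gene_id = sprintf("g%03d", 1:100),
                     degree = rpois(100, 3),
                     closeness = runif(100),
                     betweenness = rexp(100))
  got <- select_major_genes(rand)
  brute <- rand$gene_id[rand$degree > median(rand$degree) &
                          rand$closeness > median(rand$closeness) &
                          rand$betweenness > median(rand$betweenness)]
  expect_setequal_sorted(got, brute)
})

test_that("candidate selection reproduces the published six-gene signature", {
  t2 <- tg_major_genes()
  expect_identical(nrow(t2), 16L)
  got <- select_candidates(t2$gene_id, t2)
  expect_identical(got, c("CRK", "GRAPL", "MX1", "OASL", "RNF2", "SPINK1"))

  # boundary: FC exactly at the threshold is excluded in either direction
  rec <- data.frame(gene_id = c("at", "below", "above", "down"),
                    fc = c(1.5, 1.4, 1.6, 1 / 1.5),
                    p_value = rep(0.01, 4))
  expect_identical(select_candidates(rec$gene_id, rec), "above")

  # a down-regulated gene with FC 0.55 passes the reciprocal criterion
  expect_true("MX1" %in% got && t2$fc[t2$gene_id == "MX1"] == 0.55)

  expect_error(select_candidates(c("CRK", "NOPE"), t2), "NOPE")
  expect_error(select_candidates("CRK", t2, fold_threshold = 1), "exceed 1")
})
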