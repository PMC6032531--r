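# Shared fixtures and independent oracles used across test files.

# A small deterministic two-group expression matrix.
tiny_expr <- function(n_genes = 20, n1 = 4, n2 = 4, seed = 42,
                      effect_genes = character(0), effect = 0) {
  set.seed(seed)
  samples <- c(paste0("R", seq_len(n1)), paste0("N", seq_len(n2)))
  labels <- stats::setNames(
    rep(c("responder", "non_responder"), c(n1, n2)), samples)
  genes <- paste0("g", seq_len(n_genes))
  vals <- matrix(rnorm(n_genes * (n1 + n2), 7, 1), n_genes,
                 dimnames = list(genes, samples))
  vals[effect_genes, seq_len(n1)] <- vals[effect_genes, seq_len(n1)] + effect
  expression_matrix(vals, labels)
}

# Brute-force shortest-path betweenness by full path enumeration (n <= 12).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_shortest_paths_dfs <- function(s, t, dist) {
    # enumerate all shortest s->t paths following the BFS distance layers
    paths <- list()
    recurse <- function(node, path) {
      if (node == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (nb in which(adj[node, ] == 1)) {
        if (dist[nb] == dist[node] + 1 && dist[t] >= dist[nb])
          recurse(nb, c(path, nb))
      }
    }
    recurse(s, s)
    paths
  }
  bfs_dist <- function(s) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (nb in which(adj[v, ] == 1)) {
          if (is.infinite(dist[nb])) { dist[nb] <- dist[v] + 1; nxt <- c(nxt, nb) }
        }
      }
      frontier <- unique(nxt)
    }
    dist
  }
  for (s in seq_len(n - 1)) {
    dist <- bfs_dist(s)
    for (t in seq((s + 1), n)) {
      if (t <= s || is.infinite(dist[t])) next
      paths <- all_shortest_paths_dfs(s, t, dist)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(paths)
      }
    }
  }
  btw
}

# Random undirected graph as adjacency matrix + edge table.
random_graph <- function(n, p = 0.35) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1))
    for (j in seq((i + 1), n))
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  genes <- paste0("n", seq_len(n))
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      combined_score = rep(500, nrow(idx)),
                      stringsAsFactors = FALSE)
  list(adj = adj, edges = edges, genes = genes)
}

# Mann-Whitney AUC: pairwise comparisons with half credit for ties.
mw_auc <- function(scores, labels) {
  pos <- scores[labels == "responder"]
  neg <- scores[labels != "responder"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

expect_setequal_sorted <- function(x, y) expect_equal(sort(x), sort(y))
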