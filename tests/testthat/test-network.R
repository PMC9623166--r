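# helpers to build a spearman_result / co_network from raw matrices
sim_rel <- function(n, k, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n * k), n, k,
              dimnames = list(paste0("S", 1:n), paste0("O", 1:k)))
  m / rowSums(m)
}

test_that("spearman_matrix agrees with the rank oracle (monotone cases)", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9, 7, 8)
  m <- cbind(a = x, b = exp(x), c = -x, d = rev(sort(x))[rank(x)])
  rownames(m) <- paste0("S", 1:10)
  res <- spearman_matrix(m)
  expect_equal(res$rho["a", "b"], 1)   # monotone increasing
  expect_equal(res$rho["a", "c"], -1)  # reversed ranks
  expect_equal(diag(res$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(res$rho, t(res$rho))
  expect_equal(res$p, t(res$p))
  # rank property: invariance under strictly monotone transforms
  m2 <- m; m2[, "a"] <- log(m2[, "a"])
  expect_equal(spearman_matrix(m2)$rho, res$rho)
  expect_error(spearman_matrix(m[1:3, ]), ">= 4 samples")
})

test_that("exact permutation p at n = 7 matches full enumeration", {
  set.seed(42)
  for (rep in 1:3) {
    x <- sample(20, 7); y <- sample(20, 7)
    y[2] <- y[1]  # introduce a tie
    m <- cbind(a = x, b = y)
    rownames(m) <- paste0("S", 1:7)
    res <- spearman_matrix(m)
    expect_equal(res$rho["a", "b"], oracle_spearman_rho(x, y))
    expect_equal(res$p["a", "b"], oracle_spearman_p_exact(x, y))
  }
})

test_that("t-approximation p is used above n = 9 and is sane", {
  set.seed(5)
  x <- rnorm(20); y <- x + rnorm(20, sd = 0.2)
  m <- cbind(a = x, b = y, c = rnorm(20))
  rownames(m) <- paste0("S", 1:20)
  res <- spearman_matrix(m)
  r <- res$rho["a", "b"]
  tstat <- r * sqrt(18 / (1 - r^2))
  expect_equal(res$p["a", "b"], 2 * pt(-abs(tstat), 18))
  expect_gt(res$p["a", "c"], 0.05)
})

test_that("constant columns get rho 0, p 1 and never form edges", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 5, 3, 4), c = rep(7, 5))
  rownames(m) <- paste0("S", 1:5)
  res <- spearman_matrix(m)
  expect_equal(res$rho["a", "c"], 0)
  expect_equal(res$p["a", "c"], 1)
  net <- filter_edges(res, r_min = 0, p_max = 1)
  deg <- igraph::degree(net$graph)
  expect_equal(unname(deg["c"]), 0)
  expect_equal(unname(deg["a"]), 1)  # complete graph minus constant node
})

test_that("filter_edges equals the brute-force double loop", {
  rel <- sim_rel(18, 30, seed = 3)
  # plant a few strong pairs
  rel[, 2] <- rel[, 1] * 1.1; rel[, 3] <- -rel[, 1]
  res <- spearman_matrix(rel)
  net <- filter_edges(res, 0.8, 0.01)
  got <- igraph::as_edgelist(net$graph)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  want <- NULL
  for (i in 1:29) for (j in (i + 1):30) {
    if (abs(res$rho[i, j]) >= 0.8 && res$p[i, j] <= 0.01)
      want <- rbind(want, sort(c(colnames(rel)[i], colnames(rel)[j])))
  }
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(got, want, ignore_attr = TRUE)
  # rule application: rho 0.85/p 0.005 kept (O1-O2 is such a pair),
  # sign attribute matches correlation sign
  signs <- igraph::E(net$graph)$sign
  rhos <- igraph::E(net$graph)$rho
  expect_true(all((rhos > 0) == (signs == "positive")))
})

test_that("network_density counts edges over possible pairs", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- letters[1:4]
  igraph::E(g)$sign <- "positive"
  expect_equal(network_density(g), 1)
  g2 <- igraph::graph_from_literal(a - b, b - c)
  expect_equal(network_density(g2), 2 / 3)
  set.seed(2)
  adj <- random_connected_adj(12)
  g3 <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  expect_equal(network_density(g3), sum(adj) / 2 / 66)
  expect_error(network_density(igraph::make_empty_graph(1, directed = FALSE)),
               ">= 2 nodes")
})

test_that("two disjoint cliques give two modules and Q = 0.5", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  igraph::V(g)$name <- paste0("n", 1:12)
  part <- detect_modules(g, seed = 1)
  expect_equal(length(part$main_modules), 2)
  expect_equal(unname(part$sizes), c(6L, 6L))
  expect_equal(part$modularity, 0.5)
  # disjoint components are never merged
  memb <- part$module_of_node
  expect_equal(length(unique(memb[paste0("n", 1:6)])), 1)
  expect_equal(length(unique(memb[paste0("n", 7:12)])), 1)
  expect_false(memb[["n1"]] == memb[["n7"]])

  single <- igraph::make_full_graph(5)
  igraph::V(single)$name <- paste0("m", 1:5)
  expect_equal(length(detect_modules(single, seed = 1)$main_modules), 1)
  expect_error(detect_modules(igraph::make_empty_graph(3, directed = FALSE),
                              seed = 1), "edgeless")
})

test_that("module detection recovers a planted 3-block graph", {
  set.seed(7)
  n_per <- 15
  blocks <- rep(1:3, each = n_per)
  n <- length(blocks)
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (blocks[i] == blocks[j]) 0.9 else 0.02
    adj[i, j] <- adj[j, i] <- rbinom(1, 1, p)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("v%02d", 1:n)
  part <- detect_modules(g, seed = 3)
  ari <- adjusted_rand_index(part$module_of_node[sprintf("v%02d", 1:n)],
                             blocks)
  expect_gte(ari, 0.9)
})

test_that("centralities match closed forms on path and star", {
  path <- igraph::graph_from_literal(A - B, B - C)
  ct <- centralities(path)
  rownames(ct) <- ct$node
  expect_equal(ct["B", "degree"], 2L)
  expect_equal(ct["B", "closeness"], 1)
  expect_equal(ct["B", "betweenness"], 1)
  expect_equal(ct["A", "betweenness"], 0)

  star <- igraph::make_star(6, "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  cs <- centralities(star)
  expect_equal(cs$betweenness[1], 1)
  expect_true(all(cs$betweenness[-1] == 0))
})

test_that("centralities equal the all-pairs BFS oracle", {
  set.seed(99)
  for (rep in 1:10) {
    adj <- random_connected_adj(10)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- paste0("v", 1:10)
    got <- centralities(g)
    want <- oracle_centralities(adj)
    expect_equal(got$degree, as.integer(want$degree))
    expect_equal(got$closeness, want$closeness)
    expect_equal(got$betweenness, want$betweenness)
  }
})

test_that("keystone selection matches exhaustive composite scoring", {
  set.seed(13)
  adj <- random_connected_adj(25, p = 0.2)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("v%02d", 1:25)
  ct <- centralities(g)
  ks <- select_keystones(ct, 10)
  score <- rank(-ct$degree) + rank(-ct$closeness) + rank(ct$betweenness)
  want <- ct$node[order(score, ct$node)][1:10]
  expect_equal(ks$node, want)
  expect_true(all(diff(ks$score) >= 0))
  # k = n returns everything; k > n warns
  expect_equal(nrow(select_keystones(ct, 25)), 25)
  expect_warning(all_nodes <- select_keystones(ct, 30), "node count")
  expect_equal(nrow(all_nodes), 25)
  # a node dominating all three criteria scores 3 and ranks first
  tab <- data.frame(node = c("hub", "x", "y"),
                    degree = c(5L, 2L, 1L),
                    closeness = c(0.9, 0.5, 0.4),
                    betweenness = c(0.0, 0.2, 0.3))
  top <- select_keystones(tab, 1)
  expect_equal(top$node, "hub")
  expect_equal(top$score, 3)
})

test_that("keystone set is invariant to node relabeling (up to tie-break)", {
  set.seed(31)
  adj <- random_connected_adj(12, p = 0.3)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("a%02d", 1:12)
  ks1 <- select_keystones(centralities(g), 5)
  relabel <- sprintf("b%02d", 12:1)  # reversed ids, same structure
  g2 <- g
  igraph::V(g2)$name <- relabel
  ks2 <- select_keystones(centralities(g2), 5)
  map <- setNames(relabel, sprintf("a%02d", 1:12))
  expect_setequal(unname(map[ks1$node]), ks2$node)
})

test_that("adjusted_rand_index matches the contingency formula", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(3, 3, 9, 9)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
})
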