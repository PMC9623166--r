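#' Co-occurrence network inference
#'
#' Networks are built from pairwise Spearman correlations between
#' dominant OTUs across samples; edges keep only strong (|rho| >= r_min)
#' and significant (p <= p_max) correlations, with the sign retained as
#' an attribute. Modules are communities of the resulting unweighted
#' graph found by a seeded Louvain multilevel modularity heuristic, and
#' keystone taxa are the nodes with high degree, high closeness and low
#' betweenness centrality by an unweighted rank-sum composite.
#'
#' @name network
NULL

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1L)
  q <- cbind(p, as.integer(n))
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    cols <- append(seq_len(n - 1L), n, after = pos - 1L)
    out[[pos]] <- q[, cols, drop = FALSE]
  }
  do.call(rbind, out)
}

# Two-sided p for one Spearman rho: exact by full permutation
# enumeration for n <= 9, t-approximation with n - 2 df otherwise.
spearman_p <- function(rx, ry, rho, perms = NULL) {
  n <- length(rx)
  if (!is.finite(rho)) return(1)
  if (n <= 9) {
    if (is.null(perms)) perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    rx_c <- rx - mean(rx)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_null <- (ry_perm %*% rx_c) / denom
    mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
}

#' Pairwise Spearman correlations with significance
#'
#' Rank-transforms each OTU (average ranks for ties) and computes the
#' product-moment correlation on ranks. P-values are exact by full
#' permutation enumeration for n <= 9 samples and use the t
#' approximation (n - 2 df) otherwise. Constant columns have no defined
#' correlation and are recorded as rho = 0, p = 1.
#'
#' @param rel samples x OTUs abundance matrix restricted to the OTUs of
#'   interest; >= 4 samples required.
#' @return a `spearman_result`: list with symmetric matrices `rho` and
#'   `p` and the sample count `n_samples`.
#' @export
spearman_matrix <- function(rel) {
  rel <- as.matrix(rel)
  n <- nrow(rel)
  if (n < 4) stop("need >= 4 samples for correlation")
  if (ncol(rel) < 2) stop("need >= 2 OTUs")
  ranks <- apply(rel, 2, rank)
  constant <- apply(rel, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(stats::cor(ranks))
  rho[constant, ] <- 0; rho[, constant] <- 0
  diag(rho) <- 1
  p <- matrix(1, ncol(rel), ncol(rel), dimnames = dimnames(rho))
  if (n <= 9) {
    perms <- all_permutations(n)
    idx <- which(upper.tri(rho), arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (constant[i] || constant[j]) next
      p[i, j] <- p[j, i] <- spearman_p(ranks[, i], ranks[, j],
                                       rho[i, j], perms)
    }
  } else {
    r <- pmin(pmax(rho, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
    pv[abs(r) >= 1 - 1e-15] <- 0
    p[] <- pv
    p[constant, ] <- 1; p[, constant] <- 1
  }
  diag(p) <- 0
  structure(list(rho = rho, p = p, n_samples = n,
                 constant = setNames(constant, colnames(rel))),
            class = "spearman_result")
}

#' Threshold correlations into a co-occurrence network
#'
#' An edge is kept iff |rho| >= r_min and p <= p_max; the correlation
#' sign is stored on the edge. Nodes with no surviving edge are retained
#' as isolates (they are excluded from module detection).
#'
#' @param corr a [spearman_matrix()] result.
#' @param r_min minimum correlation magnitude (default 0.8).
#' @param p_max maximum p-value (default 0.01).
#' @return a `co_network`: list with the igraph `graph` (edge attributes
#'   `rho`, `sign`) and the thresholds used.
#' @export
filter_edges <- function(corr, r_min = 0.8, p_max = 0.01) {
  stopifnot(inherits(corr, "spearman_result"))
  if (r_min < 0 || r_min > 1 || p_max <= 0 || p_max > 1)
    stop("thresholds must be in [0, 1] / (0, 1]")
  nodes <- colnames(corr$rho)
  defined <- !(corr$constant %||% rep(FALSE, length(nodes)))
  ok <- outer(defined, defined, "&")
  keep <- which(upper.tri(corr$rho) & ok & abs(corr$rho) >= r_min &
                  corr$p <= p_max, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(keep)) {
    rhos <- corr$rho[keep]
    g <- igraph::add_edges(
      g, rbind(nodes[keep[, 1]], nodes[keep[, 2]]),
      rho = rhos, sign = ifelse(rhos > 0, "positive", "negative"))
  }
  structure(list(graph = g, r_min = r_min, p_max = p_max,
                 n_samples = corr$n_samples),
            class = "co_network")
}

as_conet_graph <- function(net) {
  if (inherits(net, "co_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a co_network or igraph object")
}

#' Edge density of a network or induced subgraph
#'
#' 2E / (N(N-1)) over the (sub)graph; with `positive_only = TRUE` only
#' positively signed edges are counted — the variant reported for the
#' core module of a co-occurrence network.
#'
#' @param net `co_network` or igraph graph.
#' @param node_subset optional node ids inducing a subgraph.
#' @param positive_only count only edges with sign "positive".
#' @return density in \[0, 1\].
#' @export
network_density <- function(net, node_subset = NULL, positive_only = FALSE) {
  g <- as_conet_graph(net)
  if (!is.null(node_subset))
    g <- igraph::induced_subgraph(g, node_subset)
  n <- igraph::vcount(g)
  if (n < 2) stop("need >= 2 nodes to compute density")
  e <- if (positive_only && igraph::ecount(g) > 0)
    sum(igraph::E(g)$sign == "positive") else igraph::ecount(g)
  2 * e / (n * (n - 1))
}

#' Detect network modules by modularity maximisation
#'
#' Runs the Louvain multilevel heuristic on the unweighted graph of
#' non-isolated nodes under a fixed seed. Modules are relabelled 1, 2,
#' ... by decreasing size; modules smaller than `min_size` keep their
#' label but are excluded from the `main_modules` ranking.
#'
#' @param net a `co_network` (>= 1 edge required).
#' @param seed integer seed for the heuristic.
#' @param min_size minimum node count for a "main" module (default 5).
#' @return a `module_partition`: `module_of_node` (named integer vector
#'   over non-isolated nodes), `sizes`, `main_modules`, `modularity`.
#' @export
detect_modules <- function(net, seed = 1L, min_size = 5L) {
  g <- as_conet_graph(net)
  if (igraph::ecount(g) == 0) stop("cannot detect modules in an edgeless graph")
  isolates <- igraph::V(g)[igraph::degree(g) == 0]
  g2 <- igraph::delete_vertices(g, isolates)
  comm <- with_seed(seed, igraph::cluster_louvain(g2))
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  # deterministic relabel: by decreasing size, ties by smallest member id
  first_member <- vapply(names(sizes), function(m)
    min(names(memb)[memb == as.integer(m)]), character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  module_of_node <- setNames(as.integer(relabel[as.character(memb)]),
                             names(memb))
  sizes <- table(module_of_node)
  main <- as.integer(names(sizes)[as.integer(sizes) >= min_size])
  structure(list(module_of_node = module_of_node,
                 sizes = setNames(as.integer(sizes), names(sizes)),
                 main_modules = sort(main),
                 modularity = igraph::modularity(comm)),
            class = "module_partition")
}

#' Node centralities on the unweighted graph
#'
#' Degree, Wasserman-Faust component-scaled closeness
#' ((n_c - 1)/(n - 1) * (n_c - 1) / sum of within-component distances),
#' and betweenness normalised by (n - 1)(n - 2)/2. Isolates get
#' closeness 0 and betweenness 0.
#'
#' @param net `co_network` or igraph graph with >= 2 nodes.
#' @return data.frame with columns `node`, `degree`, `closeness`,
#'   `betweenness`.
#' @export
centralities <- function(net) {
  g <- as_conet_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("need >= 2 nodes")
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  comp <- igraph::components(g)
  closeness <- vapply(seq_len(n), function(i) {
    nc <- comp$csize[comp$membership[i]]
    if (nc < 2) return(0)
    dsum <- sum(d[i, comp$membership == comp$membership[i]])
    ((nc - 1) / (n - 1)) * (nc - 1) / dsum
  }, numeric(1))
  btw <- igraph::betweenness(g, normalized = TRUE)
  data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
             closeness = closeness, betweenness = as.numeric(btw),
             row.names = NULL)
}

#' Select keystone taxa by composite centrality rank
#'
#' Composite score = rank(degree, descending) + rank(closeness,
#' descending) + rank(betweenness, ascending), with average ranks for
#' ties. The k nodes with the smallest composite score are returned,
#' ties broken by node id.
#'
#' @param cent a [centralities()] table.
#' @param k number of keystones (default 20).
#' @return data.frame of the selected nodes with their centralities and
#'   `score`, ordered by score.
#' @export
select_keystones <- function(cent, k = 20L) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(cent)) {
    warning("k exceeds node count; returning all nodes")
    k <- nrow(cent)
  }
  score <- rank(-cent$degree) + rank(-cent$closeness) + rank(cent$betweenness)
  ord <- order(score, cent$node)
  out <- cent[ord, , drop = FALSE]
  out$score <- score[ord]
  rownames(out) <- NULL
  head(out, k)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones. Used to score
#' planted-module recovery.
#'
#' @param a,b label vectors of equal length (names ignored).
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
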