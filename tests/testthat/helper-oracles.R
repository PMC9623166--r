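# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths (and igraph) so that implementation and
# check stay decoupled.

# -- permutation enumeration (recursive, independent of the package) --
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- oracle_perms(n - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# -- Spearman rho: rank with average ties, then Pearson on ranks -------
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_spearman_p_exact <- function(x, y) {
  obs <- abs(oracle_spearman_rho(x, y))
  perms <- oracle_perms(length(y))
  hits <- vapply(perms, function(p)
    abs(oracle_spearman_rho(x, y[p])) >= obs - 1e-12, logical(1))
  mean(hits)
}

# -- all-pairs BFS on an adjacency matrix ------------------------------
oracle_bfs <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[s] <- 0
  sigma <- rep(0, n); sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (v in which(adj[u, ] > 0)) {
      if (is.infinite(d[v])) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
      if (d[v] == d[u] + 1) sigma[v] <- sigma[v] + sigma[u]
    }
    frontier <- unique(nxt)
  }
  list(dist = d, sigma = sigma)
}

# degree / Wasserman-Faust closeness / pair-enumeration betweenness
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  deg <- rowSums(adj)
  closeness <- vapply(seq_len(n), function(i) {
    reach <- which(is.finite(bfs[[i]]$dist))
    nc <- length(reach)
    if (nc < 2) return(0)
    ((nc - 1) / (n - 1)) * (nc - 1) / sum(bfs[[i]]$dist[reach])
  }, numeric(1))
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    dst <- bfs[[s]]$dist[t]
    if (!is.finite(dst)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst)
        btw[v] <- btw[v] +
          bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
    }
  }
  list(degree = deg, closeness = closeness,
       betweenness = btw / ((n - 1) * (n - 2) / 2))
}

# -- closed-form OLS ---------------------------------------------------
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  n <- length(x)
  se <- sqrt(sum((y - yhat)^2) / (n - 2) / sxx)
  list(slope = slope, intercept = intercept, r_squared = r2, se = se)
}

# -- exact Mann-Whitney U enumeration ---------------------------------
oracle_mwu <- function(x, y) {
  # U for x: pairs (xi, yj) with xi > yj (+0.5 for ties)
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# -- Bray-Curtis elementwise ------------------------------------------
oracle_bray <- function(a, b) 1 - 2 * sum(pmin(a, b)) / sum(a + b)

# -- pseudo-F from a distance matrix (Anderson) ------------------------
oracle_pseudo_f <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (lv in unique(groups)) {
    idx <- which(groups == lv)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# small random connected graph as adjacency matrix
random_connected_adj <- function(n, p = 0.35) {
  repeat {
    adj <- matrix(0, n, n)
    up <- which(upper.tri(adj))
    on <- up[stats::runif(length(up)) < p]
    adj[on] <- 1
    adj <- adj + t(adj)
    # connectivity via oracle BFS
    if (all(is.finite(oracle_bfs(adj, 1)$dist))) return(adj)
  }
}

demo_dir <- function() system.file("extdata", "synthetic_demo",
                                   package = "rhizocore")
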