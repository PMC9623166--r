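#' Treatment-level statistics
#'
#' One-way ANOVA with Tukey HSD and a compact letter display for
#' per-variable treatment comparisons; Bray-Curtis dissimilarity and
#' distance-based PERMANOVA (Anderson's pseudo-F with seeded label
#' permutations) for community-level comparisons.
#'
#' @name group_stats
NULL

#' One-way ANOVA with Tukey HSD and compact letters
#'
#' @param values numeric response per sample.
#' @param groups group labels (>= 2 groups, >= 2 observations each).
#' @return a `group_comparison`: per-group `mean`/`sd`/`n`, ANOVA `F`
#'   and `p`, Tukey pairwise p matrix, and `letters` (compact letter
#'   display at alpha = 0.05, insert-absorb, alphabetical).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  lv <- levels(groups)
  pmat <- matrix(NA_real_, nlevels(groups), nlevels(groups),
                 dimnames = list(lv, lv))
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[rn, "p adj"]
  }
  diag(pmat) <- 1
  structure(list(
    groups = data.frame(
      group = lv,
      mean = as.numeric(tapply(values, groups, mean)),
      sd = as.numeric(tapply(values, groups, sd)),
      n = as.integer(table(groups)),
      row.names = NULL),
    F = an[1, "F value"], p = an[1, "Pr(>F)"],
    tukey_p = pmat,
    letters = compact_letters(pmat, alpha = 0.05)),
    class = "group_comparison")
}

# Compact letter display by the insert-absorb procedure: start with one
# letter covering all groups; for each significantly different pair
# sharing a letter, duplicate that letter column, remove one group from
# each copy, then absorb redundant columns. Letters assigned
# alphabetically over the final columns.
compact_letters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  cols <- list(setNames(rep(TRUE, length(g)), g))
  pairs <- which(upper.tri(pmat), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- g[pairs[k, 1]]; j <- g[pairs[k, 2]]
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1]] <- b
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (x in seq_along(cols)) for (y in seq_along(cols)) {
      if (x != y && keep[x] && keep[y] &&
          all(cols[[x]] <= cols[[y]]) && any(cols[[x]] < cols[[y]]))
        keep[x] <- FALSE
    }
    cols <- cols[keep]
  }
  out <- vapply(g, function(gr) {
    paste(letters[which(vapply(cols, function(c) c[gr], logical(1)))],
          collapse = "")
  }, character(1))
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(i, j) = 1 - 2 * sum_k min(p_ik, p_jk) for row-normalised
#' abundance profiles; symmetric with a zero diagonal.
#'
#' @param rel samples x OTUs relative-abundance matrix.
#' @return sample x sample dissimilarity matrix.
#' @export
bray_curtis <- function(rel) {
  rel <- as.matrix(rel)
  as.matrix(vegan::vegdist(rel, method = "bray"))
}

#' Distance-based PERMANOVA
#'
#' Anderson's pseudo-F from the among/within partition of the squared
#' distance matrix; p = (1 + #\{permuted F >= observed\}) / (1 + n_perm)
#' under seeded permutation of group labels, so p is never exactly 0.
#'
#' @param dist sample x sample dissimilarity matrix (or `dist`).
#' @param groups group labels, >= 2 groups, no singletons.
#' @param n_perm number of permutations (default 999); ignored when
#'   `exact = TRUE`.
#' @param seed integer seed.
#' @param exact enumerate all label permutations (feasible for n <= 8);
#'   p then includes the identity permutation, so it is never 0.
#' @return a `permanova_result`: `F`, `r_squared`, `p`, `n_perm`, `seed`.
#' @export
permanova <- function(dist, groups, n_perm = 999L, seed = 1L,
                      exact = FALSE) {
  d <- as.matrix(dist)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("singleton group not allowed")
  n <- nrow(d)
  stopifnot(length(groups) == n)
  d2 <- d^2
  sst <- sum(d2) / (2 * n)
  pseudo_f <- function(gr) {
    ssw <- 0
    for (lv in levels(gr)) {
      idx <- which(gr == lv)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssa <- sst - ssw
    a <- nlevels(gr)
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- pseudo_f(groups)
  ssw <- 0
  for (lv in levels(groups)) {
    idx <- which(groups == lv)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  r2 <- (sst - ssw) / sst
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    fs <- vapply(seq_len(nrow(perms)), function(i)
      pseudo_f(groups[perms[i, ]]), numeric(1))
    return(structure(list(F = f_obs, r_squared = r2,
                          p = mean(fs >= f_obs - 1e-12),
                          n_perm = nrow(perms), seed = as.integer(seed)),
                     class = "permanova_result"))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pseudo_f(factor(sample(as.character(groups)), levels = levels(groups)))
    }, numeric(1)) >= f_obs - 1e-12)
  })
  structure(list(F = f_obs, r_squared = r2,
                 p = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permanova_result")
}
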