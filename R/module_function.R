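#' Linking network modules to soil functional potential
#'
#' Module abundance per sample is the mean of the members' z-scored
#' relative abundances; modules are correlated (Spearman) against the
#' functional variables (functional-gene qPCR abundances, RubisCO
#' activity, PNR, DEA), and the "core" module is the one with the most
#' significant positive associations with soil function.
#'
#' @name module_function
NULL

#' Per-sample module abundance (mean member z-score)
#'
#' @param rel samples x OTUs relative-abundance matrix covering all
#'   partition nodes.
#' @param part a [detect_modules()] partition.
#' @param modules module ids to report (default: main modules).
#' @return samples x modules matrix of mean member z-scores; columns
#'   named `M<id>`.
#' @export
module_abundance <- function(rel, part, modules = part$main_modules) {
  stopifnot(inherits(part, "module_partition"))
  rel <- check_otu_table(rel, integer_counts = FALSE)
  missing <- setdiff(names(part$module_of_node), colnames(rel))
  if (length(missing))
    stop("partition nodes absent from table: ",
         paste(head(missing, 5), collapse = ", "))
  if (!length(modules)) stop("no modules to score")
  z <- apply(rel[, names(part$module_of_node), drop = FALSE], 2,
             function(x) suppressWarnings(zscore(x)))
  out <- vapply(modules, function(m) {
    members <- names(part$module_of_node)[part$module_of_node == m]
    if (!length(members)) stop("module ", m, " has no members in the table")
    rowMeans(z[, members, drop = FALSE])
  }, numeric(nrow(rel)))
  dimnames(out) <- list(rownames(rel), paste0("M", modules))
  out
}

#' Per-sample richness of one module
#'
#' Number of module-member OTUs observed (count > 0) in each sample.
#'
#' @param table samples x OTUs count matrix.
#' @param part a [detect_modules()] partition.
#' @param module_id module to score.
#' @return named integer vector over samples.
#' @export
module_richness <- function(table, part, module_id) {
  stopifnot(inherits(part, "module_partition"))
  table <- check_otu_table(table, integer_counts = FALSE)
  members <- names(part$module_of_node)[part$module_of_node == module_id]
  if (!length(members)) stop("unknown module id: ", module_id)
  members <- intersect(members, colnames(table))
  setNames(as.integer(rowSums(table[, members, drop = FALSE] > 0)),
           rownames(table))
}

#' Correlate module abundances with functional variables
#'
#' Spearman rho and p for every (module, functional variable) pair,
#' with significance stars at p < 0.05 / 0.01 / 0.001 mirroring the
#' usual starred-matrix display. No multiple-testing correction is
#' applied to the displayed matrix.
#'
#' @param ma [module_abundance()] matrix (samples x modules).
#' @param fp samples x variables functional-profile matrix on the
#'   original scale (sample ids as rownames).
#' @return a `core_module_report` with matrices `rho`, `p`, `stars`
#'   (modules x variables) and `n_samples`.
#' @export
module_function_correlation <- function(ma, fp) {
  fp <- as.matrix(fp)
  if (is.null(rownames(ma)) || is.null(rownames(fp)))
    stop("both matrices need sample ids as rownames")
  unmatched <- c(setdiff(rownames(ma), rownames(fp)),
                 setdiff(rownames(fp), rownames(ma)))
  if (length(unmatched))
    stop("unmatched sample ids: ", paste(unique(unmatched), collapse = ", "))
  fp <- fp[rownames(ma), , drop = FALSE]
  n <- nrow(ma)
  perms <- if (n <= 9) all_permutations(n) else NULL
  rho <- matrix(NA_real_, ncol(ma), ncol(fp),
                dimnames = list(colnames(ma), colnames(fp)))
  p <- rho
  for (i in seq_len(ncol(ma))) {
    rx <- rank(ma[, i])
    for (j in seq_len(ncol(fp))) {
      ry <- rank(fp[, j])
      r <- suppressWarnings(stats::cor(rx, ry))
      if (!is.finite(r)) { rho[i, j] <- 0; p[i, j] <- 1; next }
      rho[i, j] <- r
      p[i, j] <- spearman_p(rx, ry, r, perms)
    }
  }
  stars <- matrix(symnum_stars(p), nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(rho = rho, p = p, stars = stars, n_samples = n),
            class = "core_module_report")
}

symnum_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' Designate the core module
#'
#' The core module is the one with the greatest number of significant
#' positive correlations with the functional variables; ties are broken
#' by larger mean rho over the significant positives, then by larger
#' module size. Significance for the decision is assessed at `alpha`
#' after Benjamini-Hochberg correction across the whole module x
#' variable matrix (set `p_adjust = "none"` for raw p-values); the
#' correction keeps the false designation rate controlled when many
#' variables are screened, without touching the displayed star matrix.
#'
#' @param report a [module_function_correlation()] result.
#' @param part optional [detect_modules()] partition supplying module
#'   sizes for the final tie-break.
#' @param alpha significance level (default 0.05).
#' @param p_adjust p-value correction for the designation decision
#'   ("BH" default, or any [stats::p.adjust()] method incl. "none").
#' @return integer module id, or `NA` (with a warning) when no module
#'   has any significant positive correlation.
#' @export
designate_core <- function(report, part = NULL, alpha = 0.05,
                           p_adjust = "BH") {
  stopifnot(inherits(report, "core_module_report"))
  p_adj <- matrix(stats::p.adjust(report$p, method = p_adjust),
                  nrow(report$p), ncol(report$p),
                  dimnames = dimnames(report$p))
  sig_pos <- (p_adj < alpha) & (report$rho > 0)
  counts <- rowSums(sig_pos)
  if (all(counts == 0)) {
    warning("no module has a significant positive association with function")
    return(NA_integer_)
  }
  cand <- which(counts == max(counts))
  if (length(cand) > 1) {
    mean_rho <- vapply(cand, function(i)
      mean(report$rho[i, sig_pos[i, ]]), numeric(1))
    cand <- cand[mean_rho == max(mean_rho)]
  }
  if (length(cand) > 1 && !is.null(part)) {
    ids <- as.integer(sub("^M", "", rownames(report$rho)[cand]))
    sz <- part$sizes[as.character(ids)]
    cand <- cand[which.max(sz)]
  }
  as.integer(sub("^M", "", rownames(report$rho)[cand[1]]))
}

#' Regress functional potential on module richness
#'
#' Ordinary least squares of the functional-potential z-score on
#' per-sample richness; reports slope, intercept, R-squared (squared
#' correlation) and the two-sided p of the slope t-test (n - 2 df).
#'
#' @param richness per-sample richness counts.
#' @param fp_z per-sample functional-potential values (z-scores).
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
richness_function_regression <- function(richness, fp_z) {
  if (length(richness) != length(fp_z)) stop("length mismatch")
  if (length(richness) < 3) stop("need >= 3 paired observations")
  if (stats::var(richness) == 0) stop("zero variance in richness")
  fit <- stats::lm(fp_z ~ richness)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]), n = length(richness))
}

#' Combine functional variables into a per-sample functional potential
#'
#' Z-scores each functional variable across samples and averages the
#' z-scores per sample — the "soil functional potential" summary used
#' for diversity-function regressions.
#'
#' @param fp samples x variables functional-profile matrix.
#' @return named numeric vector of per-sample mean z-scores.
#' @export
functional_potential <- function(fp) {
  fp <- as.matrix(fp)
  z <- apply(fp, 2, function(x) suppressWarnings(zscore(x)))
  setNames(rowMeans(z), rownames(fp))
}
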