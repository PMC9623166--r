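#' OTU-table processing
#'
#' An OTU table is a non-negative integer matrix with samples as rows and
#' OTUs as columns; row and column names carry the sample and OTU ids.
#' These helpers follow the vegan convention of operating on plain
#' matrices so results compose with the rest of the ecosystem.
#'
#' @name community
NULL

# Validate samples x OTUs count/abundance matrix; returns the matrix.
check_otu_table <- function(x, integer_counts = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("OTU table must be numeric")
  if (any(x < 0)) stop("OTU table has negative entries")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("OTU", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(x))) stop("duplicate OTU ids")
  if (integer_counts && any(abs(x - round(x)) > 1e-8))
    stop("OTU table must contain integer counts")
  x
}

#' Rarefy an OTU table to an even sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. OTU columns that become all-zero are retained so that ids stay
#' stable across the pipeline.
#'
#' @param table samples x OTUs integer count matrix.
#' @param depth target reads per sample; every sample total must be >= depth.
#' @param seed integer seed controlling the subsampling.
#' @return rarefied count matrix with identical dimnames.
#' @examples
#' m <- matrix(c(60, 40, 30, 70), 2, 2,
#'             dimnames = list(c("a", "b"), c("o1", "o2")))
#' rowSums(rarefy_table(m, 50, seed = 1))
#' @export
rarefy_table <- function(table, depth, seed = 1L) {
  table <- check_otu_table(table)
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  tot <- rowSums(table)
  low <- tot < depth
  if (any(low))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(rownames(table)[low], collapse = ", "))
  # counts are validated above; silence vegan's "observed counts" heuristic
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(table, depth)))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(table)
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @param table samples x OTUs count matrix; every sample total must be > 0.
#' @return matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  table <- check_otu_table(table, integer_counts = FALSE)
  tot <- rowSums(table)
  if (any(tot <= 0))
    stop("all-zero sample(s): ",
         paste(rownames(table)[tot <= 0], collapse = ", "))
  sweep(table, 1, tot, "/")
}

#' Per-sample alpha diversity
#'
#' Shannon index in natural-log units (vegan's default base) and observed
#' richness (count of OTUs with non-zero abundance).
#'
#' @param table samples x OTUs count matrix.
#' @return data.frame with columns `sample`, `shannon`, `richness`.
#' @export
shannon_diversity <- function(table) {
  table <- check_otu_table(table, integer_counts = FALSE)
  if (any(rowSums(table) <= 0)) stop("all-zero sample present")
  data.frame(
    sample = rownames(table),
    shannon = as.numeric(vegan::diversity(table, index = "shannon")),
    richness = as.integer(rowSums(table > 0)),
    row.names = NULL
  )
}

#' Standardise a vector to zero mean and unit variance
#'
#' Uses the sample standard deviation (n - 1 denominator). A
#' zero-variance vector z-scores to all zeros with a warning rather than
#' erroring, so constant background OTUs cannot crash the pipeline.
#'
#' @param values numeric vector of length >= 2.
#' @return numeric vector of z-scores.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need >= 2 values to z-score")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("zero variance: z-scores set to 0")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' Select the dominant OTUs covering a fraction of total abundance
#'
#' OTUs are ranked by mean relative abundance across samples (ties broken
#' by OTU id, ascending) and the shortest prefix whose cumulative mean
#' relative abundance reaches `coverage` is returned. The default keeps
#' the top OTUs accounting for more than 80% of community abundance —
#' the usual dominance cut for co-occurrence networks.
#'
#' @param rel samples x OTUs relative-abundance matrix (rows sum to 1).
#' @param coverage fraction of total mean abundance to cover, in (0, 1].
#' @return character vector of selected OTU ids, most abundant first.
#' @export
select_top_otus <- function(rel, coverage = 0.80) {
  rel <- check_otu_table(rel, integer_counts = FALSE)
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  m <- colMeans(rel)
  ord <- order(-m, colnames(rel))
  m <- m[ord]
  cum <- cumsum(m) / sum(m)
  if (coverage == 1) {
    keep <- m > 0
    return(names(m)[keep])
  }
  n_keep <- which(cum >= coverage - 1e-12)[1]
  names(m)[seq_len(n_keep)]
}
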