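#' Mapping OTUs to reference genomes by 16S identity
#'
#' OTU representative 16S sequences are compared against the 16S copies
#' carried by reference genomes using global alignment with free end
#' gaps (match +1, mismatch -1, gap -2); identity is the fraction of
#' matching columns over the aligned region, excluding end-gap
#' overhangs, approximating "identity across the sequenced regions".
#' Genomes mapping at >= 97% identity to an OTU inherit the OTU's
#' network module, and their per-genome functional-gene content
#' (percentage of genes per genome) is compared between modules.
#'
#' @name genome_map
NULL

#' Reference gene sets for C- and N-cycling categories
#'
#' The eight assayed genes plus canonical reference symbols (18 C-cycling,
#' 14 N-cycling). Pass your own named list to
#' [normalized_gene_copies()] to extend or replace them.
#'
#' @return named list of gene-symbol character vectors.
#' @export
gene_categories <- function() {
  list(
    C_cycling = c("cbbL", "beta_glu", "ChiA", "abfA", "accA", "acsA",
                  "acsE", "amyA", "cdh", "cellobiase", "chiA", "frdA",
                  "glx", "lig", "mcrA", "naglu", "pgu", "xylA"),
    N_cycling = c("nifH", "AOB_amoA", "narG", "nirK", "cnorB", "anfG",
                  "hao", "hdhA", "napA", "nirS", "norB", "nosZ",
                  "nrfA", "ureC")
  )
}

#' Pairwise nucleotide identity by free-end-gap global alignment
#'
#' Needleman-Wunsch with free end gaps (overlap alignment), match +1,
#' mismatch -1, gap -2 (linear). Identity = matches / aligned columns,
#' where end-gap overhangs are excluded and `N` never counts as a match.
#' Because the best-scoring overlap between two unrelated sequences is
#' typically a short chance match, alignments covering less than
#' `min_overlap` of the shorter sequence score an identity of 0 (no
#' meaningful alignment) — the analogue of a BLAST coverage filter.
#'
#' @param seq_a,seq_b nucleotide strings (A/C/G/T/N only).
#' @param min_overlap minimum aligned-region length as a fraction of the
#'   shorter sequence (default 0.5).
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seq_a, seq_b, min_overlap = 0.5) {
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("empty sequence")
    if (grepl("[^ACGTNacgtn]", s))
      stop("non-nucleotide characters in sequence")
  }
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  mat <- matrix(-1, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(mat) <- 1
  mat["N", ] <- -1; mat[, "N"] <- -1  # N never matches, not even N/N
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(a)
  if (cols < min_overlap * min(nchar(seq_a), nchar(seq_b))) return(0)
  matches <- sum(a == b & a != "-" & a != "N")
  matches / cols
}

#' Map OTU sequences to reference genomes
#'
#' All-vs-all identity between OTU representatives and every 16S copy of
#' every genome; a genome maps to an OTU when ANY of its copies meets
#' the threshold, and the best copy's identity is recorded. Each OTU's
#' hit list is sorted by identity, descending.
#'
#' @param otu_seqs named character vector of OTU 16S sequences.
#' @param genomes list of genome records, each a list with `genome_id`,
#'   `ssu_sequences` (character vector), `gene_counts` (named integer
#'   vector) and `total_genes`.
#' @param threshold minimum identity (default 0.97).
#' @return named list (per OTU) of data.frames with columns `genome_id`
#'   and `identity`.
#' @export
map_otus_to_genomes <- function(otu_seqs, genomes, threshold = 0.97) {
  if (!length(otu_seqs)) stop("empty OTU sequence set")
  if (!length(genomes)) stop("empty genome set")
  out <- lapply(names(otu_seqs), function(oid) {
    hits <- lapply(genomes, function(g) {
      ids <- vapply(g$ssu_sequences, function(s)
        pairwise_identity(otu_seqs[[oid]], s), numeric(1))
      best <- max(ids)
      if (best >= threshold)
        data.frame(genome_id = g$genome_id, identity = best)
      else NULL
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits))
      hits <- data.frame(genome_id = character(0), identity = numeric(0))
    hits[order(-hits$identity, hits$genome_id), , drop = FALSE]
  })
  names(out) <- names(otu_seqs)
  out
}

#' Normalised per-genome functional-gene content
#'
#' For each genome, the percentage of its genes belonging to each gene
#' (or gene category): 100 * copy count / total genes; category values
#' sum over member genes.
#'
#' @param genomes list of genome records (see [map_otus_to_genomes()]).
#' @param gene_sets named list of gene-symbol vectors (default:
#'   [gene_categories()]).
#' @return data.frame, one row per genome, one column per gene set.
#' @export
normalized_gene_copies <- function(genomes, gene_sets = gene_categories()) {
  rows <- lapply(genomes, function(g) {
    if (is.null(g$total_genes) || g$total_genes <= 0)
      stop("genome ", g$genome_id, " has zero total genes")
    pct <- vapply(gene_sets, function(set)
      100 * sum(g$gene_counts[intersect(set, names(g$gene_counts))]) /
        g$total_genes, numeric(1))
    data.frame(genome_id = g$genome_id, t(pct))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare functional-gene content between network modules
#'
#' Genomes are assigned to the module of their best-identity OTU; for
#' every gene set, per-module mean/median percentages are reported and
#' module pairs are compared with a two-sided Mann-Whitney U test.
#'
#' @param map [map_otus_to_genomes()] result.
#' @param part a [detect_modules()] partition over the OTUs.
#' @param percentages [normalized_gene_copies()] table.
#' @return list with `assignment` (genome -> module), `summary`
#'   (module x gene-set mean/median) and `tests` (pairwise U statistics
#'   and p-values per gene set).
#' @export
compare_module_gene_content <- function(map, part, percentages) {
  stopifnot(inherits(part, "module_partition"))
  # genome -> (best identity, module of that OTU)
  best <- list()
  for (oid in names(map)) {
    mod <- part$module_of_node[oid]
    if (is.na(mod)) next
    h <- map[[oid]]
    for (k in seq_len(nrow(h))) {
      gid <- h$genome_id[k]
      if (is.null(best[[gid]]) || h$identity[k] > best[[gid]]$identity)
        best[[gid]] <- list(identity = h$identity[k], module = mod)
    }
  }
  if (!length(best)) stop("no genome mapped to a module node")
  assignment <- data.frame(
    genome_id = names(best),
    module = vapply(best, function(x) as.integer(x$module), integer(1)),
    identity = vapply(best, function(x) x$identity, numeric(1)),
    row.names = NULL)
  df <- merge(assignment, percentages, by = "genome_id")
  sets <- setdiff(colnames(percentages), "genome_id")
  mods <- sort(unique(df$module))
  n_by_mod <- table(df$module)
  small <- as.integer(names(n_by_mod)[n_by_mod < 2])
  if (length(small)) {
    warning("module(s) with < 2 mapped genomes excluded: ",
            paste(small, collapse = ", "))
    mods <- setdiff(mods, small)
  }
  if (length(mods) < 2) stop("need >= 2 modules with >= 2 mapped genomes")
  summary_df <- do.call(rbind, lapply(mods, function(m) {
    sub <- df[df$module == m, , drop = FALSE]
    data.frame(module = m, gene_set = sets,
               n = nrow(sub),
               mean = vapply(sets, function(s) mean(sub[[s]]), numeric(1)),
               median = vapply(sets, function(s) median(sub[[s]]),
                               numeric(1)),
               row.names = NULL)
  }))
  pairs <- combn(mods, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    m1 <- pairs[1, k]; m2 <- pairs[2, k]
    do.call(rbind, lapply(sets, function(s) {
      x <- df[[s]][df$module == m1]; y <- df[[s]][df$module == m2]
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      data.frame(module_a = m1, module_b = m2, gene_set = s,
                 U = unname(wt$statistic), p = wt$p.value,
                 row.names = NULL)
    }))
  }))
  list(assignment = assignment, summary = summary_df, tests = tests)
}
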