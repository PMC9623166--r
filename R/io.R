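#' File readers and writers
#'
#' All tabular I/O is UTF-8, tab-delimited with a mandatory header row;
#' sample ids are row keys (first column). Networks are exported as
#' GraphML and a 3-column edge-list TSV; partitions, keystones and run
#' reports as JSON; sequences as FASTA; configs as YAML.
#'
#' @name io
NULL

#' @rdname io
#' @param path file path.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  check_otu_table(m)
}

#' @rdname io
#' @param table samples x OTUs matrix.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(sample = rownames(table), table, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname io
#' @export
read_sample_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param df data.frame to write.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname io
#' @export
read_functional_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param fp samples x variables matrix.
#' @export
write_functional_profile <- function(fp, path) {
  df <- data.frame(sample = rownames(fp), fp, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname io
#' @param ts data.frame with columns sample, time_h, value.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.csv(ts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname io
#' @param net a `co_network`.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_conet_graph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname io
#' @export
write_edge_list <- function(net, path) {
  g <- as_conet_graph(net)
  el <- igraph::as_edgelist(g)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   rho = if (igraph::ecount(g)) igraph::E(g)$rho
                   else numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname io
#' @param x object serialisable by jsonlite.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
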