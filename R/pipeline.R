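#' End-to-end pipeline
#'
#' Orchestrates OTU-table processing, network inference, module
#' detection, keystone selection and module-function linkage from a
#' single configuration, writing all artifacts plus a machine-readable
#' JSON report. The report is fully determined by (inputs, config,
#' seed).
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param otu_table path to the OTU-table TSV (first column sample id).
#' @param metadata optional path to a metadata TSV with a `treatment`
#'   column.
#' @param functional_profile optional path to the functional-profile TSV.
#' @param out_dir output directory (created if needed).
#' @param coverage dominant-OTU coverage fraction (default 0.80).
#' @param r_min,p_max edge-filter thresholds (defaults 0.8, 0.01).
#' @param keystone_k keystone count (default 20).
#' @param min_module_size minimum main-module size (default 5).
#' @param rarefaction_depth reads/sample for rarefaction, or `NULL` to
#'   skip (default 28795 when rarefying).
#' @param identity_threshold genome-mapping identity cut (default 0.97).
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(otu_table, out_dir, metadata = NULL,
                       functional_profile = NULL, coverage = 0.80,
                       r_min = 0.8, p_max = 0.01, keystone_k = 20L,
                       min_module_size = 5L, rarefaction_depth = NULL,
                       identity_threshold = 0.97, seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1, r_min > 0, r_min <= 1,
            p_max > 0, p_max <= 1, keystone_k >= 1,
            is.null(rarefaction_depth) || rarefaction_depth >= 1)
  structure(list(otu_table = otu_table, metadata = metadata,
                 functional_profile = functional_profile,
                 out_dir = out_dir, coverage = coverage, r_min = r_min,
                 p_max = p_max, keystone_k = as.integer(keystone_k),
                 min_module_size = as.integer(min_module_size),
                 rarefaction_depth = rarefaction_depth,
                 identity_threshold = identity_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

log_stage <- function(con, stage, t0, ...) {
  line <- sprintf("[%s] elapsed=%.2fs %s", stage,
                  as.numeric(proc.time()[3] - t0),
                  paste(sprintf("%s=%s", names(list(...)), list(...)),
                        collapse = " "))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Stages: rarefaction (optional) -> relative abundance -> alpha
#' diversity -> dominant-OTU selection -> Spearman network -> module
#' detection -> centralities/keystones -> module abundance/richness ->
#' module-function correlation -> core-module designation -> richness
#' regression -> treatment statistics (when metadata is supplied).
#' Writes rarefied table, network (GraphML + edge list), partition,
#' keystones and a JSON `report.json` under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly identical to `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  t0 <- proc.time()[3]

  counts <- read_otu_table(config$otu_table)
  log_stage(logf, "load", t0, samples = nrow(counts), otus = ncol(counts))

  if (!is.null(config$rarefaction_depth)) {
    counts <- rarefy_table(counts, config$rarefaction_depth,
                           seed = config$seed)
    write_otu_table(counts, file.path(config$out_dir, "rarefied.tsv"))
    log_stage(logf, "rarefy", t0, depth = config$rarefaction_depth)
  }

  rel <- relative_abundance(counts)
  div <- shannon_diversity(counts)
  top <- select_top_otus(rel, config$coverage)
  log_stage(logf, "select", t0, top_otus = length(top))

  corr <- spearman_matrix(rel[, top, drop = FALSE])
  net <- filter_edges(corr, config$r_min, config$p_max)
  n_edges <- igraph::ecount(net$graph)
  write_graphml(net, file.path(config$out_dir, "network.graphml"))
  write_edge_list(net, file.path(config$out_dir, "edges.tsv"))
  log_stage(logf, "network", t0, nodes = length(top), edges = n_edges)

  part <- NULL; keystones <- NULL; core <- NA_integer_
  overlap <- NA_integer_; mod_report <- NULL
  if (n_edges > 0) {
    part <- detect_modules(net, seed = config$seed,
                           min_size = config$min_module_size)
    cent <- centralities(net)
    keystones <- select_keystones(cent, config$keystone_k)
    write_json_report(
      list(module_of_node = as.list(part$module_of_node),
           main_modules = part$main_modules,
           modularity = part$modularity),
      file.path(config$out_dir, "partition.json"))
    write_sample_table(keystones, file.path(config$out_dir, "keystones.tsv"))
    log_stage(logf, "modules", t0,
              n_modules = length(part$main_modules))
  } else {
    log_stage(logf, "modules", t0, n_modules = 0)
  }

  fp <- NULL
  if (!is.null(config$functional_profile) && !is.null(part) &&
      length(part$main_modules)) {
    fp <- read_functional_profile(config$functional_profile)
    ma <- module_abundance(rel, part)
    mf <- module_function_correlation(ma, fp)
    core <- suppressWarnings(designate_core(mf, part))
    mod_report <- list(rho = mf$rho, p = mf$p, stars = mf$stars)
    if (!is.na(core) && !is.null(keystones)) {
      key_modules <- part$module_of_node[keystones$node]
      overlap <- sum(key_modules == core, na.rm = TRUE)
    }
    log_stage(logf, "core_module", t0, core = core,
              keystone_overlap = overlap)
  }

  stats_block <- NULL
  if (!is.null(config$metadata)) {
    md <- read_sample_table(config$metadata)
    if ("treatment" %in% colnames(md) &&
        length(unique(md$treatment)) >= 2) {
      md <- md[match(rownames(counts), md$sample), ]
      an <- anova_tukey(div$shannon, md$treatment)
      pm <- permanova(bray_curtis(rel), md$treatment,
                      seed = config$seed)
      stats_block <- list(
        shannon_anova = list(F = an$F, p = an$p,
                             letters = as.list(an$letters)),
        permanova = list(F = pm$F, r_squared = pm$r_squared, p = pm$p))
      log_stage(logf, "stats", t0, permanova_p = pm$p)
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("rhizocore")),
    config = config[setdiff(names(config), "out_dir")],
    n_samples = nrow(counts), n_otus = ncol(counts),
    n_selected = length(top), n_edges = n_edges,
    density = if (length(top) >= 2) network_density(net) else NA,
    module_sizes = if (!is.null(part)) as.list(part$sizes) else list(),
    main_modules = if (!is.null(part)) part$main_modules else integer(0),
    modularity = if (!is.null(part)) part$modularity else NA,
    keystones = if (!is.null(keystones)) keystones$node else character(0),
    core_module = core,
    keystone_core_overlap = overlap,
    module_function = mod_report,
    group_stats = stats_block,
    diversity = div
  )
  class(report$config) <- NULL
  write_json_report(report, file.path(config$out_dir, "report.json"))
  log_stage(logf, "done", t0)
  invisible(report)
}

#' Write a full synthetic dataset to disk
#'
#' Generates a planted-structure community plus functional profile,
#' rate time series and 16S fixtures, writing OTU table, metadata,
#' functional profile, time-series CSV, FASTA pair and the truth JSON.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return invisible list of generated objects.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  com <- simulate_community(config)
  fp <- simulate_functions(com$truth, config)
  ts <- do.call(rbind, lapply(seq_len(nrow(com$counts)), function(i) {
    d <- simulate_rate_timeseries(slope = 0.5, intercept = 1,
                                  noise_sd = 0.05,
                                  seed = config$seed + 2L + i)
    cbind(sample = rownames(com$counts)[i], d)
  }))
  seqs <- simulate_sequences(n_genomes = 10, length = 300,
                             identity_to_otu = 0.98, seed = config$seed)
  write_otu_table(com$counts, file.path(out_dir, "otu_table.tsv"))
  write_sample_table(com$metadata, file.path(out_dir, "metadata.tsv"))
  write_functional_profile(fp, file.path(out_dir, "functional_profile.tsv"))
  write_timeseries(ts, file.path(out_dir, "rate_timeseries.csv"))
  write_fasta(seqs$otu_seqs, file.path(out_dir, "otu_seqs.fasta"))
  write_fasta(seqs$genome_seqs, file.path(out_dir, "genome_16s.fasta"))
  write_json_report(
    list(module_of_otu = as.list(com$truth$module_of_otu),
         core_module_id = com$truth$core_module_id,
         seed = com$truth$seed),
    file.path(out_dir, "truth.json"))
  invisible(list(community = com, functions = fp, timeseries = ts,
                 sequences = seqs))
}
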