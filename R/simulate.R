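#' Synthetic communities with planted network structure
#'
#' The generator plants a block-correlated community: each module m has a
#' per-sample latent factor f_m(s) ~ N(0, 1); a member OTU's log-intensity
#' is loading * f_m(s) + noise_sd * eps, a background OTU's log-intensity
#' is pure noise (noise_sd * eps). Intensities are exponentiated,
#' normalised to proportions and counts are drawn multinomially at the
#' sequencing depth, so every simulated sample sums exactly to the depth.
#' One module (the planted "core") drives functional-gene abundances and
#' process rates via `function_effect`, mimicking a module whose taxa are
#' positively associated with soil C/N-cycling potential.
#'
#' These are statistical stand-ins: no published generative model exists
#' for such data, so defaults emulate the 18-sample, 3-treatment,
#' 6-replicate field design at a 28,795-read depth.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' @param n_samples number of samples (default 18: 3 treatments x 6 reps).
#' @param n_modules number of planted modules.
#' @param otus_per_module OTUs per planted module.
#' @param n_background_otus OTUs with no module membership (pure noise).
#' @param loading factor weight on the module latent factor (default 0.9).
#' @param noise_sd sd of the per-OTU log-scale noise (default 0.3).
#' @param core_module_index which planted module drives function (1-based).
#' @param function_effect slope linking the core factor to log gene
#'   abundance (default 1).
#' @param sequencing_depth reads per sample (default 28795).
#' @param n_treatments number of treatment groups for the metadata labels.
#' @param seed integer master seed; per-stage child seeds are derived by
#'   fixed offsets (community +0, functions +1, rates +2, sequences +3).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 18L, n_modules = 3L, otus_per_module = 25L,
                       n_background_otus = 25L, loading = 0.9, noise_sd = 0.3,
                       core_module_index = 1L, function_effect = 1,
                       sequencing_depth = 28795L, n_treatments = 3L,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_modules = as.integer(n_modules),
              otus_per_module = as.integer(otus_per_module),
              n_background_otus = as.integer(n_background_otus),
              loading = loading, noise_sd = noise_sd,
              core_module_index = as.integer(core_module_index),
              function_effect = function_effect,
              sequencing_depth = as.integer(sequencing_depth),
              n_treatments = as.integer(n_treatments),
              seed = as.integer(seed))
  if (cfg$n_samples < 1 || cfg$n_modules < 1 || cfg$otus_per_module < 1)
    stop("counts must be >= 1")
  if (cfg$n_background_otus < 0) stop("n_background_otus must be >= 0")
  if (cfg$loading < 0 || cfg$noise_sd <= 0) stop("loading >= 0 and noise_sd > 0 required")
  if (cfg$sequencing_depth < 1) stop("sequencing_depth must be positive")
  if (cfg$core_module_index < 1 || cfg$core_module_index > cfg$n_modules)
    stop("core_module_index must name a planted module")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an OTU count table with planted modules
#'
#' @param config a [sim_config()].
#' @return list with `counts` (samples x OTUs integer matrix), `metadata`
#'   (sample, treatment, replicate) and `truth` (a `sim_truth`:
#'   `module_of_otu` — NA for background OTUs, `core_module_id`,
#'   `factor_values` samples x modules, `seed`).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_otus <- config$n_modules * config$otus_per_module + config$n_background_otus
  otu_ids <- sprintf("OTU%03d", seq_len(n_otus))
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  module_of_otu <- rep(NA_integer_, n_otus)
  module_of_otu[seq_len(config$n_modules * config$otus_per_module)] <-
    rep(seq_len(config$n_modules), each = config$otus_per_module)
  names(module_of_otu) <- otu_ids

  res <- with_seed(config$seed, {
    f <- matrix(stats::rnorm(config$n_samples * config$n_modules),
                config$n_samples, config$n_modules,
                dimnames = list(sample_ids, paste0("M", seq_len(config$n_modules))))
    eps <- matrix(stats::rnorm(config$n_samples * n_otus, sd = config$noise_sd),
                  config$n_samples, n_otus)
    logint <- eps
    planted <- !is.na(module_of_otu)
    logint[, planted] <- logint[, planted] +
      config$loading * f[, module_of_otu[planted], drop = FALSE]
    intens <- exp(logint)
    prop <- intens / rowSums(intens)
    counts <- t(apply(prop, 1, function(p)
      stats::rmultinom(1, config$sequencing_depth, p)[, 1]))
    list(f = f, counts = counts)
  })
  counts <- res$counts
  dimnames(counts) <- list(sample_ids, otu_ids)
  storage.mode(counts) <- "integer"

  metadata <- data.frame(
    sample = sample_ids,
    treatment = paste0("T", rep_len(seq_len(config$n_treatments),
                                    config$n_samples)),
    replicate = as.integer(ave(seq_len(config$n_samples),
                               rep_len(seq_len(config$n_treatments),
                                       config$n_samples),
                               FUN = seq_along)),
    row.names = NULL
  )

  truth <- structure(list(module_of_otu = module_of_otu,
                          core_module_id = config$core_module_index,
                          factor_values = res$f,
                          gene_effects = NULL, rate_slopes = NULL,
                          seed = config$seed),
                     class = "sim_truth")
  list(counts = counts, metadata = metadata, truth = truth)
}

# Names of the simulated functional variables.
rhizocore_genes <- function()
  c("cbbL", "beta_glu", "ChiA", "nifH", "AOB_amoA", "narG", "nirK", "cnorB")
rhizocore_rates <- function() c("rubisco", "pnr", "dea")

#' Simulate functional-gene abundances and process rates
#'
#' For each of the 8 functional genes and 3 process rates, the per-sample
#' log-value is `function_effect * f_core(s) + noise`, exponentiated onto
#' the original scale. Gene baselines are 1e6 copies per g dry soil and
#' rate baselines 10 rate units — arbitrary but realistic scales, since
#' the abundance-function link is what matters downstream.
#'
#' @param truth `sim_truth` from [simulate_community()].
#' @param config the same [sim_config()].
#' @return samples x 11 matrix of positive values, with the true slopes in
#'   `attr(, "gene_effects")`.
#' @export
simulate_functions <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  core <- truth$core_module_id
  if (is.na(core) || core > ncol(truth$factor_values))
    stop("unknown core module id: ", core)
  f_core <- truth$factor_values[, core]
  vars <- c(rhizocore_genes(), rhizocore_rates())
  base <- c(rep(log(1e6), 8), rep(log(10), 3))
  out <- with_seed(config$seed + 1L, {
    vapply(seq_along(vars), function(j) {
      exp(base[j] + config$function_effect * f_core +
            stats::rnorm(length(f_core), sd = config$noise_sd))
    }, numeric(length(f_core)))
  })
  dimnames(out) <- list(rownames(truth$factor_values), vars)
  attr(out, "gene_effects") <- setNames(rep(config$function_effect,
                                            length(vars)), vars)
  out
}

#' Simulate a noisy linear assay time series
#'
#' conc(t) = slope * t + intercept + Gaussian noise; the default grid is
#' the 24-154 h incubation used for slurry rate assays.
#'
#' @param slope true rate (concentration per hour).
#' @param intercept concentration at t = 0.
#' @param times sampling times in hours (>= 2 distinct values).
#' @param noise_sd sd of the additive measurement noise.
#' @param seed integer seed.
#' @return data.frame with columns `time_h` and `value`.
#' @export
simulate_rate_timeseries <- function(slope, intercept = 0,
                                     times = c(24, 48, 72, 96, 130, 154),
                                     noise_sd = 0, seed = 1L) {
  if (length(unique(times)) < 2) stop("need >= 2 distinct time points")
  vals <- with_seed(seed,
                    slope * times + intercept +
                      stats::rnorm(length(times), sd = noise_sd))
  data.frame(time_h = times, value = vals)
}

#' Simulate paired OTU / genome 16S sequences at known identity
#'
#' Each genome 16S sequence is derived from its OTU representative by
#' mutating exactly `round((1 - identity) * length)` positions to
#' different bases, so pairwise identity fixtures are deterministic.
#'
#' @param n_genomes number of OTU/genome pairs.
#' @param length sequence length in bases (>= 1).
#' @param identity_to_otu identity fraction in \[0, 1\], recycled across
#'   genomes.
#' @param seed integer seed.
#' @return list with character vectors `otu_seqs`, `genome_seqs` and the
#'   list `mutated_positions`.
#' @export
simulate_sequences <- function(n_genomes, length, identity_to_otu,
                               seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  if (any(identity_to_otu < 0 | identity_to_otu > 1))
    stop("identity must be in [0, 1]")
  identity_to_otu <- rep_len(identity_to_otu, n_genomes)
  bases <- c("A", "C", "G", "T")
  with_seed(seed + 3L, {
    otu <- character(n_genomes); gen <- character(n_genomes)
    mut <- vector("list", n_genomes)
    for (i in seq_len(n_genomes)) {
      s <- sample(bases, length, replace = TRUE)
      n_mut <- round((1 - identity_to_otu[i]) * length)
      pos <- if (n_mut > 0) sort(sample.int(length, n_mut)) else integer(0)
      g <- s
      for (p in pos) g[p] <- sample(setdiff(bases, s[p]), 1)
      otu[i] <- paste(s, collapse = "")
      gen[i] <- paste(g, collapse = "")
      mut[[i]] <- pos
    }
    names(otu) <- sprintf("OTU%03d", seq_len(n_genomes))
    names(gen) <- sprintf("G%03d", seq_len(n_genomes))
    list(otu_seqs = otu, genome_seqs = gen, mutated_positions = mut)
  })
}
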