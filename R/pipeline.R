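#' Run the full analysis pipeline from a config file
#'
#' Executes the whole workflow on synthetic data: simulate a multi-locus
#' dataset under a demographic model, compute per-sample heterozygosity,
#' classify dog/wolf variant sharing, build the divergence matrix and
#' bootstrapped neighbor-joining tree, tally quartet site patterns with
#' D statistics, optionally score alternative models, and emit a
#' calibration report. Every stage writes its outputs under `outdir` and
#' all parameters and seeds are recorded in a JSON run manifest, so an
#' identical config yields identical outputs.
#'
#' The YAML config supports keys: `model` (path to a model file, or the
#' name of a bundled model), `seed`, `n_loci`, `locus_length`, `mu`,
#' `samples` (leaf names; default all), `dogs`/`wolves` (group labels),
#' `outgroup`, `window_loci`, `block_loci`, `bootstrap_reps`,
#' `het_window_bp`, `alt_models` (named list of model files to score),
#' and `outdir` (overridden by the `outdir` argument if given).
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: '%s'", config), call. = FALSE)
    yaml::read_yaml(config)
  } else config
  defaults <- list(seed = 1L, n_loci = 500L, locus_length = 1000L,
                   mu = 1e-8, window_loci = 10L, block_loci = 50L,
                   bootstrap_reps = 100L, het_window_bp = 1e5,
                   outdir = "canidemog_run")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$model))
    stop("config error: 'model' entry is required", call. = FALSE)

  model <- if (file.exists(cfg$model)) read_demographic_model(cfg$model)
  else canid_model(cfg$model)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  samples <- if (is.null(cfg$samples)) model$leaves else
    unlist(cfg$samples)
  ls <- stage("simulate", simulate_dataset(
    model, n_loci = cfg$n_loci, locus_length = cfg$locus_length,
    mu = cfg$mu, seed = cfg$seed,
    samples = setNames(rep(2L, length(samples)), samples)))
  write_vcf(ls, file.path(cfg$outdir, "loci.vcf"))

  het <- stage("het", lapply(setNames(nm = samples), function(s)
    windowed_heterozygosity(ls, s, window_bp = cfg$het_window_bp)))
  het_rates <- vapply(het, attr, numeric(1), "genome_rate")
  for (s in samples)
    write_bed(het[[s]], file.path(cfg$outdir,
                                  sprintf("het_%s.bed", s)))

  sharing <- NULL
  dogs <- unlist(cfg$dogs); wolves <- unlist(cfg$wolves)
  if (length(dogs) && length(wolves)) {
    sharing <- stage("sharing", classify_variant_sites(ls, dogs, wolves))
    utils::write.table(
      data.frame(category = names(sharing$counts),
                 count = as.integer(sharing$counts),
                 percent = round(sharing$percent, 1)),
      file.path(cfg$outdir, "sharing.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }

  dm <- stage("distances", distance_matrix(
    ls, mode = "conservative", window_loci = cfg$window_loci))
  write_phylip(dm, file.path(cfg$outdir, "divergence.phylip"))
  tree <- stage("tree", window_bootstrap_support(
    dm, n_reps = cfg$bootstrap_reps, seed = cfg$seed,
    outgroup = cfg$outgroup))
  write_newick(tree, file.path(cfg$outdir, "nj_tree.nwk"))

  patterns <- NULL
  if (!is.null(cfg$outgroup) && length(samples) >= 4L) {
    ingroup <- setdiff(samples, cfg$outgroup)
    quartets <- enumerate_quartets(ingroup, cfg$outgroup)
    patterns <- stage("site_patterns", pattern_frequency_table(
      ls, quartets, block_size = cfg$block_loci,
      jackknife = cfg$n_loci / cfg$block_loci >= 20))
    write_pattern_table(patterns,
                        file.path(cfg$outdir, "site_patterns.tsv"))
  }

  modelfit <- NULL
  if (!is.null(cfg$alt_models) && !is.null(patterns)) {
    modelfit <- stage("modelfit", {
      scores <- lapply(names(cfg$alt_models), function(nm) {
        alt <- read_demographic_model(cfg$alt_models[[nm]])
        sim <- simulate_dataset(
          alt, n_loci = cfg$n_loci, locus_length = cfg$locus_length,
          mu = cfg$mu, seed = cfg$seed + 1L,
          samples = setNames(rep(2L, length(samples)), samples))
        tab <- pattern_frequency_table(
          sim, enumerate_quartets(setdiff(samples, cfg$outgroup),
                                  cfg$outgroup),
          block_size = cfg$block_loci)
        data.frame(model = nm,
                   score = model_fit_error(patterns, tab)$score)
      })
      do.call(rbind, scores)
    })
    utils::write.table(modelfit, file.path(cfg$outdir, "model_fit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  calib <- stage("calibration", {
    int <- model$pop[model$pop$t_start > 0, ]
    data.frame(population = int$name,
               split_kya = round(int$t_start * model$gen_time / 1000, 1),
               ne = int$ne)
  })
  utils::write.table(calib, file.path(cfg$outdir, "calibration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "canidemog",
    version = as.character(utils::packageVersion("canidemog")),
    model = model$name, config = cfg[order(names(cfg))],
    samples = samples,
    het_genome_rates = as.list(het_rates),
    n_variant_sites = nrow(ls$geno))
  jsonlite::write_json(manifest,
                       file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(locus_set = ls, het = het, sharing = sharing,
                 distances = dm, tree = tree, patterns = patterns,
                 modelfit = modelfit, manifest = manifest))
}
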