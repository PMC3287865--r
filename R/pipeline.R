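# Whole-pipeline runs: config handling, the simulate and scan stages,
# and the run manifest that makes every random draw attributable.

#' Default run configuration
#'
#' Scan defaults: 100-SNP bins with tail threshold 25, 1000 permutations,
#' alpha 0.05, top 10 regions, private variants only. Simulation keys
#' mirror the [sim_config()] defaults and are only used by
#' [run_simulate()].
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(bin_size = 100L, tail_threshold = NULL, n_perm = 1000L,
       alpha = 0.05, top_k = 10L, seed = 17L, format = "auto",
       plus_one_correction = FALSE, ties = "exceed", max_count = 1L,
       # simulation keys
       n_subjects = 697L, n_cases = 209L, m_snps = 24487L,
       n_chromosomes = 22L, prop_private = 0.385,
       prop_maf_lt_1pct = 0.74, n_replicates = 200L)
}

#' Load a YAML run configuration
#'
#' Reads a YAML file of configuration keys and merges it over
#' [default_config()]; keys in `overrides` (e.g. from command-line
#' flags) win over both. Unknown keys are an error.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides named list applied last.
#' @return named configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config key(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(user)] <- user
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

write_manifest <- function(path, stage, config, inputs = character(),
                           seeds = list(), timings = list()) {
  digest <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    stage = stage,
    package = "binscan",
    version = as.character(utils::packageVersion("binscan")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[!vapply(config, is.null, logical(1))],
    input_md5 = digest,
    seeds = seeds,
    timings_sec = timings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Generate and write a synthetic study
#'
#' Runs the synthetic-data generator with the configuration's simulation
#' keys and writes `genotypes.tsv`, `phenotypes.tsv`, `truth.tsv`, and
#' `manifest.json` into `out_dir`. Deterministic per `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param config configuration list from [load_config()], or a list of
#'   overrides merged over defaults.
#' @param causal optional causal design data frame (`snp`, `effect`)
#'   passed through to [sim_config()].
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, config = list(), causal = NULL) {
  if (!all(names(default_config()) %in% names(config))) {
    config <- load_config(NULL, overrides = config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  sc <- sim_config(n_subjects = config$n_subjects,
                   n_cases = config$n_cases,
                   m_snps = config$m_snps,
                   n_chromosomes = config$n_chromosomes,
                   prop_private = config$prop_private,
                   prop_maf_lt_1pct = config$prop_maf_lt_1pct,
                   n_replicates = config$n_replicates,
                   causal = causal,
                   master_seed = config$seed)
  ds <- generate_genotypes(sc)
  t1 <- Sys.time()
  sim <- generate_phenotypes(ds, sc)
  t2 <- Sys.time()
  gpath <- file.path(out_dir, "genotypes.tsv")
  ppath <- file.path(out_dir, "phenotypes.tsv")
  tpath <- file.path(out_dir, "truth.tsv")
  write_genotypes(ds, gpath)
  write_phenotypes(sim$phenotypes, ppath)
  write_truth(sim$truth, tpath)
  write_manifest(
    file.path(out_dir, "manifest.json"), "simulate", config,
    inputs = c(gpath, ppath, tpath),
    seeds = list(master_seed = config$seed,
                 genotype_seed = derive_seed(config$seed, 0L),
                 replicate_seeds = vapply(seq_len(sc$n_replicates),
                                          function(r) derive_seed(config$seed, r),
                                          integer(1))),
    timings = list(genotypes = as.numeric(difftime(t1, t0, units = "secs")),
                   phenotypes = as.numeric(difftime(t2, t1, units = "secs"))))
  invisible(out_dir)
}

#' Run the full region scan
#'
#' Reads genotypes and phenotype replicates, partitions the SNPs into
#' fixed bins, permutation-tests every testable bin in every replicate,
#' aggregates return frequencies, and writes five files into `out_dir`:
#' `partition.tsv` (BED-like), `replicate_results.tsv`,
#' `return_frequency.tsv`, `top_regions.tsv`, and `manifest.json`.
#' Re-running with the same inputs and seed reproduces the result tables
#' byte for byte.
#'
#' @param genotypes path to the genotype file (VCF or TSV dialect).
#' @param phenotypes path to the phenotype TSV.
#' @param out_dir output directory (created if needed).
#' @param config configuration list, as in [run_simulate()].
#' @return the [return_frequency()] table, invisibly.
#' @export
run_scan <- function(genotypes, phenotypes, out_dir, config = list()) {
  if (!all(names(default_config()) %in% names(config))) {
    config <- load_config(NULL, overrides = config)
  }
  if (!file.exists(genotypes)) stop("genotype file not found: ", genotypes)
  if (!file.exists(phenotypes)) {
    stop("phenotype file not found: ", phenotypes)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  ds <- read_genotypes(genotypes, format = config$format)
  ph <- read_phenotypes(phenotypes, dataset = ds)
  t1 <- Sys.time()
  part <- partition_bins(ds, bin_size = config$bin_size,
                         tail_threshold = config$tail_threshold)
  scan <- bin_scan(ds, ph, part, n_perm = config$n_perm,
                   alpha = config$alpha, seed = config$seed,
                   plus_one = config$plus_one_correction,
                   ties = config$ties, max_count = config$max_count)
  t2 <- Sys.time()
  rf <- return_frequency(scan)
  top <- rank_regions(rf, k = config$top_k)
  write_partition(part, file.path(out_dir, "partition.tsv"))
  write_scan_results(scan, file.path(out_dir, "replicate_results.tsv"))
  write_return_frequency(rf, file.path(out_dir, "return_frequency.tsv"))
  utils::write.table(top, file.path(out_dir, "top_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(
    file.path(out_dir, "manifest.json"), "scan", config,
    inputs = c(genotypes, phenotypes),
    seeds = list(master_seed = config$seed,
                 replicate_seeds = vapply(
                   seq_len(nrow(ph$statuses)),
                   function(r) derive_seed(config$seed, r, stream = 1L),
                   integer(1))),
    timings = list(read = as.numeric(difftime(t1, t0, units = "secs")),
                   scan = as.numeric(difftime(t2, t1, units = "secs"))))
  invisible(rf)
}

#' Report the top regions of a finished scan
#'
#' Reads `return_frequency.tsv` from a [run_scan()] output directory and
#' prints (and returns) the top-k table.
#'
#' @param scan_dir a [run_scan()] output directory.
#' @param top_k number of regions to report.
#' @return data frame of ranked regions.
#' @export
run_report <- function(scan_dir, top_k = 10) {
  path <- file.path(scan_dir, "return_frequency.tsv")
  if (!file.exists(path)) stop("no return_frequency.tsv under ", scan_dir)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  top <- rank_regions(tab, k = top_k)
  print(top)
  invisible(top)
}
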