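# Synthetic data emulating a fixed-genotype, multi-replicate case-control
# design with a heavily skewed MAF spectrum dominated by private and rare
# variants.

#' Simulation configuration
#'
#' Defaults describe the study design the scan was built for: 697
#' subjects split 209 cases / 488 controls, 24,487 exonic SNPs across 22
#' autosomes, a MAF spectrum in which about 74% of SNPs have MAF below 1%
#' and private (singleton) variants outnumber common ones (0.385 of all
#' SNPs), and 200 phenotype replicates generated on one fixed genotype
#' matrix. All of it can be scaled down for experimentation.
#'
#' Phenotypes follow a liability-threshold model: each subject's liability
#' is the effect-weighted sum of their dosages at the causal SNPs plus
#' standard Gaussian noise drawn fresh per replicate, and the `n_cases`
#' subjects with the highest liability are the cases, so every replicate
#' has exactly the designed case count.
#'
#' @param n_subjects number of subjects N.
#' @param n_cases number of affected subjects per replicate.
#' @param chromosome_snp_counts integer vector of SNPs per chromosome;
#'   `NULL` distributes `m_snps` over `n_chromosomes` chromosomes with
#'   linearly declining sizes (a stylised karyotype).
#' @param m_snps total number of SNPs M (used when
#'   `chromosome_snp_counts` is `NULL`).
#' @param n_chromosomes number of chromosomes (used when
#'   `chromosome_snp_counts` is `NULL`).
#' @param prop_private fraction of SNPs that are private (singletons).
#' @param prop_maf_lt_1pct fraction of SNPs with MAF < 1%, private
#'   included; must be at least `prop_private`.
#' @param maf_rare the rare/common MAF boundary (default 0.01).
#' @param n_replicates number of phenotype replicates R.
#' @param causal `NULL` for a null model, or a data frame with columns
#'   `snp` (SNP index or id) and `effect` (liability shift per
#'   minor-allele copy).
#' @param force_private_snps integer vector of SNP indices forced to be
#'   private regardless of the drawn spectrum -- useful for planting a
#'   dense block of causal singletons in a known bin.
#' @param master_seed integer seed governing every random draw.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 697, n_cases = 209,
                       chromosome_snp_counts = NULL,
                       m_snps = 24487, n_chromosomes = 22,
                       prop_private = 0.385, prop_maf_lt_1pct = 0.74,
                       maf_rare = 0.01,
                       n_replicates = 200, causal = NULL,
                       force_private_snps = integer(),
                       master_seed = 17L) {
  if (n_cases >= n_subjects || n_cases < 1) {
    stop("n_cases must lie in [1, n_subjects - 1]")
  }
  if (prop_private < 0 || prop_private > 1 ||
      prop_maf_lt_1pct < prop_private || prop_maf_lt_1pct > 1) {
    stop("need 0 <= prop_private <= prop_maf_lt_1pct <= 1")
  }
  if (is.null(chromosome_snp_counts)) {
    w <- rev(seq_len(n_chromosomes)) + n_chromosomes / 2
    chromosome_snp_counts <- floor(m_snps * w / sum(w))
    rem <- m_snps - sum(chromosome_snp_counts)
    if (rem > 0) {
      chromosome_snp_counts[seq_len(rem)] <-
        chromosome_snp_counts[seq_len(rem)] + 1L
    }
  }
  chromosome_snp_counts <- as.integer(chromosome_snp_counts)
  if (any(chromosome_snp_counts < 1L)) {
    stop("every chromosome must carry at least one SNP")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_cases = as.integer(n_cases),
                 chromosome_snp_counts = chromosome_snp_counts,
                 prop_private = prop_private,
                 prop_maf_lt_1pct = prop_maf_lt_1pct,
                 maf_rare = maf_rare,
                 n_replicates = as.integer(n_replicates),
                 causal = causal,
                 force_private_snps = as.integer(force_private_snps),
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

# Draw one SNP's minor-allele count given its class. Rare (non-private)
# counts are uniform on {2, ..., cmax}; common MAFs follow a Beta(0.8, 4)
# truncated to [maf_rare, 0.5], so the common spectrum is itself skewed
# towards its rare boundary, as empirical site-frequency spectra are.
draw_count <- function(class, n2, maf_rare) {
  cmax <- max(2L, as.integer(ceiling(maf_rare * n2)) - 1L)
  switch(class,
         private = 1L,
         rare = if (cmax <= 2L) 2L else sample(2:cmax, 1L),
         common = {
           lo <- stats::pbeta(maf_rare, 0.8, 4)
           hi <- stats::pbeta(0.5, 0.8, 4)
           maf <- stats::qbeta(stats::runif(1L, lo, hi), 0.8, 4)
           max(cmax + 1L, min(as.integer(n2 / 2), as.integer(round(maf * n2))))
         })
}

#' Generate a fixed genotype matrix with a skewed MAF spectrum
#'
#' Each SNP is assigned a frequency class (private / rare / common) with
#' probabilities `prop_private`, `prop_maf_lt_1pct - prop_private`, and
#' the remainder; a minor-allele count is drawn for the class; and that
#' many allele copies are placed on chromosomes drawn uniformly without
#' replacement among the 2N subject chromosomes, so the realised
#' `minor_allele_count` matches the draw exactly and private variants
#' have a single uniformly random carrier. Positions are increasing
#' integer steps along each chromosome. The matrix is deterministic
#' given `master_seed` and is meant to be generated once and held fixed
#' across all phenotype replicates.
#'
#' @param config a [sim_config()].
#' @return a [genotype_dataset()].
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$master_seed, 0L))
  n <- config$n_subjects
  n2 <- 2L * n
  m <- sum(config$chromosome_snp_counts)
  p_priv <- config$prop_private
  p_rare <- config$prop_maf_lt_1pct - config$prop_private
  classes <- sample(c("private", "rare", "common"), m, replace = TRUE,
                    prob = c(p_priv, p_rare, 1 - p_priv - p_rare))
  if (length(config$force_private_snps)) {
    if (any(config$force_private_snps < 1L | config$force_private_snps > m)) {
      stop("force_private_snps out of range")
    }
    classes[config$force_private_snps] <- "private"
  }
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    cnt <- draw_count(classes[j], n2, config$maf_rare)
    slots <- sample.int(n2, cnt)
    g[, j] <- tabulate((slots + 1L) %/% 2L, nbins = n)
  }
  chrom <- rep(seq_along(config$chromosome_snp_counts),
               config$chromosome_snp_counts)
  pos <- unlist(lapply(config$chromosome_snp_counts, function(mc) {
    cumsum(sample.int(5000L, mc, replace = TRUE))
  }), use.names = FALSE)
  within_idx <- unlist(lapply(config$chromosome_snp_counts, seq_len),
                       use.names = FALSE)
  snps <- data.frame(
    snp_id = sprintf("snp_%02d_%06d", chrom, within_idx),
    chromosome = as.character(chrom),
    position = pos,
    stringsAsFactors = FALSE)
  genotype_dataset(g, snps, subjects = sprintf("subj_%04d", seq_len(n)))
}

# Resolve config$causal to (column index, effect) against a dataset.
resolve_causal <- function(causal, dataset) {
  if (is.null(causal) || nrow(causal) == 0L) {
    return(data.frame(snp = integer(), effect = numeric()))
  }
  causal <- as.data.frame(causal)
  stopifnot(all(c("snp", "effect") %in% names(causal)))
  idx <- if (is.numeric(causal$snp)) as.integer(causal$snp) else
    match(as.character(causal$snp), dataset$snps$snp_id)
  if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(dataset$snps))) {
    stop("causal SNP(s) not found in the dataset")
  }
  data.frame(snp = idx, effect = as.numeric(causal$effect))
}

#' Generate phenotype replicates under a liability-threshold model
#'
#' For each replicate, liability = (dosage at causal SNPs) x effects +
#' independent standard normal noise per subject; the `n_cases` subjects
#' with the highest liability are assigned affected status 1. Genotypes
#' stay fixed; only the noise (and hence the case set) varies across
#' replicates. With no causal SNPs the cases are a uniformly random
#' subset of exactly `n_cases` subjects in every replicate -- the global
#' null. Deterministic given the config's `master_seed` and the
#' replicate number.
#'
#' @param dataset a [genotype_dataset()] from [generate_genotypes()].
#' @param config the same [sim_config()].
#' @param partition optional [partition_bins()] result used to annotate
#'   the truth set with each causal SNP's bin.
#' @return list with `phenotypes` (a [phenotype_replicates()]) and
#'   `truth` (data frame `snp_id`, `chromosome`, `position`, `effect`,
#'   `bin_index`; zero rows for a null model), of class `sim_phenotypes`.
#' @export
generate_phenotypes <- function(dataset, config, partition = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "sim_config"))
  n <- length(dataset$subjects)
  if (n != config$n_subjects) {
    stop("dataset and config disagree on the number of subjects")
  }
  causal <- resolve_causal(config$causal, dataset)
  base <- if (nrow(causal)) {
    as.vector(dataset$genotypes[, causal$snp, drop = FALSE] %*%
                causal$effect)
  } else {
    numeric(n)
  }
  statuses <- matrix(0L, config$n_replicates, n)
  for (r in seq_len(config$n_replicates)) {
    set.seed(derive_seed(config$master_seed, r))
    liab <- base + stats::rnorm(n)
    statuses[r, order(liab, decreasing = TRUE)[seq_len(config$n_cases)]] <- 1L
  }
  phen <- phenotype_replicates(
    statuses, subjects = dataset$subjects,
    replicate_ids = sprintf("rep%03d", seq_len(config$n_replicates)))
  truth <- data.frame(
    snp_id = dataset$snps$snp_id[causal$snp],
    chromosome = dataset$snps$chromosome[causal$snp],
    position = dataset$snps$position[causal$snp],
    effect = causal$effect,
    bin_index = if (is.null(partition))
      rep(NA_integer_, nrow(causal)) else
      partition$bin_of_snp[causal$snp],
    stringsAsFactors = FALSE)
  structure(list(phenotypes = phen, truth = truth),
            class = "sim_phenotypes")
}

#' Causal design for the private variants of one bin
#'
#' Builds the `causal` data frame for [sim_config()] that assigns a
#' common effect to (up to `n_snps` of) the private variants inside one
#' bin -- the planted-signal scenario used for power checks.
#'
#' @param dataset a [genotype_dataset()].
#' @param partition a [partition_bins()] result.
#' @param bin_index the bin to plant.
#' @param effect liability shift per minor-allele copy (e.g. 3.0 for a
#'   strong signal against unit-variance noise).
#' @param n_snps maximum number of private SNPs to use (default all in
#'   the bin).
#' @return data frame with columns `snp` (index) and `effect`.
#' @export
causal_private_in_bin <- function(dataset, partition, bin_index,
                                  effect = 3.0, n_snps = Inf) {
  priv <- which(dataset$snps$minor_allele_count == 1L &
                  partition$bin_of_snp == bin_index)
  if (length(priv) == 0L) stop("bin ", bin_index, " has no private variants")
  priv <- priv[seq_len(min(length(priv), n_snps))]
  data.frame(snp = priv, effect = effect)
}

#' Write a truth set as TSV
#'
#' @param truth the `truth` element of [generate_phenotypes()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
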