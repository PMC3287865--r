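# Permutation test of the affected ratio and the per-replicate scan.

# Deterministic per-replicate seed derived from a master seed. `stream`
# separates pipeline stages (0 = data generation, 1 = permutation scan)
# so that a scan never seeds its permutations with the value that
# generated the replicate's phenotype noise. Kept below 2^31 - 1 so the
# result is always a valid integer seed.
derive_seed <- function(master_seed, i, stream = 0L) {
  as.integer((as.double(master_seed) %% 2147483647 + 1000003 * i +
                777767777 * stream) %% 2147483647)
}

# Core permutation engine shared by permutation_pvalue() and
# scan_replicate(). One stream of permuted status vectors is drawn and
# every bin is scored on each of them, so cross-bin correlation under the
# null is preserved. Exceedance is counted on the integer case-allele
# counts: with the per-bin denominator fixed, permuted p_i >(=) observed
# p_i iff permuted k_i >(=) observed k_i, which avoids floating-point
# tie ambiguity.
perm_scan_core <- function(ct, bin, n_bins, status, n_perm,
                           ties = "exceed") {
  n <- length(status)
  denom <- bin_sums(ct$copies, bin, n_bins)
  k_obs <- bin_sums(ct$copies * status[ct$subject], bin, n_bins)
  perms <- vapply(seq_len(n_perm),
                  function(j) status[sample.int(n)],
                  integer(n))                       # N x n_perm
  s <- perms[ct$subject, , drop = FALSE] * ct$copies  # carriers x n_perm
  k_perm <- matrix(0, n_bins, n_perm)
  if (nrow(s)) {
    agg <- rowsum(s, group = bin)
    k_perm[as.integer(rownames(agg)), ] <- agg
  }
  n_exceed <- if (ties == "strict") {
    rowSums(k_perm > k_obs)   # ties are non-exceedances
  } else {
    rowSums(k_perm >= k_obs)  # ties exceed: the valid permutation test
  }
  list(denom = denom, k_obs = k_obs, n_exceed = n_exceed)
}

perm_result_frame <- function(core, bins, n_perm, alpha, plus_one) {
  p <- if (plus_one) (core$n_exceed + 1) / (n_perm + 1) else
    core$n_exceed / n_perm
  testable <- core$denom > 0
  p[!testable] <- NA_real_
  data.frame(bin_index = bins$bin_index,
             chromosome = bins$chromosome,
             n_private = as.integer(core$denom),
             observed_stat = ifelse(testable, core$k_obs / core$denom,
                                    NA_real_),
             n_perm = n_perm,
             n_exceed = ifelse(testable, core$n_exceed, NA_integer_),
             p_value = p,
             significant = testable & !is.na(p) & p < alpha,
             testable = testable)
}

#' Permutation p-value of one bin's affected ratio
#'
#' Draws `n_perm` uniformly random permutations of the case/control
#' labels, recomputes the affected ratio under each, and reports the
#' fraction of permutations whose statistic exceeds the observed one.
#' The test is one-sided: enrichment of private-variant carriers among
#' cases.
#'
#' Tie handling matters because the statistic is discrete (k_i takes at
#' most m_i + 1 values). With the default `ties = "exceed"`, permuted
#' statistics equal to the observed one count as exceedances, giving the
#' standard valid permutation p-value, super-uniform under the null:
#' P(p_value < alpha) <= alpha for every alpha. `ties = "strict"`
#' counts only strict exceedances; that reading of "observed < permuted"
#' shrinks every p-value by the tie mass and is anti-conservative for
#' sparse bins (a bin whose single private carrier is a case gets
#' p = 0 in every dataset), so it is provided for comparison, not as the
#' default. The two agree as the number of private variants per bin
#' grows. `plus_one = TRUE` switches to the (n_exceed + 1) /
#' (n_perm + 1) estimator, the usual guard against reporting an exact
#' zero.
#'
#' @inheritParams bin_statistics
#' @param bin_index bin to test (must contain at least one private
#'   variant).
#' @param n_perm number of label permutations (default 1000).
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param seed integer seed for the permutation stream (`NULL` leaves
#'   the RNG state alone).
#' @param plus_one use the +1-corrected p-value estimator (default
#'   `FALSE`, matching the plain exceedance fraction).
#' @param ties `"exceed"` (ties count as exceedances; valid test,
#'   default) or `"strict"` (literal strict inequality).
#' @return one-row data frame: `bin_index`, `chromosome`, `n_private`,
#'   `observed_stat`, `n_perm`, `n_exceed`, `p_value`, `significant`,
#'   `testable`.
#' @export
permutation_pvalue <- function(dataset, partition, status, bin_index,
                               n_perm = 1000, alpha = 0.05, seed = NULL,
                               plus_one = FALSE, ties = c("exceed", "strict"),
                               max_count = 1L) {
  ties <- match.arg(ties)
  stopifnot(n_perm >= 1)
  status <- check_status(status, dataset)
  ct <- carrier_table(dataset, max_count)
  keep <- partition$bin_of_snp[ct$snp] == bin_index
  ct <- ct[keep, , drop = FALSE]
  if (nrow(ct) == 0L) stop("bin ", bin_index,
                           " has no private variants; not testable")
  if (!is.null(seed)) set.seed(seed)
  core <- perm_scan_core(ct, rep.int(1L, nrow(ct)), 1L, status, n_perm,
                         ties = ties)
  out <- perm_result_frame(core,
                           partition$bins[partition$bins$bin_index ==
                                            bin_index, , drop = FALSE],
                           n_perm, alpha, plus_one)
  rownames(out) <- NULL
  out
}

#' Scan every bin of one phenotype replicate
#'
#' Tests each testable bin of the partition against the label-permutation
#' null for a single affected-status vector. All bins share one stream of
#' permuted status vectors, preserving the cross-bin correlation
#' structure of the null; per-bin marginal p-values are unaffected by the
#' sharing. Bins without private variants are reported as untested
#' (`testable = FALSE`, `p_value = NA`) rather than assigned a p-value.
#'
#' @inheritParams permutation_pvalue
#' @return data frame with one row per bin, as in
#'   [permutation_pvalue()].
#' @export
scan_replicate <- function(dataset, partition, status, n_perm = 1000,
                           alpha = 0.05, seed = NULL, plus_one = FALSE,
                           ties = c("exceed", "strict"), max_count = 1L) {
  ties <- match.arg(ties)
  stopifnot(inherits(partition, "bin_partition"), n_perm >= 1)
  status <- check_status(status, dataset)
  ct <- carrier_table(dataset, max_count)
  bin <- partition$bin_of_snp[ct$snp]
  if (!is.null(seed)) set.seed(seed)
  core <- perm_scan_core(ct, bin, nrow(partition$bins), status, n_perm,
                         ties = ties)
  perm_result_frame(core, partition$bins, n_perm, alpha, plus_one)
}

#' Scan all phenotype replicates
#'
#' Runs [scan_replicate()] for every replicate, with per-replicate
#' permutation streams derived deterministically from `seed` and the
#' replicate number, and collects the results for aggregation with
#' [return_frequency()].
#'
#' @inheritParams scan_replicate
#' @param phenotypes a [phenotype_replicates()] aligned to
#'   `dataset$subjects`.
#' @param seed master seed; replicate r uses a seed derived from
#'   `(seed, r)`, so runs are reproducible end to end.
#' @return an object of class `bin_scan`: list with `replicates` (named
#'   list of per-replicate result frames), `partition`, and `params`.
#' @export
bin_scan <- function(dataset, phenotypes, partition, n_perm = 1000,
                     alpha = 0.05, seed = 1L, plus_one = FALSE,
                     ties = c("exceed", "strict"), max_count = 1L) {
  ties <- match.arg(ties)
  stopifnot(inherits(phenotypes, "phenotype_replicates"))
  if (!identical(phenotypes$subjects, dataset$subjects)) {
    stop("phenotype subjects do not match genotype subjects")
  }
  res <- lapply(seq_len(nrow(phenotypes$statuses)), function(r) {
    scan_replicate(dataset, partition, phenotypes$statuses[r, ],
                   n_perm = n_perm, alpha = alpha,
                   seed = derive_seed(seed, r, stream = 1L),
                   plus_one = plus_one, ties = ties,
                   max_count = max_count)
  })
  names(res) <- phenotypes$replicate_ids
  structure(list(replicates = res, partition = partition,
                 params = list(n_perm = n_perm, alpha = alpha,
                               seed = seed, plus_one = plus_one,
                               ties = ties, max_count = max_count)),
            class = "bin_scan")
}

#' @export
print.bin_scan <- function(x, ...) {
  nsig <- vapply(x$replicates, function(r) sum(r$significant), integer(1))
  cat(sprintf("bin_scan: %d replicate(s) x %d bins (n_perm = %d, alpha = %g)\n",
              length(x$replicates), nrow(x$partition$bins),
              x$params$n_perm, x$params$alpha))
  cat(sprintf("  significant bins per replicate: mean %.1f (range %d-%d)\n",
              mean(nsig), min(nsig), max(nsig)))
  invisible(x)
}

#' Flatten a scan into one data frame
#'
#' @param x a [bin_scan()] result.
#' @param ... unused.
#' @return data frame of all per-replicate rows with a leading
#'   `replicate_id` column.
#' @export
as.data.frame.bin_scan <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$replicates), function(id) {
    cbind(data.frame(replicate_id = id, stringsAsFactors = FALSE),
          x$replicates[[id]])
  }))
  rownames(out) <- NULL
  out
}

#' Export per-replicate scan results as TSV
#'
#' @param scan a [bin_scan()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(scan, path) {
  df <- as.data.frame(scan)
  df <- df[, c("replicate_id", "bin_index", "observed_stat", "n_perm",
               "p_value", "significant", "testable")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
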