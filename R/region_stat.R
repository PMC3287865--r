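# The per-bin affected ratio over private variants.

# Long-format table of minor-allele carriers for SNPs with
# 1 <= minor_allele_count <= max_count: one row per (SNP, carrier) with
# the number of copies carried. For the default max_count = 1 (private
# variants) each included SNP contributes exactly one row with one copy.
carrier_table <- function(dataset, max_count = 1L) {
  counts <- dataset$snps$minor_allele_count
  incl <- which(counts >= 1L & counts <= max_count)
  if (length(incl) == 0L) {
    return(data.frame(snp = integer(), subject = integer(),
                      copies = integer()))
  }
  g <- dataset$genotypes[, incl, drop = FALSE]
  hit <- which(g > 0L, arr.ind = TRUE)
  data.frame(snp = incl[hit[, 2L]],
             subject = as.integer(hit[, 1L]),
             copies = as.integer(g[hit]))
}

# Sum x over bins, returning a dense length-n_bins vector.
bin_sums <- function(x, bin, n_bins) {
  out <- numeric(n_bins)
  if (length(x)) {
    s <- rowsum(x, group = bin)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Affected ratio per bin
#'
#' For each bin i, counts the private variants it contains (`n_private`,
#' m_i), how many of those singleton minor alleles are carried by a case
#' (`n_private_case`, k_i), and the affected ratio `p = k_i / m_i`. Bins
#' with no private variants are flagged non-testable and get `p = NA`.
#' Under the null of no genotype-phenotype association the carriers are
#' exchangeable, so E\[p\] equals the case fraction.
#'
#' With `max_count > 1` the statistic generalises to non-private rare
#' SNPs: every minor-allele copy at a SNP with total count at most
#' `max_count` contributes, weighted by its carrier's status, and
#' `n_private` / `n_private_case` then count allele copies rather than
#' SNPs. The default (`max_count = 1`) restricts to private variants.
#'
#' @param dataset a [genotype_dataset()].
#' @param partition a [partition_bins()] result for that dataset.
#' @param status integer vector of affected status (0/1), aligned to
#'   `dataset$subjects`.
#' @param max_count largest minor-allele count included (1 = private
#'   only).
#' @return data frame with one row per bin: `bin_index`, `chromosome`,
#'   `n_snps`, `n_private`, `n_private_case`, `p`, `testable`.
#' @export
bin_statistics <- function(dataset, partition, status, max_count = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(partition, "bin_partition"))
  status <- check_status(status, dataset)
  ct <- carrier_table(dataset, max_count)
  nb <- nrow(partition$bins)
  bin <- partition$bin_of_snp[ct$snp]
  denom <- bin_sums(ct$copies, bin, nb)
  k <- bin_sums(ct$copies * status[ct$subject], bin, nb)
  data.frame(bin_index = partition$bins$bin_index,
             chromosome = partition$bins$chromosome,
             n_snps = partition$bins$n_snps,
             n_private = as.integer(denom),
             n_private_case = as.integer(k),
             p = ifelse(denom > 0, k / denom, NA_real_),
             testable = denom > 0)
}

#' Affected ratio of a single bin
#'
#' Convenience wrapper around [bin_statistics()] returning the one-row
#' result for `bin_index`.
#'
#' @inheritParams bin_statistics
#' @param bin_index index of the bin of interest.
#' @return one-row data frame as in [bin_statistics()].
#' @export
affected_ratio <- function(dataset, partition, status, bin_index,
                           max_count = 1L) {
  stats <- bin_statistics(dataset, partition, status, max_count)
  row <- stats[stats$bin_index == bin_index, , drop = FALSE]
  if (nrow(row) == 0L) stop("no such bin: ", bin_index)
  row
}

#' Export per-bin statistics as TSV
#'
#' @param stats output of [bin_statistics()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bin_statistics <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_status <- function(status, dataset) {
  status <- as.integer(status)
  if (length(status) != length(dataset$subjects)) {
    stop("status length does not match number of subjects")
  }
  if (anyNA(status) || !all(status %in% 0:1)) {
    stop("status values must be 0 or 1")
  }
  status
}
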