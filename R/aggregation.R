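# Return-frequency aggregation across phenotype replicates, region
# ranking, and analytic null-calibration helpers.

#' Return frequency of each bin across replicates
#'
#' The return frequency of a bin is the number of phenotype replicates in
#' which its permutation p-value fell below the significance level -- the
#' aggregation statistic that ranks candidate regions when many
#' replicates share one fixed genotype matrix. Under a global null each
#' testable bin returns approximately `R * alpha` times in expectation
#' (slightly fewer, since the strict-inequality p-value is conservative).
#'
#' @param scan a [bin_scan()] result, or a list of per-replicate result
#'   frames from [scan_replicate()] sharing one partition.
#' @param alpha significance level recorded in the table (taken from the
#'   scan when available).
#' @return an object of class `return_frequency_table`: data frame with
#'   `bin_index`, `chromosome`, `return_frequency`, `n_tested` (number of
#'   replicates in which the bin was testable), and `ever_testable`, plus
#'   attributes `n_replicates` and `alpha`.
#' @export
return_frequency <- function(scan, alpha = NULL) {
  if (inherits(scan, "bin_scan")) {
    reps <- scan$replicates
    if (is.null(alpha)) alpha <- scan$params$alpha
  } else {
    reps <- scan
  }
  if (length(reps) == 0L) stop("no replicates to aggregate")
  ref <- reps[[1L]]$bin_index
  for (r in reps) {
    if (!identical(r$bin_index, ref)) {
      stop("replicates do not share one bin partition")
    }
  }
  sig <- vapply(reps, function(r) as.integer(r$significant),
                integer(length(ref)))
  tst <- vapply(reps, function(r) as.integer(r$testable),
                integer(length(ref)))
  if (is.null(dim(sig))) {  # single-bin partition
    sig <- matrix(sig, nrow = 1L)
    tst <- matrix(tst, nrow = 1L)
  }
  out <- data.frame(bin_index = ref,
                    chromosome = reps[[1L]]$chromosome,
                    return_frequency = as.integer(rowSums(sig)),
                    n_tested = as.integer(rowSums(tst)),
                    ever_testable = rowSums(tst) > 0)
  structure(out, class = c("return_frequency_table", "data.frame"),
            n_replicates = length(reps), alpha = alpha)
}

#' Top-k regions by return frequency
#'
#' Orders bins by decreasing return frequency, breaking ties by
#' ascending bin index so the ranking is deterministic; a note is issued
#' when a tie spans the k-th boundary. Requesting more regions than
#' exist returns all of them with a note.
#'
#' @param table a [return_frequency()] table.
#' @param k number of top regions to report (default 10).
#' @return data frame `rank`, `bin_index`, `chromosome`,
#'   `return_frequency`.
#' @export
rank_regions <- function(table, k = 10) {
  stopifnot(k >= 1)
  ord <- order(-table$return_frequency, table$bin_index)
  if (k > nrow(table)) {
    message("k exceeds the number of bins; returning all ", nrow(table))
    k <- nrow(table)
  } else if (k < nrow(table)) {
    f <- table$return_frequency[ord]
    if (f[k] == f[k + 1L]) {
      message("return-frequency tie spans the top-", k,
              " boundary; broken by ascending bin index")
    }
  }
  sel <- ord[seq_len(k)]
  data.frame(rank = seq_len(k),
             bin_index = table$bin_index[sel],
             chromosome = table$chromosome[sel],
             return_frequency = table$return_frequency[sel])
}

#' Expected null return frequency
#'
#' Under the null, a testable bin is significant in each of
#' `n_replicates` independent replicates with probability at most
#' `alpha`, so its expected return frequency is `n_replicates * alpha`
#' (e.g. 200 x 0.05 = 10).
#'
#' @param n_replicates number of phenotype replicates R.
#' @param alpha per-replicate significance level.
#' @return the expected count `n_replicates * alpha`.
#' @export
expected_null_return <- function(n_replicates, alpha) {
  n_replicates * alpha
}

#' Poisson calibration of an observed return frequency
#'
#' Approximates the null distribution of a bin's return frequency by
#' Poisson(lambda) with `lambda = n_replicates * alpha` and evaluates
#' either the point mass lambda^k e^(-lambda) / k! at `k = threshold`
#' (the default, the single-term estimate of how unlikely a large return
#' frequency is) or the upper tail P(X >= threshold). For lambda = 10
#' and threshold = 50 the point mass is about 1.5e-19.
#'
#' @param lambda expected null return frequency (> 0).
#' @param threshold observed return frequency (>= 0).
#' @param tail if `TRUE` return P(X >= threshold) instead of the point
#'   mass.
#' @return a probability.
#' @export
poisson_return_tail <- function(lambda, threshold, tail = FALSE) {
  stopifnot(lambda > 0, threshold >= 0)
  if (tail) {
    stats::ppois(threshold - 1, lambda, lower.tail = FALSE)
  } else {
    stats::dpois(threshold, lambda)
  }
}

#' Expected causal variants among the top-k regions under uniformity
#'
#' If `n_causal` causal variants were spread uniformly over `n_regions`
#' equally sized regions, the `k` top-ranked regions would be expected to
#' contain `n_causal * k / n_regions` of them -- the baseline against
#' which an observed enrichment of causal variants in the top regions is
#' judged (e.g. 90 x 10/253 = 3.56).
#'
#' @param n_causal number of causal variants.
#' @param k number of top regions reported.
#' @param n_regions total number of regions.
#' @return the expected count.
#' @export
expected_causal_in_topk <- function(n_causal, k, n_regions) {
  stopifnot(n_regions >= k, k >= 0, n_causal >= 0)
  n_causal * k / n_regions
}

#' @export
print.return_frequency_table <- function(x, ...) {
  cat(sprintf("return_frequency_table: %d bins over %d replicate(s) (alpha = %g)\n",
              nrow(x), attr(x, "n_replicates"),
              if (is.null(attr(x, "alpha"))) NA else attr(x, "alpha")))
  cat(sprintf("  mean return frequency (testable bins): %.2f\n",
              mean(x$return_frequency[x$ever_testable])))
  NextMethod()
}

#' Export a return-frequency table as TSV
#'
#' @param table a [return_frequency()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_return_frequency <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot return frequency by region
#'
#' A simple needle plot of return frequency against bin index, with the
#' expected null level `R * alpha` marked, mirroring the usual summary
#' figure of a multi-replicate scan.
#'
#' @param table a [return_frequency()] table.
#' @param file optional path; when given, a PNG is written there instead
#'   of drawing on the current device.
#' @param ... passed to [graphics::plot()].
#' @return `table`, invisibly.
#' @export
plot_return_frequency <- function(table, file = NULL, ...) {
  draw <- function() {
    graphics::plot(table$bin_index, table$return_frequency, type = "h",
                   xlab = "region (bin index)",
                   ylab = "return frequency", ...)
    alpha <- attr(table, "alpha")
    if (!is.null(alpha)) {
      graphics::abline(h = attr(table, "n_replicates") * alpha,
                       lty = 2, col = "grey40")
    }
  }
  if (is.null(file)) {
    draw()
  } else {
    grDevices::png(file, width = 900, height = 400)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(table)
}
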