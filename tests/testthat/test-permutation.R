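# Permutation test: strict-inequality p-values against the label null.

test_that("an observed ratio of 1 is never strictly exceeded", {
  ds <- private_dataset(list(2L), n_subjects = 10)
  part <- partition_bins(ds, 1, 0)
  status <- make_status(c(2L, 5L, 6L), 10)
  res <- permutation_pvalue(ds, part, status, bin_index = 1,
                            n_perm = 500, seed = 1, ties = "strict")
  expect_equal(res$observed_stat, 1)
  expect_identical(res$p_value, 0)
  expect_true(res$significant)
  # the valid (tie-inclusive) p-value instead estimates the chance a
  # permutation puts a case on the carrier -- here 3/10, not significant
  val <- permutation_pvalue(ds, part, status, bin_index = 1,
                            n_perm = 2000, seed = 1)
  expect_lt(abs(val$p_value - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("a single control-carried singleton has strict p near the case fraction", {
  # permuted statistic strictly exceeds 0 exactly when a case lands on
  # the carrier
  n <- 697L; ncase <- 209L
  ds <- private_dataset(list(1L), n_subjects = n)
  part <- partition_bins(ds, 1, 0)
  status <- make_status(seq(2L, length.out = ncase), n)  # carrier is control
  res <- permutation_pvalue(ds, part, status, 1, n_perm = 5000, seed = 2,
                            ties = "strict")
  exact <- ncase / n
  expect_lt(abs(res$p_value - exact),
            3 * sqrt(exact * (1 - exact) / 5000))
})

test_that("Monte-Carlo p-values match exhaustive label enumeration at tiny N", {
  # several layouts with 0 < p_exact < 1, N <= 8
  layouts <- list(
    list(n = 6, cases = c(1L, 2L, 3L), carriers = c(1L, 5L)),
    list(n = 6, cases = c(2L, 4L, 6L), carriers = c(1L, 2L, 3L)),
    list(n = 8, cases = c(1L, 2L, 8L), carriers = c(2L, 3L, 5L, 7L)))
  for (lay in layouts) {
    ds <- private_dataset(as.list(lay$carriers), n_subjects = lay$n)
    part <- partition_bins(ds, length(lay$carriers), 0)
    status <- make_status(lay$cases, lay$n)
    for (ties in c("exceed", "strict")) {
      exact <- enum_exceed_prob(lay$carriers, lay$n, status, ties)
      expect_gt(exact, 0); expect_lt(exact, 1)
      res <- permutation_pvalue(ds, part, status, 1, n_perm = 20000,
                                seed = 7, ties = ties)
      expect_lt(abs(res$p_value - exact),
                3 * sqrt(exact * (1 - exact) / 20000))
    }
  }
})

test_that("identical seeds reproduce p-values; the +1 correction shifts them", {
  set.seed(30)
  ds <- private_dataset(as.list(sample.int(30, 12)), n_subjects = 30)
  part <- partition_bins(ds, 4, 0)
  status <- make_status(sample.int(30, 9), 30)
  a <- scan_replicate(ds, part, status, n_perm = 300, seed = 99)
  b <- scan_replicate(ds, part, status, n_perm = 300, seed = 99)
  expect_identical(a, b)
  c1 <- scan_replicate(ds, part, status, n_perm = 300, seed = 99,
                       plus_one = TRUE)
  expect_equal(c1$p_value, (a$n_exceed + 1) / 301)
})

test_that("single-bin and whole-scan p-values agree on a shared stream", {
  # the permutation stream depends only on the seed, so testing one bin
  # alone reproduces its p-value from the joint scan
  set.seed(31)
  ds <- private_dataset(as.list(sample.int(25, 10)), n_subjects = 25)
  part <- partition_bins(ds, 5, 0)
  status <- make_status(sample.int(25, 8), 25)
  joint <- scan_replicate(ds, part, status, n_perm = 400, seed = 12)
  solo <- permutation_pvalue(ds, part, status, bin_index = 2,
                             n_perm = 400, seed = 12)
  expect_identical(solo$p_value, joint$p_value[2])
})

test_that("non-testable bins are reported untested, not significant", {
  ds <- manual_dataset(list(c(1L, 0L, 1L, 0L), c(1L, 0L, 0L, 0L)))
  part <- partition_bins(ds, 1, 0)  # bin 1 has no private SNP
  res <- scan_replicate(ds, part, make_status(1L, 4), n_perm = 100,
                        seed = 3)
  expect_false(res$testable[1])
  expect_true(is.na(res$p_value[1]))
  expect_false(res$significant[1])
  expect_error(permutation_pvalue(ds, part, make_status(1L, 4), 1),
               "not testable")
})

test_that("alpha = 0 marks nothing significant", {
  ds <- private_dataset(list(1L, 2L), n_subjects = 6)
  part <- partition_bins(ds, 2, 0)
  res <- scan_replicate(ds, part, make_status(1:2, 6), n_perm = 200,
                        alpha = 0, seed = 4)
  expect_false(any(res$significant))
})

test_that("the permutation null is never anti-conservative", {
  # label-independent phenotypes: empirical P(p < alpha) <= alpha at
  # every level, within binomial sampling error
  set.seed(55)
  n <- 40L; ncase <- 12L
  ds <- private_dataset(as.list(sample.int(n, 36, replace = TRUE)),
                        n_subjects = n)
  part <- partition_bins(ds, 6, 0)  # 6 bins, ~6 privates each
  n_rep <- 300L
  pvals <- unlist(lapply(seq_len(n_rep), function(r) {
    status <- make_status(sample.int(n, ncase), n)
    scan_replicate(ds, part, status, n_perm = 200,
                   seed = 1000L + r)$p_value
  }))
  pvals <- pvals[!is.na(pvals)]
  for (alpha in c(0.01, 0.05, 0.1)) {
    rate <- mean(pvals < alpha)
    expect_lt(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / length(pvals)))
  }
})

test_that("a bin whose private carriers are all cases returns strong significance", {
  n <- 100L; ncase <- 30L
  set.seed(21)
  carriers <- 1:20
  ds <- private_dataset(as.list(carriers), n_subjects = n)
  part <- partition_bins(ds, 20, 0)
  status <- make_status(c(carriers, 91:100), n)  # 30 cases incl. all carriers
  res <- scan_replicate(ds, part, status, n_perm = 1000, seed = 6)
  expect_lt(res$p_value, 0.001)
})
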