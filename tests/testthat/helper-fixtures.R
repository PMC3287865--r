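# Fixture builders shared across the test files. All data are generated
# in code; nothing is read from disk except files the tests write first.

# A small hand-specified dataset: `dosages` is a list of per-SNP dosage
# vectors (one per SNP, length n_subjects), already minor-coded.
manual_dataset <- function(dosages, chromosome = NULL, position = NULL,
                           subjects = NULL) {
  m <- length(dosages)
  n <- length(dosages[[1L]])
  g <- do.call(cbind, dosages)
  if (is.null(chromosome)) chromosome <- rep("1", m)
  if (is.null(position)) position <- seq_len(m) * 100L
  if (is.null(subjects)) subjects <- paste0("s", seq_len(n))
  genotype_dataset(g,
                   data.frame(snp_id = paste0("v", seq_len(m)),
                              chromosome = chromosome,
                              position = position,
                              stringsAsFactors = FALSE),
                   subjects = subjects)
}

# Dataset where every SNP is private, with a chosen carrier per SNP;
# convenient for constructing bins with known affected ratios.
private_dataset <- function(carriers, n_subjects,
                            chromosome = NULL, position = NULL) {
  manual_dataset(lapply(carriers, function(cr) {
    v <- integer(n_subjects)
    v[cr] <- 1L
    v
  }), chromosome = chromosome, position = position)
}

# Lightweight SNP table (no genotypes) for exercising the partitioner on
# arbitrary chromosome layouts.
snp_table <- function(chrom_counts) {
  chrom <- rep(seq_along(chrom_counts), chrom_counts)
  data.frame(snp_id = sprintf("v%05d", seq_along(chrom)),
             chromosome = as.character(chrom),
             position = unlist(lapply(chrom_counts, function(m)
               seq_len(m) * 10L), use.names = FALSE),
             stringsAsFactors = FALSE)
}

# Exact permutation-null oracle: enumerate every placement of the case
# labels (all subsets of size n_cases are equally likely under label
# permutation) and return P(permuted case-carrier count exceeds the
# observed one), under either tie convention.
enum_exceed_prob <- function(carriers, n_subjects, status,
                             ties = "exceed") {
  k_obs <- sum(status[carriers])
  sets <- utils::combn(n_subjects, sum(status))
  k_perm <- apply(sets, 2L, function(cases) sum(carriers %in% cases))
  if (ties == "strict") mean(k_perm > k_obs) else mean(k_perm >= k_obs)
}

# Status vector with given case indices.
make_status <- function(cases, n_subjects) {
  s <- integer(n_subjects)
  s[cases] <- 1L
  s
}
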