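# Genotype and phenotype input: construction, validation, file dialects,
# and minor-allele-frequency classification.

#' Rank chromosome labels in natural genome order
#'
#' Numeric labels sort numerically (1, 2, ..., 10, ..., 22), followed by
#' X, Y, MT/M, then any remaining labels alphabetically. A leading "chr"
#' prefix is ignored for ranking but preserved in the data.
#'
#' @param chromosome character vector of chromosome labels.
#' @return numeric rank vector, usable with [order()].
#' @keywords internal
chrom_rank <- function(chromosome) {
  lab <- sub("^chr", "", as.character(chromosome), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(lab))
  special <- match(toupper(lab), c("X", "Y", "MT", "M"))
  big <- 1e6
  rank <- ifelse(!is.na(num), num, big + special)
  other <- is.na(rank)
  if (any(other)) {
    lev <- sort(unique(lab[other]))
    rank[other] <- 2 * big + match(lab[other], lev)
  }
  rank
}

#' Construct a genotype dataset
#'
#' Bundles a subjects-by-SNPs minor-allele dosage matrix with per-SNP
#' metadata and validates the invariants the downstream scan relies on:
#' dosages are complete and lie in \{0, 1, 2\}, SNPs are sorted by
#' chromosome (natural order) then position (ties broken by `snp_id`), and
#' each SNP's `minor_allele_count` equals its dosage column sum.
#'
#' Dosages are assumed to already count the minor allele; use
#' [read_genotypes()] for files, which recodes to the in-sample minor
#' allele automatically.
#'
#' @param genotypes integer matrix, subjects in rows, SNPs in columns,
#'   values in \{0, 1, 2\} (copies of the minor allele).
#' @param snps data frame with columns `snp_id`, `chromosome`, `position`
#'   (1-based base pairs). A `minor_allele_count` column, if present, is
#'   checked against the column sums; otherwise it is computed.
#' @param subjects character vector of subject ids (defaults to the
#'   matrix row names).
#' @return an object of class `genotype_dataset`: a list with elements
#'   `genotypes` (N x M integer matrix), `snps` (metadata data frame,
#'   including `minor_allele_count`), and `subjects`.
#' @export
genotype_dataset <- function(genotypes, snps, subjects = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(subjects)) subjects <- paste0("s", seq_len(nrow(genotypes)))
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("duplicated subject ids")
  if (length(subjects) != nrow(genotypes)) {
    stop("subjects length does not match genotype rows")
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chromosome", "position")
  if (!all(need %in% names(snps))) {
    stop("snps must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(snps) != ncol(genotypes)) {
    stop("snps rows do not match genotype columns")
  }
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position <- as.integer(snps$position)
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp ids")
  if (any(snps$position < 1L)) stop("positions must be >= 1")

  if (anyNA(genotypes)) {
    idx <- which(is.na(genotypes), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing genotype at SNP '%s', subject '%s'",
                 snps$snp_id[idx[2L]], subjects[idx[1L]]))
  }
  storage.mode(genotypes) <- "integer"
  if (!all(genotypes %in% 0:2)) {
    stop("genotype dosages must be integers in {0, 1, 2}")
  }

  ord <- order(chrom_rank(snps$chromosome), snps$position, snps$snp_id)
  if (!identical(ord, seq_len(nrow(snps)))) {
    message("SNPs not in genome order; sorting by chromosome, position, id")
    snps <- snps[ord, , drop = FALSE]
    genotypes <- genotypes[, ord, drop = FALSE]
  }
  rownames(snps) <- NULL

  counts <- as.integer(colSums(genotypes))
  n2 <- 2L * length(subjects)
  if (any(counts > n2)) stop("minor_allele_count exceeds 2N")
  if (!is.null(snps$minor_allele_count)) {
    if (!identical(as.integer(snps$minor_allele_count), counts)) {
      stop("minor_allele_count does not match genotype column sums")
    }
  }
  snps$minor_allele_count <- counts

  dimnames(genotypes) <- list(subjects, snps$snp_id)
  structure(list(genotypes = genotypes, snps = snps, subjects = subjects),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cls <- classify_variants(x)
  cat(sprintf("genotype_dataset: %d subjects x %d SNPs on %d chromosome(s)\n",
              length(x$subjects), nrow(x$snps),
              length(unique(x$snps$chromosome))))
  cat("  variant classes:",
      paste(sprintf("%s=%d", levels(cls), tabulate(cls, length(levels(cls)))),
            collapse = ", "), "\n")
  invisible(x)
}

# Flip dosage columns whose allele count exceeds N (frequency > 0.5) so
# that dosage counts the in-sample minor allele; exact 50% ties keep the
# file's coding.
recode_minor <- function(genotypes) {
  n <- nrow(genotypes)
  flip <- colSums(genotypes) > n
  if (any(flip)) {
    genotypes[, flip] <- 2L - genotypes[, flip, drop = FALSE]
    message(sprintf("recoded %d SNP(s) to minor-allele dosage", sum(flip)))
  }
  genotypes
}

#' Read a genotype matrix from VCF or tabular file
#'
#' Supports VCF (v4.x; only CHROM, POS, ID and the GT field are used) and
#' a genotype TSV dialect with header
#' `snp_id chromosome position s1 ... sN` and one dosage row per SNP.
#' Alleles are recoded so that dosage counts the in-sample minor allele
#' (the less frequent allele across all subjects). Records with missing
#' genotype calls are rejected with an error naming the SNP and subject;
#' multi-allelic VCF records are rejected. Unsorted input is sorted with
#' a message.
#'
#' @param path path to the input file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension;
#'   `.vcf` is VCF, anything else the TSV dialect).
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         tsv = read_genotypes_tsv(path))
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("snp_id", "chromosome", "position")
  if (!all(need %in% names(df)[1:3])) {
    stop("genotype TSV must start with columns: snp_id chromosome position")
  }
  subjects <- names(df)[-(1:3)]
  if (length(subjects) == 0L) stop("genotype TSV has no subject columns")
  # vapply over SNP rows yields a subjects x snps matrix directly
  g <- vapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.integer(df[i, -(1:3)]))
    if (anyNA(v)) {
      stop(sprintf("missing genotype at SNP '%s', subject '%s'",
                   df$snp_id[i], subjects[which(is.na(v))[1L]]))
    }
    v
  }, integer(length(subjects)))
  if (is.null(dim(g))) g <- matrix(g, nrow = length(subjects))
  g <- recode_minor(g)
  genotype_dataset(g,
                   data.frame(snp_id = df$snp_id,
                              chromosome = df$chromosome,
                              position = as.integer(df$position),
                              stringsAsFactors = FALSE),
                   subjects = subjects)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("multi-allelic VCF record(s) not supported: ",
         paste(fix[multi, "ID"][seq_len(min(5, sum(multi)))], collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF has no GT genotype fields")
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  dosage <- function(calls, snp_id) {
    alleles <- strsplit(calls, "[/|]")
    d <- vapply(alleles, function(a) {
      if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
    if (anyNA(d) || anyNA(calls)) {
      bad <- which(is.na(d) | is.na(calls))[1L]
      stop(sprintf("missing genotype at SNP '%s', subject '%s'",
                   snp_id, colnames(gt)[bad]))
    }
    d
  }
  g <- vapply(seq_len(nrow(gt)),
              function(i) dosage(gt[i, ], ids[i]),
              integer(ncol(gt)))
  if (is.null(dim(g))) g <- matrix(g, nrow = ncol(gt))
  g <- recode_minor(g)
  genotype_dataset(g,
                   data.frame(snp_id = ids,
                              chromosome = fix[, "CHROM"],
                              position = as.integer(fix[, "POS"]),
                              stringsAsFactors = FALSE),
                   subjects = colnames(gt))
}

#' Write a genotype dataset to the tabular dialect
#'
#' Writes the TSV dialect accepted by [read_genotypes()]: header
#' `snp_id chromosome position s1 ... sN`, one row per SNP, tab-separated
#' minor-allele dosages. Round-trips losslessly.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  df <- cbind(dataset$snps[, c("snp_id", "chromosome", "position")],
              as.data.frame(t(dataset$genotypes)))
  names(df) <- c("snp_id", "chromosome", "position", dataset$subjects)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct phenotype replicates
#'
#' @param statuses integer matrix of affected status in \{0, 1\},
#'   replicates in rows, subjects in columns.
#' @param subjects character vector of subject ids (column order).
#' @param replicate_ids character vector of replicate names (row order).
#' @return an object of class `phenotype_replicates`.
#' @export
phenotype_replicates <- function(statuses,
                                 subjects = colnames(statuses),
                                 replicate_ids = rownames(statuses)) {
  statuses <- as.matrix(statuses)
  storage.mode(statuses) <- "integer"
  if (anyNA(statuses) || !all(statuses %in% 0:1)) {
    stop("affected status values must be 0 or 1")
  }
  if (is.null(subjects)) subjects <- paste0("s", seq_len(ncol(statuses)))
  if (is.null(replicate_ids)) {
    replicate_ids <- paste0("rep", seq_len(nrow(statuses)))
  }
  ncase <- rowSums(statuses)
  if (any(ncase == 0L) || any(ncase == ncol(statuses))) {
    stop("every replicate must contain at least one case and one control")
  }
  dimnames(statuses) <- list(replicate_ids, subjects)
  structure(list(statuses = statuses,
                 subjects = as.character(subjects),
                 replicate_ids = as.character(replicate_ids)),
            class = "phenotype_replicates")
}

#' @export
print.phenotype_replicates <- function(x, ...) {
  cat(sprintf("phenotype_replicates: %d replicate(s) x %d subjects (%s cases each)\n",
              nrow(x$statuses), ncol(x$statuses),
              paste(range(rowSums(x$statuses)), collapse = "-")))
  invisible(x)
}

#' Read phenotype replicates from a tabular file
#'
#' Expects the phenotype TSV dialect: header `subject_id rep1 ... repR`,
#' one row per subject, status values 0/1. When `dataset` is supplied the
#' rows are aligned to its subject order by id; unmatched ids are an
#' error.
#'
#' @param path path to the phenotype TSV.
#' @param dataset optional [genotype_dataset()] used to align and check
#'   subject ids.
#' @return a [phenotype_replicates()] with an R x N status matrix.
#' @export
read_phenotypes <- function(path, dataset = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "subject_id") {
    stop("phenotype TSV must start with a subject_id column")
  }
  subj <- as.character(df$subject_id)
  reps <- names(df)[-1L]
  if (length(reps) == 0L) stop("phenotype TSV has no replicate columns")
  m <- t(as.matrix(df[, -1L, drop = FALSE]))  # R x N
  if (!is.null(dataset)) {
    idx <- match(dataset$subjects, subj)
    if (anyNA(idx)) {
      stop("phenotype file is missing subject(s): ",
           paste(utils::head(dataset$subjects[is.na(idx)], 10),
                 collapse = ", "))
    }
    extra <- setdiff(subj, dataset$subjects)
    if (length(extra)) {
      stop("phenotype file has unknown subject(s): ",
           paste(utils::head(extra, 10), collapse = ", "))
    }
    m <- m[, idx, drop = FALSE]
    subj <- dataset$subjects
  }
  phenotype_replicates(m, subjects = subj, replicate_ids = reps)
}

#' Write phenotype replicates to the tabular dialect
#'
#' @param phenotypes a [phenotype_replicates()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(inherits(phenotypes, "phenotype_replicates"))
  df <- cbind(data.frame(subject_id = phenotypes$subjects,
                         stringsAsFactors = FALSE),
              as.data.frame(t(phenotypes$statuses)))
  names(df) <- c("subject_id", phenotypes$replicate_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minor allele frequency per SNP
#'
#' MAF is the minor-allele count divided by 2N (diploid autosomal coding).
#'
#' @param dataset a [genotype_dataset()].
#' @return numeric vector of length M.
#' @export
snp_maf <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  dataset$snps$minor_allele_count / (2 * length(dataset$subjects))
}

#' Classify variants as private, rare, or common
#'
#' A *private* variant carries exactly one minor-allele copy in the whole
#' sample (a singleton). Among non-private variants, those with
#' MAF < `maf_rare` are *rare* and the rest *common*; a MAF exactly at
#' the boundary is common, matching the convention that rare means a
#' frequency strictly below 1%. Monomorphic columns (count 0), which can
#' occur in externally supplied files, get their own level and are
#' ignored by the scan statistic.
#'
#' @param x a [genotype_dataset()], or an integer vector of minor-allele
#'   counts (then `n_subjects` is required).
#' @param n_subjects number of subjects N (taken from the dataset when
#'   `x` is one).
#' @param maf_rare MAF threshold separating rare from common
#'   (default 0.01).
#' @return factor with levels `private`, `rare`, `common`, `monomorphic`.
#' @examples
#' classify_variants(c(1L, 13L, 14L), n_subjects = 697)
#' @export
classify_variants <- function(x, n_subjects = NULL, maf_rare = 0.01) {
  if (inherits(x, "genotype_dataset")) {
    n_subjects <- length(x$subjects)
    counts <- x$snps$minor_allele_count
  } else {
    counts <- as.integer(x)
    if (is.null(n_subjects)) stop("n_subjects is required for a count vector")
  }
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (any(counts < 0L)) stop("minor-allele counts must be non-negative")
  if (any(counts > 2L * n_subjects)) {
    stop("minor-allele count exceeds 2N")
  }
  maf <- counts / (2 * n_subjects)
  lab <- ifelse(counts == 0L, "monomorphic",
         ifelse(counts == 1L, "private",
         ifelse(maf < maf_rare, "rare", "common")))
  factor(lab, levels = c("private", "rare", "common", "monomorphic"))
}
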