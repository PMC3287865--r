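# Input parsing, validation, and variant classification.

test_that("minor-allele counts are column sums and dosages are validated", {
  ds <- manual_dataset(list(c(0L, 0L, 1L), c(2L, 1L, 0L)))
  expect_identical(ds$snps$minor_allele_count, c(1L, 3L))
  expect_error(manual_dataset(list(c(0L, 3L, 1L))), "\\{0, 1, 2\\}")
  g <- matrix(c(0L, NA, 1L), nrow = 3,
              dimnames = list(c("a", "b", "c"), "v1"))
  expect_error(
    genotype_dataset(g, data.frame(snp_id = "v1", chromosome = "1",
                                   position = 1L)),
    "missing genotype at SNP 'v1', subject 'b'")
})

test_that("unsorted SNPs are sorted by chromosome, position, then id", {
  expect_message(
    ds <- manual_dataset(list(c(1L, 0L), c(0L, 1L), c(1L, 0L)),
                         chromosome = c("2", "1", "1"),
                         position = c(5L, 50L, 10L)),
    "sorting")
  expect_identical(ds$snps$snp_id, c("v3", "v2", "v1"))
  # tie on (chromosome, position) broken by snp_id, deterministically
  expect_message(
    tie <- manual_dataset(list(c(1L, 0L), c(0L, 1L)),
                          chromosome = c("1", "1"),
                          position = c(10L, 10L)),
    NA)
  expect_identical(tie$snps$snp_id, c("v1", "v2"))
})

test_that("chromosome labels rank in natural genome order", {
  labs <- c("10", "2", "X", "1", "chr22", "Y", "MT")
  expect_identical(labs[order(binscan:::chrom_rank(labs))],
                   c("1", "2", "10", "chr22", "X", "Y", "MT"))
})

test_that("genotype TSV dialect round-trips a dataset exactly", {
  cfg <- sim_config(n_subjects = 12, n_cases = 4,
                    chromosome_snp_counts = c(40, 25), n_replicates = 2,
                    master_seed = 3)
  ds <- generate_genotypes(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(ds, path)
  back <- read_genotypes(path, format = "tsv")
  expect_identical(back$genotypes, ds$genotypes)
  expect_identical(back$snps, ds$snps)
  expect_identical(back$subjects, ds$subjects)
})

test_that("TSV reader recodes to the in-sample minor allele", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchromosome\tposition\ta\tb\tc",
               "v1\t1\t100\t2\t2\t1",   # allele count 5 of 6 -> flip
               "v2\t1\t200\t1\t0\t0",
               "v3\t1\t300\t1\t1\t1"),  # exactly 50%: keep coding
             path)
  expect_message(ds <- read_genotypes(path), "recoded 1 SNP")
  expect_identical(unname(ds$genotypes[, "v1"]), c(0L, 0L, 1L))
  expect_identical(unname(ds$genotypes[, "v3"]), c(1L, 1L, 1L))
  expect_identical(ds$snps$minor_allele_count, c(1L, 1L, 3L))
})

test_that("TSV reader rejects missing genotypes, naming SNP and subject", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchromosome\tposition\ta\tb",
               "v1\t1\t100\t0\t."), path)
  expect_error(read_genotypes(path), "SNP 'v1', subject 'b'")
})

write_test_vcf <- function(path, records,
                           samples = c("sampA", "sampB", "sampC")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=1>"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               records), path)
}

test_that("VCF genotypes load with minor-allele recoding", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1"))  # ALT freq 5/6
  ds <- read_genotypes(path, format = "vcf")
  expect_identical(ds$subjects, c("sampA", "sampB", "sampC"))
  expect_identical(unname(ds$genotypes[, "rs1"]), c(0L, 1L, 0L))
  # rs2's ALT is the major allele in-sample; dosage counts REF instead
  expect_identical(unname(ds$genotypes[, "rs2"]), c(0L, 0L, 1L))
  expect_identical(ds$snps$minor_allele_count, c(1L, 1L))
})

test_that("VCF reader rejects missing calls and multi-allelic records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t./.\t0/1")
  expect_error(read_genotypes(path), "SNP 'rs1', subject 'sampB'")
  write_test_vcf(path, "1\t100\trs9\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2")
  expect_error(read_genotypes(path), "multi-allelic.*rs9")
})

test_that("phenotype files align to genotype subject order", {
  ds <- manual_dataset(list(c(1L, 0L, 0L)), subjects = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\trep1\trep2",
               "c\t1\t0", "a\t0\t1", "b\t1\t1"), path)
  ph <- read_phenotypes(path, dataset = ds)
  expect_identical(ph$subjects, c("a", "b", "c"))
  expect_identical(unname(ph$statuses["rep1", ]), c(0L, 1L, 1L))
  expect_identical(unname(ph$statuses["rep2", ]), c(1L, 1L, 0L))
})

test_that("phenotype validation rejects bad subjects, values, and degenerate replicates", {
  ds <- manual_dataset(list(c(1L, 0L, 0L)), subjects = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\trep1", "a\t1", "b\t0", "zz\t0"), path)
  expect_error(read_phenotypes(path, dataset = ds), "missing subject.*c")
  expect_error(read_phenotypes(path), NA)  # standalone read is fine
  writeLines(c("subject_id\trep1", "a\t1", "b\t2", "c\t0"), path)
  expect_error(read_phenotypes(path), "0 or 1")
  writeLines(c("subject_id\trep1", "a\t1", "b\t1", "c\t1"), path)
  expect_error(read_phenotypes(path), "at least one case and one control")
})

test_that("phenotype round trip preserves the status matrix", {
  ph <- phenotype_replicates(matrix(c(0L, 1L, 1L, 0L, 1L, 0L), nrow = 2),
                             subjects = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, path)
  back <- read_phenotypes(path)
  expect_identical(back$statuses, ph$statuses)
})

test_that("variant classification follows the private/rare/common rules", {
  # singleton in 697 subjects is private; MAF 14/1394 >= 1% is common;
  # 13/1394 < 1% is rare
  cls <- classify_variants(c(1L, 14L, 13L, 0L), n_subjects = 697)
  expect_identical(as.character(cls),
                   c("private", "rare", "common", "monomorphic")[
                     c(1, 3, 2, 4)])
  expect_error(classify_variants(10L, n_subjects = 4), "exceeds 2N")
})

test_that("classification is exhaustive and exclusive over a random spectrum", {
  set.seed(11)
  for (n in c(50, 697)) {
    counts <- sample.int(2L * n, 500, replace = TRUE)
    cls <- classify_variants(counts, n_subjects = n)
    expect_false(anyNA(cls))
    tab <- table(cls)
    expect_identical(sum(tab), 500L)               # every SNP classified once
    expect_identical(sum(cls == "private"), sum(counts == 1L))
    expect_identical(sum(cls == "monomorphic"), 0L)
    maf <- counts / (2 * n)
    expect_identical(sum(cls == "common"), sum(counts > 1L & maf >= 0.01))
  }
})
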