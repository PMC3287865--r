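Package: binscan
Title: Fixed-Bin Region Scan for Private-Variant Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Region-based association scan for private (singleton) variants
    in case-control studies. Genome-ordered SNPs are partitioned into
    fixed-size, chromosome-respecting bins; within each bin an affected
    ratio -- the proportion of private minor alleles carried by cases -- is
    tested against the label-permutation null; and per-replicate
    significance calls are aggregated across phenotype replicates into a
    return-frequency ranking of candidate regions. Includes readers for
    VCF and tabular genotype/phenotype formats, a synthetic-data generator
    emulating a skewed minor-allele-frequency spectrum with fixed genotypes
    and replicate phenotypes under a liability-threshold model, analytic
    null-calibration helpers, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
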