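---
title: "The fixed-bin private-variant region scan: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fixed-bin private-variant region scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binscan)
```

## The problem

Private variants -- SNPs carried, as a single minor-allele copy, by one
subject in the whole sample -- are the extreme end of the rare-variant
spectrum. Individually they are untestable: a 2x2 table with one carrier
has essentially no power, whatever the test. Yet in deeply sequenced
exome panels they are often the *largest* frequency class, so discarding
them discards most of the data. The standard answer is *collapsing*:
combine many rare variants into one unit and test the unit.

binscan implements a deliberately simple, annotation-free collapsing
unit: the **fixed bin**. SNPs are ordered along the genome and grouped,
per chromosome, into consecutive blocks of B SNPs (B = 100 and B = 30
are the sizes the method was developed with). Compared with gene-based
grouping, fixed bins never produce single-SNP units, merge the signal of
small neighbouring genes, are non-overlapping by construction, and need
no external annotation. The price is resolution: a hit names a region of
B SNPs, not a gene.

## The statistic

Within bin $i$, let $m_i$ be the number of private variants and $k_i$
the number of them whose sole carrier is a case. The **affected ratio**
is

$$p_i = k_i / m_i,$$

the proportion of the bin's private minor alleles carried by affected
subjects. Under the null hypothesis that affected status is independent
of genotype, carriers are exchangeable with everyone else, so
$E[p_i]$ equals the case fraction (e.g. $209/697 \approx 0.30$ for a
209-case / 488-control design). The alternative of interest is
one-sided: an excess of case-carried private alleles.

Counting is per variant, not per carrier: a subject carrying two private
SNPs in one bin contributes twice. Because permutation is of the status
vector, the test remains valid under such carrier dependence. A
homozygous singleton is arithmetically impossible (the column sum would
be 2), so $k_i$ is a sum of 0/1 carrier statuses. Bins with $m_i = 0$
are *non-testable*: they are reported as untested rather than given a
p-value, and they are excluded from calibration averages (they can
never fire, so counting them would dilute every summary ambiguously).

The `max_count` argument generalises the statistic to non-private rare
SNPs: every minor-allele copy at a SNP with total count at most
`max_count` contributes one status-weighted term. The default
(`max_count = 1`) is the private-only analysis.

## Significance by permutation, and a tie-handling decision

Each bin is tested by permuting the case/control labels `n_perm` times
(default 1000) and recomputing the statistic. All bins share one stream
of permuted vectors per replicate, which preserves the joint null
across bins and costs one pass per permutation; marginal p-values are
unaffected.

The p-value definition needs care because the statistic is discrete:
$k_i$ takes at most $m_i + 1$ values, so ties between permuted and
observed statistics are common. Two conventions exist:

* **`ties = "exceed"` (default):** $p = \#\{k^{perm} \ge k^{obs}\}/B$.
  This is the standard permutation p-value; it is super-uniform
  ($P(p < \alpha) \le \alpha$ for every $\alpha$), i.e. the test never
  exceeds its nominal level.
* **`ties = "strict"`:** $p = \#\{k^{perm} > k^{obs}\}/B$. This reading
  subtracts the tie mass from every p-value and is *anti-conservative*
  for sparse bins. The degenerate case makes the problem vivid: a bin
  with one private variant whose carrier is a case has no permutation
  that strictly exceeds it, so $p = 0$ in every dataset, and such bins
  fire at the case-fraction rate (~0.3), not at $\alpha$. Empirically,
  with ~6 privates per bin the strict rule fires at roughly twice the
  nominal 5% level.

The two conventions converge as $m_i$ grows (at ~38 privates per
100-SNP bin they differ by under 0.01 in achieved level), so for the
dense bins the method was designed around the choice hardly matters.
binscan defaults to the valid convention because the aggregation step
below leans on the null calibration $E[\text{return frequency}] \le
R\alpha$, which the strict rule breaks badly for small bins; the strict
rule is kept as an option for comparison. The `plus_one` flag applies
the usual $(n_{exceed}+1)/(B+1)$ estimator, which avoids exact zeros;
it is off by default so that reported p-values are plain exceedance
fractions.

Comparisons are made on the integer counts $k$ rather than the ratios,
which is equivalent (the denominator is fixed within a bin) and immune
to floating-point tie artefacts.

## Aggregation: return frequency

When $R$ phenotype replicates share one fixed genotype matrix, each
replicate yields its own set of significant bins at level $\alpha$
(default 0.05). The **return frequency** of a bin is the number of
replicates in which it was significant. Under the global null a
testable bin's return frequency is Binomial$(R, q)$ with $q \le
\alpha$, so its expectation is at most $R\alpha$ -- 10 for $R = 200$,
$\alpha = 0.05$ (`expected_null_return()`). A Poisson approximation
with $\lambda = R\alpha$ calibrates how surprising a large return
frequency is: `poisson_return_tail(10, 50)` $\approx 1.5\times
10^{-19}$ (the single-term point mass; the upper tail is also
available and is the quantity a practitioner usually wants).
`rank_regions()` reports the top-k bins (default 10), ties broken by
ascending bin index so the ranking is deterministic, and
`expected_causal_in_topk()` gives the uniform-placement baseline
$n_{causal} \cdot k / n_{regions}$ for judging whether the top regions
are enriched for known causal variants.

Because the p-value null is discrete, the achieved per-replicate level
is typically *below* $\alpha$: with ~11 privates per 30-SNP bin the
largest attainable rejection region under 0.05 has probability
~0.02--0.03, so null mean return frequencies land around 4--6 per 200
replicates rather than near 10. This is ordinary conservatism -- the
$\le R\alpha$ bound always holds -- but summaries that expect the mean
to sit *near* $R\alpha$ implicitly assume near-continuous p-values,
which small bins do not provide.

## Binning rules

Per chromosome with $m$ SNPs, $\lfloor m/B \rfloor$ full bins are laid
left to right. A terminal remainder of $r \ge T$ SNPs stands alone; a
smaller remainder merges into the previous bin (size then in
$[B{+}1, B{+}T{-}1]$); a chromosome with fewer than $T$ SNPs is one
small bin. Bins never span chromosomes. $T = 25$ is the stated
companion of $B = 100$; for other sizes the default preserves that
ratio, $T = \lceil B/4 \rceil$ (8 for $B = 30$), and is overridable.
Bins are defined over *all* SNPs regardless of frequency class --
privateness enters only the statistic -- so the partition is a property
of the genotype panel alone. Position ties are ordered by SNP id,
making bin membership reproducible.

## The synthetic-data generator

The generator emulates the study design the scan targets: one fixed
genotype matrix reused by every phenotype replicate. Defaults are 697
subjects (209 cases), 24,487 SNPs on 22 autosomes, ~74% of SNPs with
MAF < 1%, and a private fraction (0.385) chosen so singletons outnumber
common variants; all are configurable. Each SNP draws a frequency class
(private / rare / common), then a minor-allele count -- 1 for private,
uniform on $\{2, \dots, \lceil 0.01 \cdot 2N \rceil - 1\}$ for rare,
and a Beta(0.8, 4) MAF truncated to $[0.01, 0.5]$ for common, so the
common spectrum is itself skewed toward its rare boundary as empirical
site-frequency spectra are. The class-based mixture (rather than one
continuous frequency law) is deliberate: it pins the two spectrum
summaries the design is specified by -- the private fraction and the
MAF < 1% fraction -- exactly in expectation. Allele copies are placed
uniformly without replacement over the $2N$ subject chromosomes, so
realised counts match the draws exactly and each private variant has a
single uniformly random carrier.

Phenotypes follow a liability-threshold model: liability = effects
$\times$ dosage at causal SNPs + standard Gaussian noise, fresh noise
per replicate, and exactly `n_cases` top-liability subjects become
cases -- matching a fixed case/control split by construction. With no
causal SNPs this is the exact global null (cases are a uniform random
subset of fixed size). `force_private_snps` lets a block of SNPs be
forced private so a bin can be packed with causal singletons for power
studies; `causal_private_in_bin()` builds that design.

What the generator does *not* emulate: linkage disequilibrium between
SNPs (carriers are independent across SNPs), population structure,
genotyping error, or missingness. Passing tests on synthetic data
therefore demonstrate the statistical machinery -- calibration,
ranking, determinism -- not robustness to the correlation structure of
real genotypes, where neighbouring false positives that track a causal
variant are expected and must be interpreted regionally. A small-N
artefact is also worth knowing: when $N \le 50$ no non-private SNP can
have MAF < 1%, so the "rare" class is empty in toy datasets.

## Numerical and reproducibility choices

* All randomness flows from one master seed. Replicate $r$ derives its
  seed as a fixed affine function of (master seed, $r$, stage), where
  the stage offset separates data generation from permutation scanning
  so the two never share a seed for the same replicate. Derived seeds
  stay below $2^{31}$.
* Minor-allele recoding is in-sample: a column whose allele count
  exceeds $N$ is flipped, an exact 50% tie keeps the file's coding.
* Multi-allelic VCF records are rejected, not split; missing genotypes
  are an error naming the SNP and subject (inputs are assumed
  imputed).
* Chromosome order is natural (1, 2, ..., 10, ..., 22, X, Y, MT), so
  global bin indices are stable across runs and machines.
* Problem sizes in the test suite are chosen to exercise every code
  path at small cost: the null-calibration check runs 50 replicates
  over 50 bins of 30 SNPs at 200 permutations (300 subjects, 90
  cases), and the power check plants 30 causal singletons of effect
  3.0 in one bin over 20 independent runs of the same scale. The
  acceptance script scales the same null design up to 100 bins, 200
  replicates, and 1,000 permutations.

## Known limitations

* Resolution is the bin: the scan nominates regions, not SNPs.
* The ranking is relative. No absolute significance cutoff on return
  frequency is attempted; the Poisson calibration contextualises the
  counts but the intended use is to hand a short candidate list to
  downstream analysis.
* With one genotype matrix behind all replicates, a chance association
  propagates through every replicate; high return frequency therefore
  ranks signals *within* a panel rather than certifying them.
* Marker density is not modelled: a fixed SNP count per bin spans
  variable physical distance. Varying B within its robust range
  (roughly 30--100) is the practical answer.
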