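---
title: "Modelling loss-of-function variation: CAF, knockouts and constraint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling loss-of-function variation: CAF, knockouts and constraint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofkit)
```

This vignette is the package's account of the models it implements, the
assumptions behind them, and the design choices made where the design was
genuinely open.

## The estimand: cumulative pLoF allele frequency

For a gene, let $p$ be the probability that a random haplotype carries at
least one predicted loss-of-function (pLoF) variant — the *cumulative
allele frequency* (CAF). Exome call sets report genotypes, not haplotypes,
so $p$ is estimated from the fraction $q$ of individuals carrying **no**
pLoF variant. Under random mating, $q = (1-p)^2$, hence

$$p = 1 - \sqrt{q}.$$

`estimate_caf()` implements exactly this. The convention is deliberately
conservative: an individual with two *different* pLoF variants is treated
as carrying them in cis on one haplotype, so contributes once to the
carrier count. On phased data this undercounts trans pairs; on unphased
data it avoids inflating $p$ with doubly counted compound heterozygotes.

Two boundary conventions matter:

- **Single carrier.** We report $p = 1 - \sqrt{1 - 1/n}$ rather than
  overriding with the allele-frequency convention $1/(2n)$. The two agree
  to first order (difference $O(1/n^2)$; for $n = 125{,}748$ both give
  $3.976\times10^{-6}$), and one formula keeps the estimator uniform.
- **Zero carriers.** $p = 0$ with `caf_censored = TRUE`: at finite sample
  size, absence of observed pLoF is censoring, not a measured zero.
  Downstream, censored genes fall into the "pLoF not yet observed" roadmap
  category rather than getting projections.

A further known bias is not corrected: singletons' true frequencies are on
average below their nominal $1/(2n)$, so $\hat p$ for singleton-driven
genes is, if anything, an overestimate. No correction is applied because
none is well identified from a single cohort.

## Genotype frequencies under three population structures

With $p$ in hand, `genotype_frequencies()` gives closed forms, all
assuming no selection against the two-hit genotype:

| structure | heterozygote | two-hit |
|---|---|---|
| outbred | $2p(1-p)$ | $p^2$ |
| bottlenecked | $2p(1-p)$ | $p^2$ (population-specific $p$) |
| consanguineous | $2p(1-p)$ | $(1-a)p^2 + ap$ |

The bottleneck affects the *distribution* of $p$ across genes (rare-allele
spectrum distorted by founder sampling), not the genotype-frequency
formulas; it therefore lives in the simulator and in the choice of which
cohort's $p$ you supply. For consanguineous individuals, $a$ is the
expected autozygous fraction of the genome: with probability $a$ the locus
is identical by descent and a single haplotype draw (probability $p$)
decides both copies. The default $a = 0.058$ is the reported mean for
individuals with second-cousin-or-closer parents. For reference,
second-cousin parents alone imply a child inbreeding coefficient
$F = 1/64 = 0.015625$; `inbreeding_coefficient(cousin_pedigree(2), "child")`
derives this by recursive kinship on the explicit pedigree, which doubles
as an internal consistency check of the consanguinity bookkeeping.
Per-individual variation in $a$ is **not** modelled — only the mean enters
the expectation, which is exact for the two-hit frequency but would matter
for higher moments.

## Sample-size projections

For two-hit frequency $f$:

- `discovery_sample_size(f)` returns $\lceil 1/f \rceil$, the size at
  which one two-hit individual is *expected*. The alternative definition
  $P(\ge 1) \ge 1/2$ differs only by $\ln 2$ and is available via
  `method = "probability"`; the expectation form is the default because
  histogram-versus-cohort-size comparisons read most naturally on expected
  counts. The exact rule behind published projection figures is not
  printed anywhere we could verify, so the default is documented as this
  package's choice.
- `lethality_sample_size(f, alpha)` returns
  $\lceil \ln\alpha / \ln(1-f) \rceil$: the smallest cohort in which
  observing zero two-hit individuals rejects viability at one-sided level
  $\alpha$. The default $\alpha = 0.05$ matches the 95% convention used
  throughout. For small $f$ the ratio of the two sizes tends to
  $-\ln(0.05) \approx 3.0$.

$f = 0$ yields `Inf` (unattainable), never an error.

## Constraint and Poisson bounds

Constraint is the ratio of observed pLoF variants $O$ to the expectation
$E$ under a neutral mutation model; $E$ is an input, never recomputed. The
upper bound is the one-sided Garwood construction:
$\lambda_{up} = \texttt{qgamma}(1-\alpha,\,O+1)$, so that
$P(\mathrm{Pois}(\lambda_{up}) \le O) = \alpha$, reported as
$\lambda_{up}/E$. For $O = 0$ this reduces analytically to $-\ln(\alpha)/E$
— e.g. $2.996/12.6 = 23.8\%$ for a fully unobserved region with 12.6
expected variants (published rounding of the same quantity prints 23.7%,
consistent with an unrounded expected count slightly above 12.6; the
package reports full precision). The likelihood-ratio-style intervals used
by some constraint browsers are a different construction and are out of
scope.

Region-restricted expectations use
`region_adjusted_expected(E, mu_region, mu_gene)` $= E \cdot
\mu_{region}/\mu_{gene}$, with $\mu$ the summed mutation frequencies of
all possible pLoF variants in the region; the map is additive over any
partition of the transcript. Codon intervals are 1-based and inclusive at
both ends (a mask over codons 1–144 contains codon 144). The bundled
PRNP-like fixture uses *uniform* per-codon weights and a synthetic
whole-transcript expectation calibrated so the codon 1–144 region maps to
the curated expectation of ≈6.06; real trinucleotide-context mutation
tables would replace both in a real analysis.

Gene-set comparison computes the two-sample Kolmogorov–Smirnov $D$
directly from integer ECDF counts at the pooled sample points (so it is
bit-for-bit the supremum ECDF difference), takes the asymptotic two-sided
p-value from `stats::ks.test()`, and summarises each set by its mean with
a t-based 95% CI — appropriate because realistic gene-set sizes are in the
hundreds.

## The knockout roadmap

`classify_genes()` applies rules sequentially, first match wins: OMIM-style
disease flag → two-hit-reported flag → pLI $> 0.9$ (strict) → CAF $= 0$ →
pLoF observed. A missing pLI skips the haploinsufficiency rule with a
warning; a gene with missing pLI *and* $p = 0$ therefore lands in "pLoF not
yet observed", reading the sequence as a data-availability cascade. The
two-hit-reported flag is consumed as a single merged boolean — the source
cohorts behind such flags use differing MAF rules, and reconciling them is
upstream curation, not computation.

## The synthetic cohort generator

`simulate_catalog()` draws per-gene true CAF log-uniformly over
$[10^{-6}, 10^{-2}]$ by default, spanning the orders of magnitude seen in
large exome call sets without asserting their exact distribution. The CAF
is split across a number of variants proportional to coding length
(default 1 per 100 codons), with at most 10% of variants given "common"
weights and the rest held within 2× of the rarest — an ultra-rare-dominated
spectrum. Variants are independent across haplotypes (no linkage
disequilibrium), matching the frequency-only treatment of the closed
forms.

`simulate_cohort()` is the stochastic counterpart of the formulas, stored
sparsely (per variant, the indices of carrying haplotype slots), so a
2,000,000-individual consanguineous cohort at $p = 10^{-3}$ simulates in
well under a second:

- *outbred*: each haplotype carries each variant independently with its
  frequency (binomial count, then uniform slot choice — exact, not
  approximate);
- *bottlenecked*: founder haplotypes are drawn once, then every cohort
  haplotype is a uniform draw with replacement from the pool, so alleles
  absent from the pool have cohort count exactly 0;
- *consanguineous*: per individual **and per gene**, an IBD coin-flip with
  probability $a$ copies one haplotype draw to both slots. Modelling
  autozygosity per gene rather than as genome-length runs reproduces the
  expectation $(1-a)p^2 + ap$ exactly, which is all the closed forms use.

What passing tests on this generator do **not** show: robustness to LD,
population stratification, genotype error, variant miscalling, or a
realistic (non-log-uniform) CAF distribution. The generator validates the
estimators under their own assumptions; real-data behaviour depends on the
upstream call set and annotation.

## Numerical and operational choices

- MAF thresholds are strict (`<`), with defaults 0.05 for CAF input sets
  and 0.001 for constraint input sets; all thresholds flow from the run
  config (`default_run_config()`), never from duplicated literals.
- Problem sizes in the test suite: convergence checks use
  $n = 2\times10^5$ outbred and $2\times10^6$ consanguineous individuals
  at $p \ge 10^{-3}$ (3-SE binomial bands); property tests use 200–1,000
  random cases under fixed seeds; the end-to-end determinism check runs
  two 60-gene pipelines and compares bytes. These sizes give comfortable
  statistical resolution at negligible runtime.
- Determinism: every stochastic entry point takes an explicit seed;
  pipeline stages derive child seeds by small offsets; outputs contain no
  timestamps, so identical configs reproduce byte-identical TSVs.
- Degenerate inputs: zero-frequency genes give zero carriers and censored
  CAF; `expected = 0` flags the ratio undefined rather than dividing;
  empty catalogs produce valid empty reports; header-only VCFs parse to
  empty tables.

## Known limitations

Selection against two-hit genotypes is deliberately excluded (projections
are therefore upper bounds on discovery feasibility for genes where the
knockout is deleterious). Phasing is never attempted. The prevalence
module implements only the incidence × attribution × survival product and
a direct-estimate override; per-disease refinements (at-risk-population
corrections) are left to the caller.
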