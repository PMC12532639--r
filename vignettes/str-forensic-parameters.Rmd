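---
title: "Forensic parameters and population structure from autosomal STR genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic parameters and population structure from autosomal STR genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpopgen)
```

## Purpose and scope

Forensic genetics laboratories maintain population databases of autosomal
short tandem repeat (STR) genotypes. Before such a database can support
casework (identification, kinship testing) or publication, a standard set of
summary statistics must be computed: allele and genotype frequencies, a test
of Hardy-Weinberg equilibrium (HWE) per locus, the per-locus and combined
forensic efficiency parameters, and — when several population samples are
present — pairwise genetic distances to screen for substructure. `strpopgen`
implements exactly this stack over plain tab-delimited genotype tables, for
diploid autosomal STR data only (no SNPs, no X/Y markers, no haploid or
polyploid genotypes).

## Input data model

The input format is the one used throughout the forensic STR literature:
a header row, sample ID in column 1, population ID in column 2, then two
columns per locus carrying the two allele calls of each diploid genotype.
Alleles are repeat counts; "point alleles" such as `9.3` denote partial
repeats and are preserved exactly. Internally, allele labels are stored as
canonical strings (`"12.0"` reads as `"12"`) and compared numerically, which
sidesteps floating-point equality problems while keeping `9.3 < 10` ordering.

Missing data: `0`, the empty string and `NA` all mark a missing allele on
input; `0` is written on output. A call with only one allele present is
treated as fully missing at that locus (with a warning), because every
statistic here needs complete diploid genotypes. Missing calls are dropped
per locus, not per sample: an individual untyped at one locus still counts
everywhere else, which maximizes the usable data. Population order is the
order of first appearance in the file and locus order is header order, so
every output is deterministic for a given input.

## The exact Hardy-Weinberg test

For one locus, condition on the observed allele counts $n_1, \dots, n_k$
(with $\sum_i n_i = 2n$ for $n$ individuals). Under random mating every way
of pairing the $2n$ allele copies into $n$ genotypes is equally likely, so a
genotype configuration $\{n_{ij}\}$ has conditional probability

$$
P(\{n_{ij}\} \mid \{n_i\}) \;=\;
\frac{n!\,\prod_i n_i!\; 2^{H}}{(2n)!\,\prod_{i\le j} n_{ij}!},
$$

where $H = \sum_{i<j} n_{ij}$ is the number of heterozygous individuals.
Note the $2^H$ factor and that the $n_i$ are integer allele *counts*: with
these conventions the probabilities over all configurations with the same
allele counts sum to 1, which the implementation verifies to $10^{-9}$ on
every complete enumeration. The exact p-value sums the probabilities of all
configurations no more probable than the observed one.

Two evaluation paths share this null:

* **Complete enumeration** walks every configuration compatible with the
  allele counts (a recursion over the symmetric count table, with dead
  branches pruned so every path ends in a valid configuration). It is used
  whenever the number of configurations is within a budget (default $10^6$);
  a cheap count-only pass decides feasibility before any probability work is
  done. Enumeration results are seed-independent.
* **Permutation Monte Carlo** is used beyond the budget: each replicate
  shuffles the multiset of $2n$ observed allele copies and re-pairs
  consecutive copies, which samples configurations exactly from the
  conditional null. The p-value uses the add-one estimator
  $(1 + \#\{s_{\text{rep}} \le s_{\text{obs}}\})/(B + 1)$ so it is never 0,
  and is reported with its binomial standard error
  $\sqrt{p(1-p)/B}$. The default is $B = 10{,}000$ replicates with an
  explicit seed — there is no hidden RNG state.

Probabilities are compared in log space; configurations tied with the
observed one (within $10^{-7}$ on the log scale) count toward the p-value,
as ties must in an exact test. Bonferroni adjustment multiplies each p-value
by the number of testable loci in its group, capped at 1; loci with fewer
than two typed individuals are flagged untestable and excluded from that
count. Asymptotic chi-square tests and one-sided heterozygote
excess/deficit variants are deliberately out of scope.

## Forensic parameters

With $p_i$ the allele frequencies and $g_i$ the *observed* genotype
frequencies at a locus:

| Parameter | Definition |
|---|---|
| Ho | heterozygous individuals / typed individuals |
| He | $1 - \sum_i p_i^2$ (per locus); arithmetic mean across loci |
| PIC | $1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ |
| PM | $\sum_i g_i^2$ |
| PD | $1 - \mathrm{PM}$ |
| PE | $h^2 (1 - 2 h H^2)$, $h$ = Ho, $H$ = 1 − Ho |
| TPI | $1/(2H)$ |

Three conventions worth stating explicitly, because the symbols collide
across formulas in parts of the literature:

* PE takes *proportions*, not counts; the count form is unbounded and is
  not a probability. With proportions this is the standard
  exclusion-probability formula.
* PM squares observed genotype frequencies, not HWE-expected ones, so it is
  meaningful even at loci out of equilibrium.
* TPI at $H = 0$ (every individual heterozygous) is reported as `Inf` with
  a warning rather than an error — all-heterozygote samples are legitimate
  small-sample data.

No small-sample bias correction is applied to He, and no minimum-allele-
frequency flooring (5/2N-style casework rules) is applied to any frequency.

Combined values across loci follow two rules: Ho, He, PM and TPI multiply
across loci, while PE and PD combine as $1 - \prod_\ell (1 - x_\ell)$.
Because $\mathrm{PD}_\ell = 1 - \mathrm{PM}_\ell$ per locus, the combined PD
equals $1 - \prod_\ell \mathrm{PM}_\ell$ exactly — the two combining rules
are mutually consistent, and the test suite asserts the identity to
$10^{-12}$. Product-combining Ho and He is unusual (most published tables
report means); both are provided, with the product as the default and
`combined_het = "mean"` as the alternative. PIC and the HWE p-value have no
combined form and are reported per locus only.

## Genetic distances

For populations $x$ and $y$, with $x_{ij}$, $y_{ij}$ the frequency of
allele $i$ at locus $j$:

* **Nei's D_A**:
  $D_A = 1 - \frac{1}{r} \sum_j \sum_i \sqrt{x_{ij} y_{ij}}$, summing over
  the union of alleles at each of the $r$ loci typed in both populations
  (alleles absent from one population contribute 0).
* **Homozygosity-based F_st**:
  $F_{st} = \dfrac{(J_x + J_y)/2 - J_{xy}}{1 - J_{xy}}$, where
  $J_x = \frac{1}{r}\sum_j \sum_i x_{ij}^2$ (similarly $J_y$) and
  $J_{xy} = \frac{1}{r}\sum_j \sum_i x_{ij} y_{ij}$. The numerator uses the
  *mean* of the two within-population homozygosities; a difference form
  would be asymmetric in the pair and could be negative for identical
  populations, contradicting the 0–1 range both statistics are defined on.
  Homozygosities are averaged across loci first and the ratio formed once
  (ratio of averages, not average of ratios). Two populations fixed for the
  same allele ($J_{xy} = 1$) get $F_{st} = 0$ by definition, and negative
  sampling estimates are clipped to 0 with a flag in the result.

Both statistics are 0 for identical frequency vectors and 1 for disjoint
fixed ones. Per pair, only loci typed in both populations enter (pairwise-
complete), and $r$ counts exactly those loci. Weir–Cockerham
variance-component F_st, bootstrap intervals and tree building from the
matrices are out of scope.

## The synthetic-population generator

Validation needs data with known truth, so the generator is first-class
code, not a test fixture. A `population_spec` fixes per-locus allele
frequency vectors, a sample size, an inbreeding coefficient `fis` and a
missing-call rate. Genotypes are drawn per individual per locus: with
probability `fis` one allele is drawn and duplicated (identical by
descent), otherwise two independent draws. This mixture model was chosen
over per-allele correlation because it gives the exact marginal
$\mathrm{Ho} = (1 - f_{is})\,\mathrm{He}$ needed to calibrate the HWE power
checks. Between-population divergence is generated by a multiplicative
log-normal tilt: population 2's frequencies are
$f'_i \propto f_i \exp(\delta z_i)$ with $z_i \sim N(0,1)$, renormalized.
At $\delta = 0$ this is exactly the identity, and the mean D_A between the
two simulated populations increases with $\delta$ (verified by simulation
in the test suite). All randomness flows from one explicit seed per call.

What the generator does *not* emulate: stepwise mutation along pedigrees,
kit-specific allele ladders, linkage between loci, genotyping artifacts
(stutter, dropout correlated with allele length). Tests passing on this
generator therefore validate the *statistics*, not robustness to real-world
typing error.

## Numerical choices and problem sizes

* All factorial arithmetic is in log space (`lgamma`); enumeration
  normalization is checked to $10^{-9}$.
* Exact-test ties are detected on the log scale with tolerance $10^{-7}$.
* Allele labels are canonical strings; no numeric value is ever used as a
  map key.
* The enumeration/Monte-Carlo switch is a configuration count budget
  (default $10^6$), not a locus-count or allele-count heuristic.

The validation suite exercises, among others: complete enumeration against
two independently written brute-force oracles (exhaustive matching of
distinguishable allele copies, and loop-based enumeration of genotype
tables) over all 2-allele configurations with $n \le 10$ and all 3-allele
configurations with $n \le 6$; Monte-Carlo agreement with enumeration
within 3 standard errors on a 20-configuration panel; null calibration on
1000 loci simulated under HWE at $n = 100$ with 5 equifrequent alleles
(the exact test is conservative, so the rejection rate at $\alpha = 0.05$
stays at or below nominal); power above 50% at $f_{is} = 0.3$, $n = 200$;
frequency recovery within 0.05 at $n = 2000$; and read–write–read identity
over 100 simulated tables. These sizes keep the whole suite within a couple
of minutes on a single core while leaving the binomial noise on every rate
well below the margin being asserted.

## Known limitations

* Autosomal diploid STR data only; the reader rejects anything else.
* PM is a sample statistic; with $n$ individuals it is bounded below by
  $1/n$, so very small samples overstate matching probability.
* The Monte-Carlo p-value has resolution $1/(B+1)$; raise `replicates` for
  loci whose p-values sit near a decision threshold.
* F_st here is the homozygosity-based estimator; it is not comparable
  numerically to variance-component estimators on the same data.
* The English/Spanish toggle in the command-line layer translates column
  headers only; numbers are locale-independent.
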