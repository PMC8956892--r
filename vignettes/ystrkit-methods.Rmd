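---
title: "Methods: forensic Y-STR parameters, AMOVA/Rst and haplogroup assignment"
author: "ystrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic Y-STR parameters, AMOVA/Rst and haplogroup assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

## Scope and data model

ystrkit analyses Y-chromosomal short tandem repeat (Y-STR) haplotypes of the
kind produced by forensic multiplex kits. A haplotype is one male's joint
allele profile across a locus panel; because the Y chromosome is transmitted
as a non-recombining block, the haplotype — not the genotype — is the unit of
analysis. Four panels are built in (minimal haplotype with 9 locus slots,
PowerPlex Y12, Yfiler 17, PowerPlex Y23 with 23 slots); the multi-copy locus
DYS385 contributes two calls per male, stored as an unordered pair sorted
ascending so haplotype comparison never depends on copy order.

Alleles are named by complete repeat count, with micro-variants written as
`24.1` (24 repeats plus one extra base). Designations are kept as exact text
and round-trip losslessly; a variant suffix of two digits (`24.15`) is
malformed by construction, since the suffix counts the bases of one
incomplete repeat. Parsed repeat counts outside 5–45 are treated as missing
with a warning by default (hard error on request); the observed range in
typical population samples is roughly 7–32, so anything beyond the band is
overwhelmingly a typing or transcription artifact. Amelogenin is carried as
sample metadata (the Y-deletion flag) and never enters any statistic.
Profiles with any failed locus ("partial profiles") are excluded from all
statistics by `filterComplete()`, which partitions rather than drops: the
excluded set remains available, and the pipeline manifest records
`n_input = n_excluded + n_complete`.

## Forensic summary parameters

For a locus with allele frequencies $p_i$ estimated from $n$ sampled alleles
(single-copy loci: $n$ males; DYS385: $2n$ pooled copies):

* **Gene diversity** $GD = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$,
  the unbiased probability that two alleles drawn without replacement
  differ. The estimate is clipped into $[0,1]$.
* **Polymorphic information content** (Botstein form)
  $PIC = 1 - \sum_i p_i^2 - \left(\sum_i p_i^2\right)^2 + \sum_i p_i^4$.
* **Match probability** $PM = \sum_i p_i^2$ and
  **power of discrimination** $PD = 1 - PM$, so $PM + PD = 1$ identically.

At the haplotype level, with $p_i$ the relative frequencies of the $h$
distinct haplotypes among $n$ males:

* **Haplotype diversity** $HD = \frac{n\left(1-\sum_i p_i^2\right)}{n-1}$.
  This equals the fraction of unordered sample pairs carrying different
  haplotypes — an exact algebraic identity the test suite checks to 1e-12
  against a brute-force pair count.
* **Discrimination capacity** $DC = h/n$.
* Haplotype-level $PM = \sum_i p_i^2$; the singleton count is the number of
  haplotypes observed exactly once.

`forensicSummary()` reports one row per panel locus, with DYS385 summarised
once from its pooled a/b distribution. The mean-alleles-per-locus figure
divides the total distinct-allele count by the panel's *slot* count (23 for
PowerPlex Y23), which is how these kits are conventionally reported; the
mean gene diversity and its standard error (sample SD across locus rows
divided by the square root of their number) use the locus rows themselves.
With a single locus the SE is reported as absent rather than zero.

**Display convention.** Published forensic tables print these parameters at
four decimals by truncation: $DC = 94/95 = 0.98947\ldots$ is displayed as
0.9894, not 0.9895. `displayTrunc()` implements this; JSON output and all
internal arithmetic keep full double precision.

## Population comparison: Rst by AMOVA

Differentiation between populations uses the microsatellite-specific
distance: for two haplotypes, the squared difference in repeat number summed
over loci, with micro-variants valued at repeats + variant/10. The 0.1
weight keeps the allele ordering (24 < 24.1 < 25) while making an
incomplete-repeat difference deliberately small next to a full repeat step;
the alternative of excluding micro-variant-bearing loci is available by
subsetting the panel. Two conventions follow common database practice and
are switchable: DYS385 is excluded by default (when included, the unordered
pair contributes the minimum over its two possible pairings), and DYS389II
is used as typed, with optional subtraction of DYS389I (DYS389II is a
compound fragment that contains DYS389I).

A two-level analysis of molecular variance partitions the total sum of
squared deviations over $N$ individuals in $K$ populations, using the
identity that a group's SSD equals the sum of its pairwise squared distances
divided by its size:

$$SSD_{total} = \frac{1}{N}\sum_{i<j} d_{ij}, \qquad
  SSD_{within} = \sum_k \frac{1}{n_k}\sum_{i<j \in k} d_{ij}, \qquad
  SSD_{among} = SSD_{total} - SSD_{within}.$$

Variance components come from equating mean squares to expectations:
$\sigma^2_w = SSD_{within}/(N-K)$ and
$\sigma^2_a = \left(SSD_{among}/(K-1) - \sigma^2_w\right)/\bar n$ with
$\bar n = (N - \sum_k n_k^2/N)/(K-1)$, giving
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$, the Rst analogue for
repeat-count distances. On one-locus data this reduces exactly to the
classical ANOVA decomposition, which the test suite exploits: every 2-group
instance up to $N = 8$ over exhaustively enumerated small allele
configurations is compared to an explicit group-mean/deviation oracle at
1e-9.

Significance is assessed by permuting individual-to-population labels
(default 1000 permutations, seed recorded in the result) with the
$(b+1)/(m+1)$ p-value convention, which can never report zero. Calibration
is itself under test: splitting one simulated population randomly in two, the
test rejects at $\alpha = 0.05$ in 2–8% of 500 replicates. Negative
$\Phi_{ST}$ estimates — the unbiased estimator's sampling behaviour around
zero, with floor $-1/(\bar n - 1)$ for identical populations — are reported
as computed in the pairwise Rst matrix and clamped to zero only when the
matrix is fed to MDS, where a negative distance has no meaning. When
$\sigma^2_a + \sigma^2_w = 0$ (all haplotypes identical everywhere)
$\Phi_{ST}$ is defined as 0.

## Ordination

`classicalMDS()` embeds the Rst matrix by Torgerson double centering
($B = -\tfrac12 J D^2 J$) and eigendecomposition, delegating the numerics to
`stats::cmdscale`; the tests verify exact recovery of planted Euclidean
configurations (planar point sets to 1e-9, up to rigid motion). Negative
eigenvalues — Rst matrices are not guaranteed Euclidean — are dropped with a
warning, and if fewer positive eigenvalues than requested dimensions exist,
fewer columns are returned and flagged.

## Bayesian haplogroup assignment

Deep paternal lineages (haplogroups such as R1a, H, L) can be inferred from
STR alleles because allele frequency distributions differ between
haplogroups. Given a table of per-haplogroup, per-locus allele frequencies
$f_g(a)$ and priors $\pi_g$ (uniform by default), each haplotype is scored by

$$P(g \mid \text{haplotype}) \propto \pi_g \prod_{\ell} f_g(a_\ell),$$

the two DYS385 calls entering as exchangeable draws from a single per-locus
distribution. Alleles unseen in a haplogroup's table are floored at
$\varepsilon = 10^{-3}$ (configurable): an unseen allele should penalize a
haplogroup heavily but not eliminate it, since reference tables are finite
samples. With smoothing disabled, a haplotype with zero likelihood under
every haplogroup is reported as unclassifiable rather than raising an error.
Posteriors are normalized across haplogroups on every call; the population
spectrum reports percentages over classified samples (summing to 100) with
unclassifiable samples counted separately.

The package ships no real reference table — published haplogroup predictor
tables are external data users supply in the documented long CSV format
(`haplogroup, locus, allele, frequency`). The synthetic fixture
(`makeHaplogroupFixture()`) places unimodal per-locus distributions
(0.1/0.8/0.1 on a mode and its neighbours) with modes a configurable number
of repeats apart: at separation 0 accuracy is at chance, at separation 4
with ten haplogroups and fifteen loci the classifier recovers at least 95%
of 1000 planted labels, which is what the recovery test asserts.

## The synthetic population generator

Real Y-STR population samples are dominated by singletons: in a typical
~100-male sample at 23 loci nearly every complete haplotype is unique. The
generator reproduces that structure with a star genealogy: each sample draws
a haplogroup from a configurable mixture (default R1a-dominated with
substantial H and L, the profile typical of North-Indian caste populations),
then descends independently from that haplogroup's founder haplotype for
`depthGenerations` generations, accumulating strictly single-step (±1
repeat) mutations — Poisson-distributed counts per locus at `mutationRate`
per generation, fair coin for direction. Defaults are 0.002 per locus per
generation (the typical Y-STR order of magnitude) and depth 600, which at 23
loci yields $h/n \ge 0.9$ with a heavily singleton-dominated spectrum.
Micro-variant alleles are injected as a separate, locus-restricted event at
DYS481, DYS576 and DYS390 only — the loci where such alleles are commonly
observed — at 0.03 per sample-locus, giving a handful per 100-male sample.
Four partial profiles per 100 samples are blanked at random loci. Repeat
counts are reflected back into the 5–45 band. Every dataset carries its full
configuration including the seed; the same seed reproduces the dataset
byte-for-byte.

`simulateDivergentPair()` adds planted population structure: both
populations share founders, each population's founders first drift
independently for `divergenceT` generations, then samples radiate as above.
Rst between the pair grows with `divergenceT`, which the divergence-recovery
test checks as a median over ten seed replicates at 50 vs 500 generations
(50 samples per population).

What the generator deliberately does not emulate: coalescent genealogy
(lineages are independent given the founder, so it understates haplotype
sharing relative to a Wright–Fisher population of small size), multi-step
mutations, locus-specific empirical mutation rates, and linkage between
haplogroup and specific diagnostic alleles beyond founder differences. Its
per-locus diversity under default settings is somewhat higher than in real
population samples (founder offsets plus 600 generations of drift spread
alleles over more states than a real bottlenecked population shows).
Passing tests therefore demonstrate correctness of the estimators and
calibration of the tests on data with the assumed structure, not demographic
realism.

## Numerical and validation choices

* Gene diversity clipped to $[0,1]$; $\Phi_{ST}$ defined 0 when both
  variance components vanish; negative eigenvalues dropped in MDS.
* Haplotype identity is exact string equality of allele designations with
  the DYS385 pair pre-sorted; micro-variants make alleles distinct (24 ≠
  24.1).
* Permutation p-values use $(b+1)/(m+1)$; every stochastic routine takes an
  explicit seed and records it in its result object.
* Displayed tables truncate at 4 decimals; JSON round-trips at 17
  significant digits.
* Validation problem sizes: the HD identity runs over 200 random datasets of
  4–25 samples; the AMOVA oracle enumerates all 2-group splits with
  $N \le 8$ over 3-allele (for $N \le 6$) and 2-allele (for $N \le 8$)
  configurations, several thousand instances; permutation calibration uses
  500 splits of a 40-sample population at 200 permutations each; divergence
  recovery uses 10 seeds at 50 samples per population. These sizes give the
  properties room to fail while keeping the default check quick on a
  desktop.

## Limitations

Rst estimation follows one declared convention set (Slatkin-style squared
repeat distances, individual-level permutation, the $\bar n$ correction for
unequal sizes); other software makes other choices, and small numerical
differences between implementations are expected. The haplogroup classifier
is only as good as the supplied frequency table and reports posteriors under
the stated independence-across-loci assumption, which real linkage on the
non-recombining Y violates for closely related haplogroups. Hierarchical
(three-level) AMOVA with regional grouping and haplotype-frequency-based
(Fst) distances are out of scope.
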