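---
title: "Methods: individual-based ABBA/BABA tests, admixture proportions and hybrid-triangle analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-based ABBA/BABA tests, admixture proportions and hybrid-triangle analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgressr)
```

## The inference problem

Two taxa that share polymorphism may do so because of hybridization or
simply because ancestral variation persisted through successive
speciation events (incomplete lineage sorting, ILS). Clustering methods
cannot separate the two; the four-taxon ABBA/BABA framework can. On the
species tree `(((P1, P2), P3), O)`, biallelic sites whose gene trees
conflict with the species tree fall into two classes: ABBA
(`h1 = h4 ≠ h2 = h3`, P2 and P3 share the derived allele) and BABA
(`h2 = h4 ≠ h1 = h3`, P1 and P3 share it). ILS alone produces the two
classes at equal rates, so

$$D = \frac{n_{ABBA} - n_{BABA}}{n_{ABBA} + n_{BABA}}$$

is centred on zero without gene flow and pushed toward 1 by P3→P2
introgression. Everything in this package is built around estimating D
and its derived quantities honestly from small samples of diploid,
unphased RAD genotypes.

## Data model

Genotypes live in a long tibble (`locus`, `individual`, `a1`, `a2`),
unphased, with `NA`/`NA` as the missing call. Allele order is the storage
order of the input file (VCF GT order, TSV column order): arbitrary, but
fixed, which is what makes the "both alleles" test scheme below
deterministic for a given input. Missing data are never imputed; all
analyses require the complete biallelic core obtained by
`filter_complete_biallelic()` (exactly two observed alleles, zero missing
calls — the same rule that reduces a raw RAD SNP set to its fully
genotyped polymorphic core). Multi-SNP RAD loci are treated as
independent sites; `filter_one_snp_per_locus()` provides the stricter
one-site-per-locus alternative for users worried about intra-locus
linkage.

## Individual-based tests

With only a handful of individuals per taxon and possible admixture in
the reference taxa themselves, a single arbitrary choice of reference
individuals can bias D. The package therefore enumerates the full
Cartesian product P1 × P3 × O of reference individuals for every P2
candidate. Each combination is evaluated twice: run 1 on the first-stored
allele of all four individuals, run 2 on the second. Heterozygous sites
thus contribute to the counts instead of being discarded. The exact
pairing of alleles into two pseudo-haplotypes is arbitrary for unphased
data; because homozygous sites are unaffected and heterozygous sites
appear once in each run, the *sum* of counts over the two runs is
invariant to the pairing. An exhaustive 16-assignment scheme
(`allele_scheme = "all_haplotypes"`) is available for users who prefer to
average over every possible assignment; the default paired scheme matches
the natural "two runs per combination" design and its test count
`N = N1 · N3 · NO · 2` per P2 individual.

Tests with no informative site have undefined D and are excluded from
averages; their count is logged in the summaries and the report metadata.
Taxon summaries weight member individuals equally (mean of individual
means), so unequal test counts cannot skew a taxon value.

**Controls.** With `controls = TRUE`, every P1-group member is also run
as P2 (expected D ≈ 0 — in fact the taxon mean is exactly 0 under full
enumeration, because each ordered pair of P1 individuals appears in both
roles and swapping P1 and P2 negates D), and every P3-group member is run
as P2 (maximal gene flow). Control individuals are removed from their own
reference pool, so no sequence is ever tested against itself.

**Admixture proportion f.** Each individual's mean excess
$\bar S_i = \overline{n_{ABBA} - n_{BABA}}$ is scaled by the mean excess
$\bar S_{max}$ pooled over *all* maximal-control tests:
$f_i = \bar S_i / \bar S_{max}$. A pooled denominator (rather than one
matched per reference combination) is used because the matched pairing is
not identifiable from the published design this implements; the pooled
definition preserves the key identity that the ratio of two taxa's f
values equals the ratio of their mean excesses, which the acceptance
suite checks against published values. `f` is reported as a percentage
and is a conservative minimum estimate.

**Reference bias.** For each role (P1, P3, outgroup),
`reference_bias_analysis()` reports every reference individual's mean D
over the tests containing it, its deviation from the grand mean
(deviations weighted by test counts sum to zero within a role), a
one-way ANOVA of the individual effect, and flags individuals whose
|deviation| exceeds 0.1 (typical benign references sit below ~0.09 on
real RAD data; problematic ones reach 0.18–0.29). ANOVA is the default
test; because the tests sharing a dataset are not independent, its
p-value is a screening diagnostic, not a calibrated error rate —
Kruskal–Wallis is offered for heavy-tailed D distributions. Note the
direction: a P1 reference that itself carries P3 ancestry matches P3 at
extra sites, inflates BABA, and biases D *downward* in the tests that
use it.

## Population-frequency D and bootstrap

`population_dstat()` computes D from per-group derived-allele
frequencies,

$$D = \frac{\sum_l (1-\hat p_1)\hat p_2 \hat p_3 (1-\hat p_4) - \hat p_1 (1-\hat p_2)\hat p_3(1-\hat p_4)}
           {\sum_l (1-\hat p_1)\hat p_2 \hat p_3 (1-\hat p_4) + \hat p_1 (1-\hat p_2)\hat p_3(1-\hat p_4)},$$

with the derived allele defined per locus as the least frequent allele in
the outgroup sample. An exact 0.5 tie is broken by the global minor
allele, then lexicographically — a fully deterministic rule. With one
haploid sequence per group the formula reduces *exactly* to the
site-pattern D, a property the test suite asserts on random instances.
Significance uses 100 bootstrap replicates in which each locus ×
population derived-allele count is redrawn from a binomial with size
equal to the sampled gene copies and probability equal to the observed
frequency; the min–max range of replicate D values is reported and the
statistic called significant when the range excludes zero. When every
frequency is 0 or 1 the binomial is degenerate and the range has zero
width — the correct limiting behaviour.

## Hybrid-triangle analysis

Loci fixed for different alleles between the two parental taxa
("diagnostic" loci; fixation means fixation in the sample, with an
optional minor-allele-frequency relaxation that defaults to strict) give,
for each individual, the hybrid index `q` (proportion of B-type gene
copies) and the inter-source heterozygosity `Q12` (proportion of
panel loci heterozygous A-type/B-type). Two reference curves structure
the triangle: `Q12 = 2·min(q, 1−q)`, attained when every individual has
one pure parent (F1s and first-generation backcrosses), and
`Q12 = 2q(1−q)`, the Hardy–Weinberg expectation of a randomly mating
hybrid population. Old, stabilized admixture falls below both curves.
Parental individuals may be profiled and land at the corners.

## The synthetic-data generator

The generator is a frequency-drift model, not a coalescent: per locus, an
ancestral derived-allele frequency is drawn from a symmetric U-shaped
beta (shape 0.5) and evolves down each branch of `(((P1, H), P3), O)` by
Balding–Nichols drift (`p' ~ Beta(p(1−c)/c, (1−p)(1−c)/c)`), whose
parameter `c` is the expected single-branch Fst. This preserves shared
ancestral polymorphism across taxa, so zero-gene-flow datasets still
contain ABBA and BABA sites (ILS) with mean D ≈ 0 — exactly the
confound the method must defeat. The admixture pulse replaces the hybrid
frequency with `(1−f)·p_sister + f·p_P3`, followed by `n_generations` of
binomial drift at effective size `ne`.

Default sample sizes (8/12/12/3 for P1/hybrid/P3/outgroup) and the
977-locus matrix mirror a typical ddRAD study of this design. The branch
drift intensities (`c_out = 0.6`, `c_ingroup = 0.15`, `c_p3 = 0.75`,
`c_split = 0.35`, `c_p1 = c_h = 0.25`) were calibrated once so that the
simulated P1-vs-P3 Weir–Cockerham Fst lands near 0.6–0.75 and the
P1-vs-hybrid Fst near 0.2 — the scale separating strongly diverged
congeners from sister populations in comparable viper RAD data — making
simulated D and f magnitudes interpretable against that scale. The
outgroup branch keeps its own polymorphism so the least-frequent-allele
rule is exercised non-trivially.

**Mosaic mode** builds hybrids with known per-copy ancestry. Parental
pools are simulated with `f = 0`; each hybrid haplotype then copies, per
locus, from the sampled P3 pool or the sampled P1 pool. Two design
choices matter here:

- At generation 0, haplotype sources are whole-haplotype and arranged to
  maximise inter-source heterozygosity (an individual carries one
  P3-derived haplotype with probability `2f` for `f ≤ 0.5`), so `f = 0.5`
  produces exact F1s and generation-0 datasets sit exactly on the
  backcross line. Each of `n_generations` rounds of random mating —
  performed in a virtual population of 400 individuals so that inbreeding
  decay of heterozygosity stays negligible over realistic horizons —
  freely recombines ancestry across the unlinked loci, decaying Q12
  toward `2f(1−f)`.
- The non-introgressed source pool is the sampled P1 group itself rather
  than a separately drifted sister lineage. This makes the truth
  guarantee exact: at every diagnostic locus the source pools are fixed,
  so `q` computed from genotypes equals the truth-label proportion with
  no tolerance. The frequency-mode generator retains the distinct sister
  lineage (`c_h`) for realistic D-statistic null and alternative worlds.

What the generator does **not** emulate: physical linkage and
recombination maps (RAD loci are treated as unlinked, matching their use
here), sequencing error and missing data (the complete-matrix filter is
upstream of every analysis), selection, and continuous migration (the
pulse model only). Passing tests on simulated data therefore validate the
estimators under ILS + pulse admixture with clean complete genotypes;
they do not certify behaviour under genotyping error or continuous gene
flow.

## Diversity statistics and Fst

`diversity_table()` reports K (mean observed alleles per locus), rarefied
allelic richness (hypergeometric rarefaction, by default to
`2·min(group size)` gene copies — the largest depth every group supports;
with the smallest group at two individuals that is four copies), private
alleles (a (locus, allele) pair observed in exactly one group), observed
heterozygosity, and unbiased expected heterozygosity
`2p(1−p)·2n/(2n−1)`. Pairwise Fst is the Weir–Cockerham (1984) θ,
multilocus as the ratio of summed variance components — chosen over
AMOVA-style variants because it is the standard, hand-verifiable
estimator for single-level diploid designs; the two agree closely there,
but exact reproduction of AMOVA-based software output is not promised.
θ was verified against an exact-rational-arithmetic hand computation of
the variance components on a three-locus toy (θ = 10/21). Significance
comes from permuting individuals (both alleles move together) between the
two groups; the p-value is the proportion of permuted datasets with
Fst ≥ observed. Note that θ is slightly negative, not zero, for
undifferentiated groups at very small sample sizes — the permutation
p-value, not the sign, carries the inference. A group pair monomorphic at
every locus has undefined θ (`NaN` with a warning).

## Numerical and reproducibility choices

- Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; `pipeline_analyze()` derives its stage seeds
  from one master seed by fixed offsets, and seeds are recorded in the
  JSON metadata. Fixed seed implies byte-identical output files.
- Degenerate inputs are defined, not fatal: zero loci after filtering
  warns; an empty diagnostic panel warns with count 0; D with no
  informative sites is `NaN` and excluded from means with a logged count;
  `f` is an error when the maximal-control excess is non-positive (the
  denominator is meaningless then).
- Coordinates are never arithmetically manipulated: locus ids are opaque
  strings and strand is never complemented (RAD loci are anonymous).

## Problem sizes used by the test suite

The suite validates properties at sizes chosen to make each check
decisive yet quick: exact identities on toys of 1–5 loci; oracle
comparisons on 15–60-locus random instances (20 replicates); estimator
behaviour on 300–1000-locus simulations; the zero-gene-flow control on
five replicate 2000-locus datasets at the default 8/12/12/3 design; and
f-recovery on 2000-locus mosaic datasets (6/6/6/2, five seeds per f in
{0, 0.05, 0.1, 0.2, 0.5}), where the taxon-level f̂ must land within
±0.05 of truth with mean D monotone in f.

## Known limitations

- No block-jackknife Z-scores: with unlinked RAD loci and the
  full-combination averaging design, the bootstrap/control-interval
  machinery replaces genome-window jackknifing; D_FOIL-style partitioned
  tests are out of scope.
- The ANOVA bias test treats correlated tests as exchangeable
  observations (see above).
- f is a minimum estimate and inherits the assumption that the maximal
  control (P3 as P2) saturates the attainable excess.
- Exact reproduction of Arlequin/GENEPOP output is not attempted where
  those tools' estimator variants differ or are undocumented.
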