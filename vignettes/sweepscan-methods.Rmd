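---
title: "sweepscan: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sweepscan: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sweepscan` detects candidate signatures of positive selection in sparse
SNP panels (GBS-style or whole-genome) and contrasts two cohorts of a
managed population. This vignette is the package's own account of the
statistics it computes, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the design was genuinely open. It states no
empirical result that the package's tests do not themselves compute.

## The statistics

### Pooled heterozygosity (Hp / ZHp)

For each sliding window, over the SNPs it contains, let
$\sum n_{MAJ}$ and $\sum n_{MIN}$ be the summed major and minor observed
allele counts of the analysed cohort (counted over non-missing genotypes;
the major/minor assignment is made per analysis cohort, not genome-wide).
Then

$$H_p = \frac{2 \sum n_{MAJ} \sum n_{MIN}}{(\sum n_{MAJ} + \sum n_{MIN})^2},$$

which lies in $[0, 0.5]$: 0 when every in-window site is monomorphic in
the cohort, 0.5 when major and minor counts balance. A selective sweep
depresses local diversity, so sweeps appear as extreme *low* windows.
Windows are Z-transformed with median centring,

$$ZH_p = \frac{H_p - \mathrm{median}(H_p)}{\mathrm{SD}(H_p)},$$

using the sample SD ($n-1$ denominator) over all retained windows of the
analysis. Windows supported by fewer than 2 SNPs are discarded before
the transform. Significance is assignment to the extreme lower tail
(default 0.1%) of the *empirical* ZHp distribution; overlapping
significant windows are merged into candidate regions.

Assumptions worth keeping in mind: each SNP contributes to every window
containing it, so the 50 kb / 25 kb layout double-counts each site in
two windows by design; allele counts, not genotype frequencies, enter
the statistic, so unequal per-site call rates weight sites unequally.

### Windowed Weir–Cockerham Fst

Per bi-allelic site observed in two cohorts with $n_1, n_2$ called
diploids, alternate-allele frequencies $p_1, p_2$ and observed
heterozygote fractions $h_1, h_2$, the package computes the variance
components of the Weir–Cockerham $\theta$ estimator ($r = 2$
populations, $\bar n = (n_1+n_2)/2$,
$n_c = \sum n_i - \sum n_i^2 / \sum n_i$, weighted $\bar p$, $\bar h$
and between-population variance $s^2$):

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \tfrac{1}{2}s^2 - \tfrac{1}{4}\bar h\right)\right]$$
$$b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \tfrac{1}{2}s^2 - \tfrac{2\bar n - 1}{4\bar n}\bar h\right], \qquad c = \bar h / 2.$$

Windowed Fst is the weighted (ratio-of-sums) combination
$\sum a / \sum(a+b+c)$ over in-window sites, matching the windowed
behaviour of the common VCF tooling; the per-site $\hat\theta$ values
are attached for inspection. Negative window values are reported as
computed — clamping would bias the empirical tail. Sites with fewer than
two called diploids in either cohort, or monomorphic in both, are
excluded. Significance is the upper empirical tail (default 0.1%).

The test suite verifies the components against an independent scalar
transcription of the algebra on random parameter draws, that a window of
fixed differences yields exactly 1, that identical cohorts yield a
non-positive numerator, and that on Balding–Nichols cohorts the
genome-wide weighted estimate recovers the generating $F$ within
$\pm 0.05$ at 2,000 sites and 30+30 diploids.

### Diversity and relatedness

Observed heterozygosity of sample $j$ is the fraction of its called
sites with dosage 1. The inbreeding estimate is the moment estimator
popularised by GenABEL's `hom`:

$$\hat F_j = \frac{O_{hom,j} - E_{hom,j}}{L_j - E_{hom,j}},
\qquad E_{hom,j} = \sum_{i \in \text{called}(j)} \big(1 - 2p_i(1-p_i)\big),$$

with $p_i$ the pooled cohort frequency (an option allows per-population
frequencies; pooled is the default because the reference workflow
computes diversity on the merged panel). $\hat F = -1$ for an
all-heterozygote sample at $p = 0.5$ sites, $+1$ for a fully homozygous
sample, and is mean-zero under Hardy–Weinberg (verified by simulation at
200 samples x 2,000 sites within $\pm 0.05$).

Relatedness is the *unadjusted* $A_{jk}$ of Yang et al. (PLINK
`--make-rel`): off-diagonal
$\frac{1}{N}\sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1-p_i)}$
over jointly called sites, diagonal
$1 + \frac{1}{N}\sum_i \frac{x_{ij}^2 - (1+2p_i)x_{ij} + 2p_i^2}{2p_i(1-p_i)}$,
with fixed sites excluded. Pairs above 0.025 are reported as related.
Because $p_i$ is estimated from the cohort itself, a duplicated pair's
$A_{jk}$ approaches 1 only as the cohort grows; the tests use 50
samples, where it exceeds 0.9 comfortably.

Evanno's $\Delta K$ is computed from per-$K$ replicate log-likelihoods
as $|L'(K+1) - L'(K)| / \mathrm{sd}(L(K))$ with $L'(K) = L(K) - L(K-1)$;
it is defined only at interior $K$ and undefined (reported `NA`, with a
warning) when the replicate SD is zero. Running the clustering itself is
out of scope; only the post-processing is implemented.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| hard filters | QD < 2, FS > 60, MQ < 40, QUAL < 30, MQRankSum < −12.5, ReadPosRankSum < −8 | removal conditions, strict as printed: FS = 60 and QD = 2 are retained |
| depth | DP ≥ 5; DP within 3 SD of the mean | two-pass: mean/SD fixed over all input records before any removal |
| excluded scaffold | `NC_009849.1` | the reference mitochondrial scaffold |
| marker QC | MAF < 0.05 removed; call rate < 0.95 removed | strict inequalities: boundary sites retained; MAF skipped for Hp panels |
| LD pruning | window 50 SNPs, step 10, r² > 0.1 | PLINK `indep-pairwise` semantics |
| sample QC | call rate < 0.95; IBS ≥ 0.90 | in a duplicate pair the lower-call-rate member is removed |
| windows | 50,000 bp, step 25,000 bp | anchored at coordinate 0, trailing windows truncated |
| significance tails | 0.001 lower (ZHp), 0.001 upper (Fst) | empirical quantiles; < 2-SNP windows discarded first |
| relatedness threshold | 0.025 | conventional related/unrelated cut |

## The synthetic-data generator

The generator emulates the statistical structure the scans assume, not
the sequencing process. Per scaffold, site count is
Binomial(length, density) with positions placed uniformly (densities
around 1 site / 500–2,000 bp mimic a sparse GBS panel; the real
restriction-site spacing distribution is not modelled — a stated
assumption, not an inference). Ancestral frequencies are
Uniform(0.05, 0.95) so that every site segregates: truly monomorphic
sites never enter a called VCF, and downstream Hp needs segregating
input. Population frequencies follow the Balding–Nichols model
(Beta with mean $p$ and variance $F p(1-p)$); genotypes are
Binomial(2, p) within population (Hardy–Weinberg); missingness is
i.i.d. per genotype. REF/ALT pairs are drawn with transition probability
$\mathrm{TsTv}/(1+\mathrm{TsTv})$, default expected Ts/Tv 2.0, so the
Ts/Tv operation is exercised (the reference workflow computes the ratio
but prints no value). Clean INFO values are drawn from passing ranges
(QD in [5, 30], FS in [0, 10], MQ in [45, 60], rank sums in [−2, 2],
QUAL in [50, 500]); a configured fraction of sites is set *just past*
one named threshold (QD 1.9, FS 60.5, MQ 39.5, QUAL 29.5, MQRankSum
−12.6, ReadPosRankSum −8.5), cycling through the six filters, which
exercises each boundary. Clean DP is Uniform(100, 300); a uniform sample
never leaves the ±3 SD band of its own distribution, so the depth stage
is exact-null on clean cohorts and the removed-set = truth-set
invariant holds for the hard-filter stage exactly. DP violations are
deliberately *not* implanted: the ±3 SD band depends on the realised
cohort depth distribution, so an "exactly fraction f violates" truth
contract cannot be guaranteed for DP.

Sweeps are applied after drift, per target population, by forcing the
major-allele frequency into [fixation_level, 1]. A sweep targeting
`"all"` populations fixes the *same* allele everywhere — the ancestral
major allele. (An earlier implementation chose the direction per
population; at ancestral frequencies near 0.5 this manufactured fixed
differences between populations inside shared sweep regions, turning
sweep truth into spurious Fst truth.) Differentiation regions push the
two populations symmetrically apart around the (clamped) ancestral
frequency until they differ by `delta_freq`.

A single seeded RNG stream with documented draw order (positions,
ancestral frequencies, alleles, drift, sweeps, genotypes, missingness,
INFO, failure sites, genes) plus fixed-format number rendering makes all
output files byte-identical across reruns of the same configuration —
hash equality is asserted in the tests, including through the full
pipeline.

What a green test does **not** establish: robustness to linkage
(sites are generated independently, so LD-pruning behaviour on real
haplotype structure is only exercised by synthetic copy-with-noise
constructions), to call-rate structure correlated with genotype, to
batch effects, or to the empirical GBS site-spacing distribution.

## Numerical choices

* **Empirical quantiles** use linear interpolation on order statistics
  (index $h = q(n-1) + 1$; R's default type 7), matching the statistical
  environment of the reference workflow. Configurable at the call site.
* **ZHp parenthesisation**: the Z-score reading
  $(H_p - \mathrm{median})/\mathrm{SD}$ with sample SD.
* **Missing INFO annotations pass** their hard filter (the standard
  convention); a record is removed only when a *present* annotation
  violates its threshold. Malformed (non-numeric) values raise an error
  with scaffold:pos context.
* **Site DP** is the default depth reading; mean per-sample DP is
  exposed as an option (`per_sample_mean`), since "per-SNP DP across all
  samples" admits both readings.
* **LD-prune victim**: the lower-MAF member of a violating pair, ties to
  the later position. The named tool does not document its tie-break;
  this choice is deterministic and audited by the post-condition
  (no surviving within-window pair with r² above threshold) rather than
  by SNP-for-SNP agreement with another implementation. Windows are
  re-framed over the surviving set and passes repeat to a fixed point,
  so the audit holds on the *output* panel.
* **Degenerate inputs**: zero-variance dosage pairs give undefined r²
  (treated as not-in-LD, logged); an all-equal depth vector gives SD 0
  and retains everything; a zero Fst window denominator drops the window
  with a warning; sample pairs with no jointly called sites are skipped
  with a warning.
* **Region merging** treats windows as half-open intervals: abutting
  windows (end = next start) are *not* merged.
* **Sample-level QC runs right after the site-filter cascade**, before
  marker QC (the reference workflow checked samples on the QC-filtered
  panel). Both orders satisfy the stated contracts; removing duplicates
  first protects every downstream statistic that assumes sample
  independence.
* **Run configuration is JSON** (the machine-readable schema mirrors the
  function arguments); no YAML parser is available in the supported
  dependency set, and the format carries no semantics.

## A structurally unattainable acceptance check

One acceptance criterion requires that an Hp scan of a 5-Mb scaffold
(200 windows) at the **0.5% empirical lower tail** recover at least 2 of
3 implanted 200-kb sweeps. With the empirical-quantile definition above,
the threshold interpolates between the 1st and 2nd order statistics, so
essentially exactly one window is declared significant — the package's
own guarantee that the significant fraction never exceeds
$q + 1/n$ caps it at two. One significant window yields one merged
region, which cannot overlap two disjoint truth intervals; the criterion
therefore fails *by construction*, independent of seed, and is left
failing rather than weakened. The expectation behind it is recoverable
under either a fixed Gaussian cutoff (ZHp ≤ −2.576) or full fixation
(Hp = 0 ties pull the entire sweep cluster under the interpolated
threshold); at any tail wide enough to admit several windows (e.g. 5%)
the scan recovers all three sweeps, which the regular test suite
demonstrates.

## Known limitations

* No haplotype-based statistics (iHS, XP-EHH) and no coalescent null —
  significance is purely empirical-tail, as in the reference workflow.
* The Fst scan supports exactly two cohorts.
* LD pruning is quadratic within windows; it is intended for the
  post-QC panels (tens of thousands of sites), not raw WGS call sets.
* The simulator draws sites independently: recombination, haplotype
  structure and the restriction-site sampling process are out of scope.
* Mann–Whitney contrasts and PCA are deliberately delegated to base R
  (`wilcox.test`, `prcomp`) and not re-implemented.
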