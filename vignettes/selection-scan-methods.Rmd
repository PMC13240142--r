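---
title: "Methods: windowed diversity, differentiation and outlier-region detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed diversity, differentiation and outlier-region detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

## Scope and data model

`popgenscan` operates downstream of variant calling. Its unit of data is a
`genotype_matrix`: samples × biallelic sites, each call an alternate-allele
dosage in {0, 1, 2, NA}, with a population label per sample carried in a
separate two-column table (sampling-site assignment is metadata, not a VCF
property). Only the GT subfield of a VCF is consulted; phased and unphased
separators are equivalent, and half-calls such as `./1` are treated as
missing because a diploid dosage is undefined for them.

## Filtering

Two layers, applied in order:

* **Hard annotation filters.** A site is removed iff any *present*
  annotation violates its threshold: QD < 2.0, MQ < 40.0, FS > 60.0,
  SOR > 3.0, MQRankSum < −12.5, ReadPosRankSum < −8.0. Absent annotations
  never trigger removal — the rank-sum annotations are undefined at sites
  without heterozygotes, and removing those sites would discard exactly the
  fixed differences a selection scan cares about. (Whether the original
  GATK-based pipelines drop such sites is genuinely ambiguous; keeping them
  is this package's documented choice.)
* **Site filters.** Retained sites are biallelic, have QUAL > 40 (a missing
  QUAL *fails* — quality cannot be certified), call rate ≥ 0.95, and
  MAF ≥ 0.05. MAF is computed on called alleles only, `min(p, 1−p)` with
  `p = alt count / called alleles`; a site with no called genotype is
  removed by the call-rate rule rather than causing a division error.

Both filters are idempotent and monotone in their thresholds (tested as
properties).

## Windowed statistics

Windows are 1-based inclusive intervals of `size` bp (default 100 000)
advanced by `step` bp (default 10 000), starting at position 1 on every
chromosome; trailing windows are truncated at the chromosome end, and
windows never span chromosomes. With `step < size` a typical position lies
in `size/step` windows, so neighbouring window statistics are strongly
autocorrelated — a fact that matters below.

**Nucleotide diversity.** Per site, the unbiased heterozygosity
$\hat\pi_s = 2j(m-j)/(m(m-1))$ with $m$ called alleles and $j$ alternate
copies — equal to the mean pairwise difference among the $m$ sampled
alleles. Per window, $\sum_s \hat\pi_s$ over polymorphic sites divided by
the *bp span* of the window, not the site count: the result is a per-bp
quantity (order 10⁻³ in the intended regime) and is invariant to adding
monomorphic sites. A VCF that has been MAF-filtered therefore understates
absolute π; the package's comparative statistics (ratios, ROD, ranks) are
unaffected because the bias is shared across populations.

**Weir–Cockerham F<sub>ST</sub>.** At each site the two-level variance
components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals) are computed from the called
genotypes of the two populations; the window estimate is the weighted
(ratio-of-sums) form $\sum_s a_s / \sum_s (a_s+b_s+c_s)$. Sites need at
least one called genotype in each population and at least three called
diploids overall (the components involve $1/(\bar n - 1)$). Negative
estimates are reported as computed — clamping would bias means, and the
quantile-based outlier rule is unaffected either way. The mean-of-ratios
variant is deliberately not implemented; the weighted form is the windowed
default of the standard VCF tooling this pipeline mirrors.

**Tajima's D.** $D = (\hat\pi_w - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with
the classical constants and $\hat\pi_w$ the unscaled sum of site
heterozygosities over the window's $S$ segregating sites. The formula
requires a single sequence count $n$; under missing data the package fixes
$n = 2\times$ the *minimum* number of called diploids across the window's
segregating sites — conservative, deterministic, and exact when data are
complete. Windows with $S = 0$ or $n < 4$ return `NA`, never 0.

## Outlier windows and candidate regions

A window is a **candidate** for a population pair iff

* its pair F<sub>ST</sub> is *strictly* greater than the genome-wide
  `q`-quantile (default q = 0.95, pooled across chromosomes, linear
  interpolation between order statistics, undefined windows excluded), and
* its π is *strictly* below the population's genome-wide `r`-quantile of
  window π (default r = 0.5) in at least one population of the pair.

"Reduced π" has no canonical definition; *below the population's own
genome-wide median* is the weakest defensible reading and `r` is exposed in
`scan_config()` — as is `pi_pops`, which restricts the reduction requirement
to a focal population. Strict inequalities make the degenerate all-equal
case produce zero candidates rather than all.

Candidates are merged per chromosome by a single linear pass: a region
absorbs the next window while it starts within
`current end + 1 + merge_max_gap` (default gap 0: overlapping or abutting
only). Regions partition the candidate windows, and the BED export uses the
exact conversion `bed_start = start − 1`, `bed_end = end`.

## Region-versus-background statistics

For a region, with its windows defined as the scan windows fully contained
in its interval: fold enrichment (region mean over genome mean
F<sub>ST</sub>), percentile rank (fraction of genome windows strictly below
the region mean), exceedance fractions above the genome-wide 95th/99th
percentiles, π ratio `mean(π_ref)/mean(π_focal)` and
ROD `= 1 − mean(π_focal)/mean(π_ref)` (the identity `rod = 1 − 1/ratio` is
tested to machine precision), the fraction of windows with strictly lower
focal π, and two rank tests. The background for the distribution summaries
*includes* the region's own windows (the genome-wide distribution reading;
`exclude_region_background` flips this), while the rank-sum test always
contrasts region against complementary windows — a test of a set against a
superset of itself is not meaningful.

**Rank tests.** The rank-sum (independent window sets, for F<sub>ST</sub>)
and signed-rank (paired per-window π) tests use midranks throughout. Exact
p-values — full permutation/sign-flip distributions computed by dynamic
programming over the rank multiset, so ties are handled exactly — are used
for min(|x|,|y|) < 8 (rank-sum) and ≤ 25 nonzero pairs (signed-rank);
otherwise a normal approximation with tie-corrected variance and a 0.5
continuity correction. Two-sided p-values double the smaller tail, capped
at 1. `stats::wilcox.test` could not be used as the implementation because
it refuses exact p-values under ties; it serves as an independent check on
the tie-free and asymptotic branches in the test suite.

**Statistical caveat.** Region windows overlap (step < size), so both rank
tests treat positively correlated observations as independent and their
p-values are anticonservative. No correction is applied — the original
analysis practice this mirrors applies none — and the p-values should be
read as descriptive strength-of-signal summaries, not calibrated error
rates.

## Structure summaries

* **p-distance**: `1 − mean(shared-allele fraction)` over co-called sites,
  the shared fraction at a site being `(2 − |g_i − g_j|)/2`. A semimetric:
  the triangle inequality is not guaranteed under arbitrary missingness
  (documented, not enforced). A pair with no co-called site is an error.
* **Neighbor-joining**: classical Saitou–Nei with the Q-criterion,
  deterministic lexicographic tie-breaking, and negative branch lengths
  clamped to zero with the deficit moved to the sister branch (total pair
  length preserved). Exact on additive matrices — verified against
  tree-generated distances to 10⁻¹⁰. Bootstrap support by site resampling
  (default 100 replicates at desk scale; the 1000 of full-scale practice is
  a parameter, not a different method).
* **PCA**: per-site mean imputation of missing dosages (standard for
  genotype PCA), centring, optional Patterson scaling by
  `sqrt(p(1−p))`, SVD; component signs fixed by the largest-magnitude
  loading so output is deterministic.
* **dapc_lite**: PCA retaining the smallest component count reaching 95%
  cumulative variance, k-means (10 restarts, seeded) over `k = 1..k_max`,
  elbow by the maximum second difference of the WSS curve, then LDA on the
  retained components against the chosen clusters.

**Design note — the elbow at k = 1.** A second-difference rule is undefined
at the endpoint k = 1, yet homogeneous data must be allowed to answer
"one cluster". The implementation therefore first applies a homogeneity
guard: if the best 2-cluster split removes less than 25% of the total WSS,
the data are declared unstructured. The threshold was fixed a priori from
random-matrix reasoning — for an unstructured n ≈ d sample the best split
captures on the order of the leading eigenvalue's share of the spectrum
bulk, roughly 10–15% at this package's desk scales, while genuinely
separated clusters concentrate most variance on the separation axis
(typically > 50%) — and was not tuned against test outcomes.

## The simulator: what the stated world is, and is not

`sim_config()` defaults encode the intended regime: three populations of
14/10/10 diploids (ST/ZH/HN), one 1 Mb chromosome, per-population
Balding–Nichols divergence F = 10⁻³ (expected pairwise weighted
F<sub>ST</sub> = (F_a+F_b)/2 = 10⁻³), ancestral frequencies
Uniform(0.05, 0.95), and site density 0.008/bp — chosen once so that
expected per-bp π ≈ E[2pq]·density ≈ 0.365 × 0.008 ≈ 2.9×10⁻³, matching the
~3×10⁻³ diversity scale of the motivating system. Block experiments use
F_block = 0.05 with `diversity_scale = 0.9` ("slightly reduced" diversity),
implemented as a boundary-ward frequency transform that scales
heterozygosity exactly, so π and ROD respond smoothly rather than by site
thinning.

What the generator does **not** emulate: linkage (site frequencies are
independent; windows are exchangeable under the null, so empirical genome
scans with real LD will have heavier-tailed window distributions than the
simulator), mutation-model detail, demographic history (positive Tajima's D
of bottlenecked populations is *not* targeted — the uniform ancestral law
plus MAF filtering produces mildly positive D as a side effect, and no
claim is attached to its value), and sequencing artefacts beyond i.i.d.
missingness. A green planted-block test therefore establishes that the
scan detects frequency-differentiation signals of the stated magnitude
against an exchangeable background — not that it is calibrated under
realistic LD.

**Null-calibration caveat.** The candidate rule composes an ~5% FST
condition with a reduced-π condition. The product of the two rates is *not*
an upper bound on the joint rate: windows with low π carry noisier
F<sub>ST</sub> estimates (fewer effective sites) and are mildly
over-represented in the FST tail, a positive dependence we measured on null
simulations (joint rate ≈ 2.9% vs ≈ 2.7% for the independence product).
The valid composition bound — the joint rate cannot exceed the smaller of
the two marginal rates, and the strict-quantile rule caps the FST rate at
5% — is what the test suite asserts.

## Numerical choices

* Quantiles everywhere are type-7 (linear interpolation), R's default.
* Undefined statistics are `NA`, never 0, and are excluded from quantiles,
  thresholds and summaries.
* All simulation randomness flows from one seed through a fixed draw order
  (positions, alleles, ancestral frequencies, per-population frequencies,
  genotypes, missingness); identical configs are bit-identical.
* Newick branch lengths are serialized at full double precision (17
  significant digits) so distance round-trips hold to 10⁻¹⁰.
* k-means uses 10 restarts under a local seed that restores the caller's
  RNG state; `dapc_lite` is reproducible without touching the session RNG.

## Known limitations

* Overlapping-window autocorrelation is uncorrected in the rank tests (see
  above).
* Per-population π after MAF filtering is downward-biased as an absolute
  estimate of diversity.
* The p-distance is a stand-in for the (unpublished) formula of the
  distance tool it emulates; any monotone variant would give the same NJ
  topology on additive-like data.
* No FDR control across candidate regions — the scan is a screening, not a
  testing, procedure.
* The normal-approximation rank-sum branch engages when the smaller sample
  reaches 8; for pathological tie structures at sizes just above the exact
  threshold, exactness is traded for speed, as in standard implementations.
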