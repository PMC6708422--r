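---
title: "Simulation-calibrated selection scans in a selfing allohexaploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-calibrated selection scans in a selfing allohexaploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(polysweep)
```

## The problem

Genome scans for artificial selection compare a statistic computed along the
genome against a significance threshold. Taking that threshold from the
empirical outlier tail is known to misbehave in structured breeding
populations: every genome has a top 1% of windows whether or not anything
was selected. `polysweep` instead calibrates thresholds by simulation. A
neutral, forward-time model of the population's own demography — here, an
allohexaploid, predominantly self-pollinating wheat breeding population —
is run repeatedly; the scan statistics computed on those neutral replicates
form null distributions, and their upper percentiles become the
significance thresholds applied to the observed data. Windows above
threshold are merged into sweep regions, and unlinked regions are then
tested for mutual linkage disequilibrium (LD), the signature of
simultaneous selection on allele combinations.

Four statistics are implemented from scratch with a common configuration
surface (`scan_config()`):

* **Windowed Fst** — a per-locus population-drift moment statistic,
  `mean((p_j - p)^2) / (p (1 - p))` over the K population frequencies with
  unweighted mean `p`, averaged in sliding windows of 15 SNPs with step 1
  and reported at the center SNP. The underlying model treats each
  population as having drifted independently from a common ancestral
  frequency; the moment form is used rather than a Bayesian fit, and it
  rank-agrees with a Hudson-style two-population estimator (checked in the
  test suite). This is the largest interpretive decision in the package:
  only the drift-model family, not the estimator, is fixed by convention.
* **iHS** — log-ratio of the integrated extended haplotype homozygosity
  (EHH) of the two alleles at a core SNP. EHH is the probability that two
  random carrier haplotypes are identical from the core out to a site;
  it is integrated over genetic distance (trapezoid rule) until it falls
  below a truncation cutoff. Chip data carry no ancestral-state
  information, so alleles are polarized by the major allele in the combined
  sample and scores are standardized to mean 0, variance 1 within
  minor-allele-frequency bins (width 0.025, sparse bins merged downward).
  Cores whose EHH is still above the cutoff at a chromosome end, or whose
  integration would cross an inter-SNP gap larger than 2 cM, are missing.
* **nSL** — the same log-ratio idea with tract lengths measured in numbers
  of consecutive segregating sites instead of map distance: for a carrier
  pair, SL is the size of the maximal interval containing the core on which
  the pair is identical, averaged over pairs. No genetic map is needed and
  no edge rule applies.
* **XPCLR** — a cross-population composite likelihood ratio on a regular
  physical grid (1 Mb spacing, 1 cM windows, at most 50 SNPs per window,
  LD-pruned at r² > 0.95). Given the reference-population frequency `p` of
  a SNP at recombination distance `r` from the grid point, the objective
  population's frequency is modelled as Gaussian drift around `p` with
  genome-wide variance `w p (1 - p)`; under a sweep of intensity `s`, a
  lineage escapes the hitchhiking with probability
  `c = 1 - exp(-(r/s) log(2 Ne))`, giving a two-component mixture with
  means `c p` (allele off the sweeping background) and `c p + (1 - c)`
  (on it), component sd `c` times the drift sd, and boundary mass lumped at
  0 and 1. The composite likelihood of the observed allele counts is
  maximized over a fixed logarithmic grid of 20 intensities from 1e-5 to
  0.1; the neutral model is the `c = 1` member of the same family, so the
  likelihood-ratio score is non-negative by construction. Each mixture
  component is integrated against the binomial with Gauss–Legendre nodes
  mapped onto the component's own ±8σ support, which keeps narrow drift
  densities resolvable.

iHS and nSL are two-sided: thresholds are derived from, and applied to,
absolute standardized scores. Fst and XPCLR are one-sided on the raw
value. Thresholds use the empirical quantile with linear interpolation
between order statistics (`stats::quantile` type 7); significance is
strict (`>`).

## The simulator

`popsim` is an individual-based, forward-time simulator of diploid and
allopolyploid populations:

* each offspring is produced by selfing a uniform parent with probability
  `1 - s_out`, otherwise by crossing two distinct uniform parents;
* each transmitted chromosome is a recombinant with Poisson(`lambda_xo`)
  crossovers placed uniformly on the inter-locus boundaries, no
  interference, random start phase;
* every transmitted allele flips with probability `mu` (symmetric biallelic
  mutation, recurrent mutation allowed — a two-allele model matches
  SNP-chip data downstream);
* inheritance is strictly disomic: alleles never move between the A, B and
  D subgenomes (asserted by tagging in the test suite);
* new taxa are founded from a single individual and grown by geometric
  doubling to the target size; polyploidization samples one gamete from
  each parent population and chromosome-doubles the amphiploid, so the
  founder is fully homozygous within every subgenome and fixed differences
  between parents become homoeologous differences.

Loci are evenly spaced; with `lambda_xo = 1` a chromosome is 100 cM long,
locus `i` of `L` sits at `100 i / L` cM, and 1 cM corresponds to 1 Mb.
This is the simplest embedding consistent with a Poisson(1) crossover
count, and it gives the XPCLR grid a defined physical scale.

`initialize_population(..., "stationary")` replaces a multi-thousand-
generation burn-in: per-locus frequencies are drawn from the symmetric
mutation–drift stationary density Beta(θ, θ) with `θ = 4 Ne mu` and
`Ne = N / (1 + F)`, `F = (1 - s_out) / (1 + s_out)` the selfing-equilibrium
inbreeding, and genotypes are sampled at that equilibrium inbreeding. At
`mu = 0` the limit (every locus fixed at 0 or 1 with equal probability) is
used. Loci start in linkage equilibrium, so LD must build up during the
simulated generations; scenario schedules leave a few hundred generations
for this.

## The wheat scenario

`run_wheat_scenario()` executes the breeding-population demography: a
common ancestor; founding of the A, B and D genome taxa; an AB tetraploid;
a hexaploid (A, B, D) population founded from a tetraploid × D amphiploid;
then a random split into Pre70 and Post70 cohorts which differentiate with
restricted gene flow until the genome-wide Fst reaches 0.13, tracked each
generation (`drift_until_fst()`). Array genotyping is emulated by
`ascertain_snp_panel()`: loci are kept only if polymorphic within a
19-individual discovery panel drawn from the Post70 cohort, which shifts
the folded site-frequency spectrum toward common alleles exactly as chip
ascertainment does. An optional tetraploid component of the discovery
panel is available but off by default.

Two profiles are shipped:

* **full** — the literal cluster-scale schedule: N = 500 ancestor, seven
  chromosomes of 100,000 loci, `mu = 1e-5`, taxa at generations 6,000 /
  6,200 / 11,000, tetraploid at 12,000, the 482-individual hexaploid at
  18,000, run to 25,000; cohorts 259/223; 9,858 ascertained SNPs.
* **desk** — the package's down-scaled study condition, used by the test
  suite: N = 200, one chromosome of 2,000 loci per subgenome, stationary
  initialization, a compressed event schedule (about 600 simulated
  generations in total), cohorts 108/92, 1,500 ascertained SNPs.

Two desk-profile choices deserve explanation:

* `mu = 5e-4` preserves the full profile's mutation density per
  centimorgan (1e-5 × 1,000 loci/cM = 1e-2 per cM per meiosis; at 20
  loci/cM this requires 5e-4 per locus). Per-cM density is what the
  haplotype statistics see. Under this scaling the simulated observed
  heterozygosity of the hexaploid cohorts comes out near the low
  percentages expected for material released after roughly six to eight
  generations of selfing (`selfing_het()` gives the analytic ladder
  1/2^(g−1): 3.125% at g = 6, 0.78% at g = 8).
* the 1,500-SNP panel (≈5 panel SNPs per cM) matches the per-cM marker
  density of a 90K-style array panel on a hexaploid map. Panel density
  matters for iHS: haplotype identity is evaluated at panel SNPs only, and
  at desk scale the recent selfing ancestry leaves many near-clonal
  haplotype pairs, so a sparse panel would leave EHH above its truncation
  cutoff across whole chromosomes and few cores evaluable.

For the same reason the pipeline applies the single-population statistics
iHS and nSL to the pooled population by default (`scan_dataset()`): the
pooled sample has twice the haplotype depth of a single cohort, and a
whole-population run of these statistics is part of the published design
as well. With the desk profile this leaves a few hundred evaluable iHS
cores per replicate; statistics with no evaluable neutral score at all are
skipped by `run_pipeline()` and recorded in its `skipped` field rather
than aborting the run.

**Migration during differentiation.** The gene flow between the
differentiating cohorts is "restricted" but its magnitude is not part of
the recorded design, so it is a configurable parameter with default
`m = 1e-4` per offspring. The default was chosen from the two-deme
equilibrium: with cohort effective sizes near 130 under 3.3% outcrossing,
the island-model equilibrium Fst is `1 / (16 Ne m + 1)`, which at
`m = 5e-3` is ≈0.09 — *below* the 0.13 stopping target, i.e. the target
would be unreachable. At `m = 1e-4` the equilibrium is ≈0.84 and the
expected stopping time at the real cohort sizes is in the mid-30s of
generations, consistent with the tracked-differentiation behaviour of the
full-scale experiment. Every scenario output records the value used.

**The genome-wide Fst tracker.** `drift_until_fst()` starts from a known
split, so it anchors the estimator at the ancestral state: with `pi` the
pooled frequencies at entry, it tracks
`sum mean_j (p_j - pi)^2 / sum pi (1 - pi)` over the loci polymorphic at
the split. This is exactly the population-drift coefficient of the
underlying model, with expectation `c(t) = 1 - exp(-t / 2Ne)`, so the
stopping rule obeys the textbook drift law `t ≈ -2 Ne log(1 - target)` —
a property the test suite verifies at N = 50 to within a fraction of a
generation. A pooled-pair estimator without the anchor
(`fst_genomewide()`, kept for settings where no ancestral state is known)
saturates below `c` because the pooled heterozygosity in its denominator
itself shrinks as the demes drift; the per-locus scan statistic keeps the
`1/K` moment form. The three serve different purposes and the package
does not pretend they are the same estimator.

## Outcrossing calibration

`fit_outcrossing_rate()` reproduces the two-pass protocol for matching the
simulated LD decay to an empirical target: a coarse grid from 0.01 to 0.10
in steps of 0.01, then a fine pass at 0.001 over the bracketing interval
(the coarse argmin and its better neighbour). The objective is the mean
squared difference between binned mean-r² curves over 0–50 cM.

The calibration simulations (`calibration_params()`) use a single
population of 300 individuals with eight chromosomes of 300 loci, run 250
generations from stationarity, with loci below 5% minor-allele frequency
dropped before the curve is computed (the empirical target comes from
ascertained chip SNPs, which are common by construction). These choices
are driven by the error budget: all chromosomes share one pedigree, so the
replicate-to-replicate variance of mean r² is dominated by the pedigree
and shrinks only with replicates and population size, not with more loci.
At this design, four replicates per coarse point and fourteen per fine
point recover a generating rate of 0.05 to within ±0.005, which the test
suite checks end to end.

## Region calling and inter-region LD

Significant points are merged into a single signature when they are
adjacent on a chromosome *and* their contributing SNPs are in strong LD —
operationalized as mean inter-point r² above the 99th percentile of
background LD (r² between SNPs on different chromosomes), the same cut
used by the inter-region analysis; the published panel value of that
percentile, 0.161, is the default constant when no panel is supplied.
Tables from different statistics and population contrasts are combined by
transitive interval union (`combine_scans()`), which is idempotent and
order-independent.

The inter-region criterion (`interregion_ld()`): a SNP's inter-region LD
is its *median* Hill–Robertson r² against the other region's SNPs (a
max-based rule would be dominated by exactly the outliers the analysis is
supposed to exclude); SNPs more than 3 raw median absolute deviations
above the region median are excluded as not following the general
pattern; the pair is "in LD" iff a strict majority of retained SNPs on
*both* sides exceeds the background cut; the reported value is the highest
r² among retained SNP pairs. Regions with fewer than five SNPs are
ineligible. All three numeric choices (median summary, 3×MAD, strict
majority) are configurable through `ld_config()`. For inbred material r²
should be computed on one haplotype per homozygous individual; the
simulator's populations are essentially homozygous so both rows are kept,
and heterozygous chip calls in empirical data are better treated as
missing.

`ld_cluster()` builds the graph of in-LD region pairs on different
chromosomes and reports connected components with the mean of the
reported pairwise r² values. The packaged 17×17 inter-region r² table
(13 sweep regions plus the *Ppd-D1*, *Rht-B1*, *Vrn-B1* and *Psy-A1*
genes) is transcribed as printed, including asymmetric and missing cells;
`mean_offdiag()` averages all non-missing off-diagonal cells — the
printed table is not symmetric, and averaging the printed cells (rather
than unique unordered pairs) is the convention that reproduces the
published mean of 0.35.

## What the desk-scale tests do and do not show

The desk profile demonstrates that the machinery is calibrated: on a
held-out neutral replicate, P99 thresholds flag about 1% of evaluation
points (binomial-band check in the test suite), the drift law holds,
ascertainment shifts the frequency spectrum, and the parameter-recovery
loop closes. One qualification is structural: the binomial band holds for
the statistics with a within-replicate normalization (iHS and nSL are
standardized per replicate; XPCLR estimates its drift variance per
replicate) but not for windowed Fst, whose whole genome-wide level shifts
between desk replicates — the realized differentiation at the stopping
generation varies by a few percent, and a three-chromosome genome gives
the level only about three independent genealogical components. Every
window of a replicate moves together, so single-replicate exceedance
counts for Fst are overdispersed relative to a binomial at desk scale; at
full scale (21 chromosomes, per-generation Fst increments forty times
smaller relative to the target) the shift shrinks by an order of
magnitude. This is also why the published design holds Fst to the
stricter 99.9th percentile. It does not reproduce full-scale summary
values that depend on absolute population sizes and generation counts —
nucleotide-level diversity, the exact LD-decay curve, or per-state
differentiation times — and the observed heterozygosity of simulated data
is sensitive to how heterozygosity is defined and sampled, which is why it
is exposed as `observed_heterozygosity()` but not asserted against any
fixed value. Power to *detect* selection is out of scope: the simulator is
strictly neutral, as the calibration design requires.

## Known limitations

* Polysomic inheritance, gene conversion and crossover interference are
  not modelled; subgenomes are strictly disomic.
* The Fst scan uses a moment estimator of the population-drift model, not
  a Bayesian posterior; scans that rank windows are insensitive to this,
  but absolute per-locus values differ from an MCMC fit.
* The XPCLR selection-intensity grid is fixed and coarse by design;
  scores are comparable across windows, not estimates of `s`.
* VCF input assumes biallelic SNPs; multiallelic records are rejected
  rather than split.
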