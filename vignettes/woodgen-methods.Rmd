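---
title: "Simulating and analysing spatial genetic structure in a nestbox population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing spatial genetic structure in a nestbox population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

woodgen studies how dispersal, immigration and population turnover shape the
spatial genetic structure of a continuously monitored nestbox bird
population. Because the interesting quantities (isolation by distance,
kin clustering, temporal renewal of structure, immigrant/local
differentiation, inbreeding) are all estimated from noisy pairwise
statistics, the package couples every analysis to a spatially explicit
forward simulator, so that each estimator and each qualitative claim can be
validated by parameter recovery on data whose truth is known.

This vignette explains the model behind the simulator, the estimators, the
numerical choices, and what passing the package's tests does and does not
say about real data.

## The simulated population

`run_simulation()` iterates an annual cycle over a fixed map of nestboxes
(`build_landscape()` places them by jittered-grid sampling inside a circular
woodland and rescales so the maximum pairwise box distance equals the
configured extent, 4 km by default):

1. **Breeding.** Every box holding one male and one female fledges a
   Poisson-distributed brood (`clutch_size_mean`, default 6.8).
2. **Extra-pair paternity.** With probability `epp_rate` (default 0.08, a
   mid-range value for open-nesting passerines) an offspring's genetic sire
   is a random male breeding within `epp_radius_m` of the natal box; the
   social sire remains the box mate. Pedigree records store both.
3. **Survival and box retention.** Adults survive with probability
   `adult_survival` (default 0.5, typical of small temperate passerines and
   giving a realized generation time close to 2 years) and keep their box.
4. **Natal dispersal.** Each recruit (binomial thinning of the brood at
   `recruit_prob`) draws a distance from a sex-specific log-normal kernel
   (medians 700 m for males and 1050 m for females: a 1.5-fold,
   roughly 300 m female bias, both medians below 1 km) and a uniform
   direction, then settles at the nearest active box with a free slot for
   its sex; ties go to the lowest box id. A target point outside the
   woodland is an emigration event and the recruit is lost
   (`edge_behaviour = "emigrate"`), which is what an open study site
   actually observes; without it, long draws pile up on edge boxes and the
   realized kernel medians are badly compressed.
5. **Immigration.** Each remaining vacancy is filled with probability
   `immigration_fill` by an immigrant: an adult of unknown age and origin
   whose haplotypes are drawn from an external allele-frequency pool.

The defaults (`adult_survival = 0.5`, `recruit_prob = 0.10`,
`immigration_fill = 0.95`) were calibrated once so that about half of the
breeding adults each year are immigrants, a typical figure for long-running
nestbox studies of small woodland passerines; the calibration is checked,
not re-tuned, by the tests.

**Genetics.** Biallelic SNPs sit on `n_autosomes` autosomes plus one Z
chromosome. Transmission is Mendelian with recombination: crossover counts
per chromosome are Poisson with mean equal to the map length in Morgans
(2 cM/Mb by default), positions uniform, no interference. Sex chromosomes
follow the ZW system: sons receive a recombined paternal Z and their
mother's single Z unchanged; daughters receive only a recombined paternal
Z. The W carries no analysed loci and is not modelled. Two census
identities follow and are tested exactly: with equal sex numbers,
two-thirds of all Z copies reside in males, and in long neutral runs the
Z-to-autosome diversity ratio approaches 3/4 (the Z effective population
size is 3/4 of the autosomal one).

**Founders and immigrants.** Founder allele frequencies are drawn from a
Beta distribution restricted to [0.05, 0.95], emulating an ascertained SNP
chip. The immigrant pool is a Balding–Nichols perturbation of the founder
frequencies. One subtlety: a Balding–Nichols draw at parameter $F$ measured
against the *unperturbed* founder pool realizes a pairwise Hudson $F_{ST}$
of $F/2$, because only one branch drifts. The configuration parameter
`immigrant_divergence_fst` is therefore defined as the *realized*
founder–immigrant $F_{ST}$ and the internal draw uses $2F$
(`immigrant_pool_freqs()`). The default (0.001) reflects an immigrant pool
drawn from a continuous surrounding population: genetically almost
indistinguishable, which is exactly the regime in which a random-forest
classifier achieves only modest accuracy.

**What the simulator does not emulate.** Habitat heterogeneity,
phenotype-dependent dispersal, mate choice, age-dependent survival and
fecundity, genotyping error, and linkage disequilibrium in the founder and
immigrant pools (founder haplotypes are drawn site-independently, so
LD in the simulation arises only from admixture, drift and co-ancestry).
Consequently, tests passing on simulated data validate estimator
implementations and the demographic mechanism, not the full complexity of a
real SNP-chip dataset.

## Estimators

**QC** (`apply_qc()`) keeps loci with call rate above 95%, minor allele
frequency above 0.05 and Hardy–Weinberg exact-test p above 0.001. The HWE
test (`hwe_exact_p()`) is the two-sided conditional exact test without
mid-p, evaluated on all samples by default (a founders-only flag exists
because monitored populations mix cohorts); on the Z it uses males only,
and allele frequencies everywhere count copies (two per diploid call, one
per female Z call). **LD pruning** (`ld_prune()`) greedily drops the later
member of any pair with genotype $r^2 > 0.2$ inside 50 kb windows advanced
by 50 loci.

**Identity by descent** (`mom_ibd()`) is the frequency-based
method-of-moments estimator: observed IBS0/IBS1/IBS2 pair counts are
combined with their expectations under IBD states 0/1/2 to solve for
$P(\mathrm{IBD}=k)$; the probabilities are clamped to the simplex and
renormalised, and $\hat\pi = P_2 + P_1/2$. Loci with MAF < 0.1 are excluded
first (rare variants destabilise the moments). Allele frequencies come from
the analysis sample itself. Clamping leaves a positive noise floor in
$\hat\pi$ that shrinks with marker count — the reported `pi_raw` column is
the unclamped estimate, unbiased around zero for unrelated pairs — and this
floor, not zero, is the natural baseline of every decay curve at a given
marker density.

**Kinship** (`king_robust()`) is
$\hat\phi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N^{(a)}_{Aa} + N^{(b)}_{Aa})$,
robust to allele-frequency misspecification and negative for pairs drawn
from diverged pools. Degrees (`classify_degree()`) use the standard
powers-of-one-half cutoffs (first degree above 0.177, and so on).

**Runs of homozygosity** (`detect_roh()`) follow the scanning-window
design of diploid SNP toolchains: 50-SNP windows tolerate one heterozygous
and five missing calls; a SNP is a candidate when at least 5% of windows
spanning it are compatible; candidate runs must hold 100 SNPs, span 1 Mb,
average at most 50 kb per SNP and contain no 1 Mb gap. These defaults
assume SNP-chip marker density (one marker per ≲25 kb); at sparser
densities the density filter rejects genuine runs, so the desk-scale
presets are not a substrate for ROH and the tests build denser fixtures.
ROH calling refuses MAF-filtered or LD-pruned input unless overridden,
since both filters remove exactly the information homozygous runs carry.
On offspring of simulated full-sib matings the detected genome fraction in
ROH recovers the pedigree inbreeding coefficient $F = 1/4$.

**Z relatedness for pairs involving females.** Two dialects are
implemented deliberately (`z_pair_ibd()`). The copy-aware moment estimator
(`z_relatedness()`) treats the female Z as the single copy it is; on that
scale close cross-sex kin are extremely similar on the Z (a son carries his
mother's entire Z, so a mother–son pair has relatedness near 1). The
`plink_diploid` dialect codes female Z calls as duplicated homozygous
diploid genotypes and runs the ordinary diploid estimator — the convention
of mainstream diploid toolchains. Under that convention, relatedness in
pairs involving females is compressed toward a kinship-independent constant,
which is why classical chip-based analyses see a clear Z
isolation-by-distance signal only in male–male pairs. The package treats
the copy-aware estimator as the principled measurement and the diploid
dialect as the reproduction of what published toolchains report; the
mechanism-recovery tests use the dialect because the qualitative pattern
they check is defined by it.

**Decay curves and spline fits.** `decay_curve()` bins pair relatedness by
distance (500 m bins to 4 km by default, matching the granularity at which
neighbourhood effects are discussed for a 4 km woodland) with a cluster
bootstrap that resamples *individuals* and weights each pair by the product
of its members' multiplicities — pairwise data are multi-membership data,
and pair-level resampling would be anticonservative. `stratified_fit()`
replaces a Bayesian GAMM with a penalized B-spline regression of
relatedness on distance per immigration pair type; the reported $\beta$ is
the average first derivative of the fitted smooth evaluated *at the
observed pair distances* (density weighting; a uniform grid would let the
sparse far tail of the distance distribution dominate the average), with a
95% CI from the same individual-level cluster bootstrap implemented as
weighted refits. Both a per-km and a per-SD (standardized) $\beta$ are
reported since published effect sizes are printed on an unstated scale.

**Temporal renewal.** `select_areas()` anchors the two most distant boxes
(ties toward the lexicographically smallest id pair) and takes the 50
nearest boxes around each; convex-hull area (shoelace) standardises box
density between the areas. `lag_curve()` groups within-area pairs by birth
cohort gap — area membership uses the *natal* box, because the analysis
concerns birth cohorts, so immigrants never qualify — and compares them to
a baseline: the mean relatedness of cross-area pairs born the same year,
pooled over years with at least 10 such pairs. The crossing lag is the
smallest lag at which the curve is statistically indistinguishable from
baseline, requiring both the lag's own bin and the pooled forward window of
the next five cohort gaps to be non-elevated; the two-sided per-bin rule
alone is dominated by bootstrap CI width (it reports 0 at low power and is
blocked by single noisy late bins at high power). Renewal of the
population's structure is complete when the slower of the two areas has
crossed.

**Immigrant classification.** `classify_immigrants()` undersamples the
majority class to balance, fits the genotype PCA on the full balanced
sample (mirroring common published practice; a leakage-safe per-split PCA
is available and off by default, with a logged message), and feeds the
first 15 components to random forests: repeated balanced 70/30 splits for
the accuracy distribution, a 50-forest ensemble whose proximity matrices
are averaged and embedded by classical MDS, out-of-bag error, and a
randomized-label null (`null_baseline()`, one forest per permutation
repeat) that brackets chance at 50% balanced accuracy. Prediction ties
break toward "local". `extreme_subsets()` picks the most distinct
immigrants on MDS axis 1 and locals on MDS axis 2 (sign oriented toward
each group's centroid) and reports the maximum within-subset kinship as a
screen against selecting families.

**Differentiation.** `fst_per_snp()` implements the two-group
Weir–Cockerham (1984) variance components exactly, keeps negative
per-locus estimates, and aggregates windows (50 kb tiles, non-overlapping
by default as in the common windowed-scan dialect) and the global value as
ratios of sums. A copy-aware Hudson estimator (`hudson_fst()`) serves as a
cross-check. Because selecting classifier-extreme subsets conditions on
genetic distinctness, the subset $F_{ST}$ is mechanically at least the
all-birds value; the tests assert exactly that inequality rather than any
significance claim.

## Numerical and design choices

- **Seeding.** One master seed drives the whole simulation stream; runs
  are bit-reproducible, and `replay()` reports are byte-identical for a
  fixed seed and configuration.
- **Settlement ties** go to the lowest box id; anchor-distance ties to the
  smallest id pair: all order-dependent steps are deterministic.
- **Degenerate inputs.** Population collapse returns an object flagged
  `extinct` at the failing year; an empty post-QC locus set is flagged, not
  an error; zero KING denominators and monomorphic-in-both-groups loci are
  NA with flags; collinear area hulls warn and return NA density.
- **Problem sizes.** The `desk` preset (1019 boxes, 20 years, 5000 + 500
  SNPs, up to 1000 genotyped breeders) runs the full `replay()` in a few
  minutes on one core. The mechanism-recovery experiments in the test
  suite use 5000 + 800 SNPs and ~1800 genotyped breeders from a 12-year
  study window of an 18-year run; the neutral-drift ratio uses the
  `neutral` preset (24 breeders, 40 non-overlapping generations, 3000
  loci, 20 replicates), whose map length is inflated to 10 cM/Mb so loci
  decorrelate and the drift ratio concentrates. The `paper_like` preset
  (~2600 genotyped, 10,000 SNPs) is provided for users with more time.
- **Generation time** is measured from the realized pedigree (mean
  parent–offspring birth-year gap, immigrant parents excluded for lack of a
  birth year), about 1.9 years under the defaults; lags in years are
  converted to generations with it.

## Known limitations

- Founder and immigrant haplotypes carry no background LD, so LD-pruning
  retention rates on simulated data are optimistic relative to real chips.
- The ROH caller needs chip-density markers; desk-scale marker counts are
  too sparse for meaningful ROH summaries.
- The clamped $\hat\pi$ noise floor makes absolute relatedness levels
  density-dependent; only contrasts (between strata, lags, or distances)
  transfer across marker counts.
- The plink-diploid Z dialect reproduces a toolchain convention, not a
  biological quantity; conclusions about female-line Z structure should use
  the copy-aware estimator.
- The spline $\beta$ is a summary of a smooth, not a parametric slope; its
  bootstrap CI reflects individual resampling only, not model selection.
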