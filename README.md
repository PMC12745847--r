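# woodgen

Spatial population genetics of a continuously monitored nestbox songbird
population: a spatially explicit forward simulator plus the full analysis
stack that such monitoring data support.

## The scientific problem

In a large, continuous woodland population of a vagile songbird, limited
natal dispersal keeps close kin spatially clustered, producing a fine-scale
isolation-by-distance pattern: pairwise identity by descent (IBD,
$\hat\pi$) declines with the distance between breeding sites, most steeply
when first-degree relatives are included, and more steeply on the Z
chromosome among males (females disperse ~1.5x further, and the Z spends
two-thirds of its history in males, with effective size $3N_e/4$). Because
annual turnover is high — roughly half of breeders each year are immigrants
from the surrounding landscape — the genetic basis of this structure is
continually renewed: birds born in the same area become as unrelated as
birds from opposite ends of the wood within a few generations. Immigrants
are nearly indistinguishable from locals genome-wide (F_ST of order
10⁻³–10⁻⁴), yet carry enough subtle signal for a random-forest classifier
on genomic principal components to beat chance, and both groups are
essentially outbred (few, short runs of homozygosity).

None of these claims is desk-reproducible from the original chip data, so
woodgen replaces the data with a forward simulator whose demography
(nestbox occupancy, survival, sex-biased dispersal kernels, immigration,
ZW inheritance with recombination, extra-pair paternity) is calibrated to
the study system, and validates every estimator against brute-force oracles
and every qualitative claim by parameter recovery across replicate
simulations.

Core estimators, all implemented here and oracle-checked: PLINK-style
method-of-moments IBD ($\hat\pi = P_2 + P_1/2$ from IBS counts),
KING-robust kinship
$\hat\phi = (N_{Aa,Aa} - 2N_{AA,aa})/(N^{(a)}_{Aa}+N^{(b)}_{Aa})$, the
Hardy–Weinberg conditional exact test, greedy 50 kb/r²>0.2 LD pruning,
scanning-window ROH calling, two-group Weir–Cockerham F_ST with
ratio-of-sums windows, penalized-spline IBD-on-distance fits with
individual-level cluster bootstrap, and a balanced random-forest ensemble
with averaged proximity, MDS embedding and a randomized-label null.

## A worked example

```r
library(woodgen)
cfg <- sim_preset("desk", n_boxes = 300L, occupancy = 0.4,
                  n_autosomal_snps = 3000L, n_z_snps = 600L,
                  n_years = 16L, max_genotyped = 400, seed = 42L)
rep <- replay(cfg, classifier = classifier_config(n_repeats = 10, n_forests = 10),
              n_boot = 100, areas_k = 40, verbose = FALSE)
print(rep)
#> Pipeline replay report
#>   genotyped breeders: 400; immigrant fraction 0.51; generation time 1.94 y
#>   relatedness-on-distance beta (per km):
#>     immigrant-immigrant  -0.0007
#>     local-immigrant      -0.0006
#>     local-local          -0.0017
#>   classifier accuracy 64.8%, null balanced 50.7%
#>   global F_ST (immigrant vs local) 1.20e-03
print(rep$curves$all)
#> Relatedness decay curve [all]
#>   bin_lo bin_hi  mid    mean      lo      hi n_pairs
#> 1      0    500  250 0.03072 0.02764 0.03391    4432
#> 2    500   1000  750 0.03052 0.02835 0.03254   11015
#> 3   1000   1500 1250 0.02811 0.02665 0.02975   15750
#> ...
#> 8   3500   4000 3750 0.02634 0.02397 0.02879    2059
```

Reading the output: the simulated wood settles at ~51% immigrant breeders
and a generation time of 1.9 years. Mean IBD declines with breeding
distance (the decay-curve bins, with cluster-bootstrap CIs), the
penalized-spline slope is steepest for local–local pairs (−0.0017 IBD/km
versus −0.0007 for immigrant pairs: locals carry the kin-clustering
signal), the classifier separates immigrants from locals well above its
randomized-label null (64.8% vs 50.7%) even though genome-wide F_ST is only
1.2 × 10⁻³, and the absolute IBD level (~0.03) is the clamped-estimator
noise floor at 3000 markers, which is why contrasts rather than levels are
the meaningful quantities.

The simulator is also usable on its own (`run_simulation()`,
`export_simulation()` writing VCF/PLINK/CSV), as are the analysis stages on
user-supplied genotypes read with `read_genotypes()`. A thin CLI wraps the
pipeline: `inst/cli/woodgen replay --config cfg.yaml --out dir/ --seed 1`.

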