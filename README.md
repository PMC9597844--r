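# msatpower

How many individuals per population are enough? For endangered or rare
species — sedentary marine invertebrates are the motivating case — genetic
monitoring often has to work with fewer than 20 samples per site, and every
quantity of a microsatellite survey inherits that limitation: allele counts
and rarefied allelic richness, heterozygosities, F-statistics, and the
power of tests for population differentiation. `msatpower` is an R package
for quantifying those sample-size effects on diploid microsatellite data,
combining the standard estimators with three purpose-built simulators and
two experiment pipelines.

## What it computes

**Within-population diversity** (`diversity_summary`,
`summarize_population`): number of alleles *A*, rarefied allelic richness
*A*<sub>R</sub>(g) = Σ<sub>i</sub> [1 − C(N−N<sub>i</sub>, g)/C(N, g)]
(hypergeometric expectation at a standardized gene-copy size *g*),
effective alleles *A*<sub>E</sub> = 1/Σp², *H*<sub>E</sub> = 1 − Σp², the
unbiased *uH*<sub>E</sub> = 2N/(2N−1)·*H*<sub>E</sub>, *H*<sub>O</sub>,
and *F*<sub>IS</sub> = 1 − *H*<sub>O</sub>/*H*<sub>E</sub>, each reported
per locus and as mean ± SE over loci.

**Between-population differentiation** (`wc_theta`, `gst_hedrick`,
`bootstrap_ci`, `exact_genic_test`, `fisher_combine`, `narum_adjust`,
`pairwise_differentiation`): the Weir–Cockerham θ from summed variance
components; Hedrick's G′<sub>ST</sub> = G<sub>ST</sub>(k−1+H<sub>S</sub>) /
[(k−1)(1−H<sub>S</sub>)] with Nei–Chesser small-sample corrections;
percentile bootstrap CIs (resampling loci); Monte-Carlo exact genic tests
on allele-by-population tables with fixed margins; Fisher's method across
loci with the conventional 10⁻⁴ per-locus floor; and Narum-adjusted
significance for pairwise batteries.

**Simulators and pipelines**: a forward-time bottleneck simulator with
overlapping generations, hard 20-year lifespan and monoecious mating
without selfing (`run_scenario`); a drift-only divergence simulator with
the closed-form oracle F<sub>ST</sub>(t) = 1 − (1 − 1/2N<sub>e</sub>)ᵗ
(`drift_populations`, `expected_fst`); a symmetric finite-island simulator
with stepwise mutation (`island_model_sim`); subsampling curves of allelic
richness versus sample size (`subsample_richness`); and power grids over
sample size × divergence or sample size × N<sub>e</sub> × migration rate
(`power_drift`, `power_island`). A synthetic-data generator
(`generate_baseline`, `generate_null_metapopulation`) emulates an
8-locus / 84-allele limpet panel with mean H<sub>E</sub> ≈ 0.62 so every
pipeline is testable without external data. Genepop reading/writing
(`read_genepop`, `write_genepop`) handles 2- and 3-digit encodings.

## Worked example

```r
library(msatpower)

baseline <- generate_baseline(synthetic_spec(), seed = 11)
ds <- generate_null_metapopulation(baseline, n_pops = 4,
                                   sizes = c(10, 12, 9, 14), seed = 12)

diversity_summary(ds)
#> Within-population diversity (mean ± SE over loci), rarefaction g = 18 gene copies
#>
#>  population           A         A_R         A_E         H_E         H_O        uH_E         F_IS
#>      pop_01 4.62 ± 0.53 4.51 ± 0.51 2.88 ± 0.46 0.60 ± 0.05 0.61 ± 0.08 0.63 ± 0.05  0.01 ± 0.07
#>      pop_02 5.12 ± 0.52 4.68 ± 0.44 2.68 ± 0.23 0.61 ± 0.03 0.60 ± 0.07 0.63 ± 0.04  0.02 ± 0.07
#>      pop_03 3.75 ± 0.25 3.75 ± 0.25 2.21 ± 0.20 0.52 ± 0.05 0.60 ± 0.07 0.55 ± 0.06 -0.15 ± 0.05
#>      pop_04 4.88 ± 0.40 4.39 ± 0.32 2.57 ± 0.23 0.59 ± 0.04 0.62 ± 0.06 0.61 ± 0.04 -0.03 ± 0.06

wc_theta(ds)$theta
#> [1] 0.002052

ci <- bootstrap_ci(ds, "theta", reps = 1000, seed = 13)
c(ci$lower, ci$upper)
#> [1] -0.0147  0.0246

tst <- diff_test(ds, method = "exact_mc", mc_reps = 10000, seed = 14)
c(chisq = tst$chisq, df = tst$df, p = tst$p)
#>  chisq     df      p
#>  17.74  16.00  0.340
```

The four populations were all drawn from the same baseline pool, and the
numbers say so: rarefied richness and heterozygosity are homogeneous
across sites (per-site *F*<sub>IS</sub> hovers near zero, with the small
negative values expected from 9–14-individual samples), the multilocus θ
is indistinguishable from zero with a bootstrap interval spanning it, and
the Fisher-combined exact test across the 8 loci (χ² = 17.7, 16 df,
p = 0.34) finds no differentiation — the correct null behaviour.

A power question then looks like:

```r
power_drift(baseline, t_grid = c(0, 20), S_grid = c(10, 30),
            n_pops = 14, replicates = 200, seed = 1)
```

which reports, per cell, the rejection fraction together with the realized
mean θ and G′<sub>ST</sub>, so power can be read against realized
divergence rather than the generative drift duration.

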