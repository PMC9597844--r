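---
title: "Models and methods: sample-size effects on microsatellite diversity and differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sample-size effects on microsatellite diversity and differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatpower)
```

## The scientific problem

For endangered or rare species — marine invertebrates in particular — it is
often impossible to sample more than a handful of individuals per
population. Every downstream quantity of a microsatellite survey is then
estimated from noisy allele frequencies: within-population diversity
(allele counts, allelic richness, heterozygosities), between-population
differentiation ($\theta$, $G'_{ST}$), and the verdict of significance
tests for population structure. `msatpower` bundles the estimators, the
tests and three simulators so that, for a marker panel like the one it
emulates (8 dinucleotide-motif microsatellite loci, 84 alleles, moderate
gene diversity), one can ask directly: *how small a sample still yields
reliable answers?*

## Estimators

Within-population metrics follow the standard definitions: gene diversity
$H_E = 1 - \sum_i p_i^2$; Nei's small-sample correction
$uH_E = \frac{2N}{2N-1} H_E$; effective alleles $A_E = 1/\sum_i p_i^2$;
rarefied allelic richness as the hypergeometric expectation
$A_R(g) = \sum_i [1 - \binom{N-N_i}{g}/\binom{N}{g}]$ evaluated in log
space (stable for thousands of gene copies); and
$F_{IS} = 1 - H_O/H_E$ per locus, undefined at monomorphic loci. Two
choices here were genuinely open:

* **$F_{IS}$ definition.** We use $1 - H_O/H_E$ rather than the
  Weir–Cockerham within-population $f$. It reproduces the expected sign
  behaviour (small negative values — a slight heterozygote excess — on
  small samples from declining populations), at the cost of a known
  $\approx -1/(2S-1)$ small-sample bias, visible in our own HWE
  calibration tests at $S \le 15$.
* **Rarefaction size $g$.** Default: the smallest per-locus gene-copy
  count across the populations being compared, after removing missing
  calls — standard rarefaction practice, overridable everywhere.
* **Summary shape.** Population summaries report mean ± SE over loci with
  SE computed from the sample standard deviation over $L$ loci divided by
  $\sqrt{L}$.

Between-population differentiation uses the Weir–Cockerham (1984) moment
estimator: per-allele, per-locus variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals), with the multilocus estimate the *ratio of summed
components* — never the mean of per-locus ratios. Negative estimates are
preserved. Hedrick's standardized measure is
$G'_{ST} = G_{ST}\,\frac{k-1+H_S}{(k-1)(1-H_S)}$; the dataset-level
version applies the Nei–Chesser small-sample corrections to $H_S$ and
$H_T$ (harmonic-mean sample size, observed-heterozygosity terms), while a
raw frequency-parameter version is kept for closed-form checks.

### Significance machinery

Per-locus tests operate on the allele-by-population table of gene copies
(genic tests, matching the convention that power simulators in this field
test allele counts, not genotypes). Two variants are provided: a Pearson
chi-square with asymptotic p, and a Monte-Carlo exact test that generates
tables with fixed margins via the Patefield algorithm
(`stats::r2dtable`) and uses probability ordering with the estimator
$p = (1 + \#\{P_{sim} \le P_{obs}\})/(R+1)$, so $p$ is never zero.
Per-locus p-values are combined by Fisher's method with each $p_l$ floored
at $10^{-4}$ — the floor prevents one locus from dominating the global
$\chi^2 = -2\sum_l \ln p_l$ ($2L$ df). Pairwise batteries adjust the
significance level by the Narum rule $\alpha/\sum_{i=1}^k 1/i$.

**Bootstrap confidence intervals.** The resampling unit is *loci*
(percentile interval over resampled per-locus variance components, or
per-locus $H_S$/$H_T$). We originally implemented resampling individuals
within populations, but that scheme is measurably upward-biased near zero
differentiation: the duplication noise it injects mimics extra
between-population variance, shifting the whole bootstrap distribution by
roughly $+1/(2S)$, and on panmictic 14-population null data its 95%
intervals essentially never contained zero. Locus resampling — the
convention of the multilocus F-statistic literature — restores the
expected behaviour (null intervals contain zero in about 95% of runs);
individual resampling remains available as an explicit option with its
bias documented.

## The forward bottleneck simulator

An isolated, constant-size, monoecious population with overlapping
generations: hard maximum lifespan of 20 years (ages 0–19, uniform random
starting ages, i.e. 100% generation overlap), maturity at 2 years, random
mating without selfing, no mutation or migration. Scenarios start at
$N_e = 500$ and either stay there or drop to 100 or 50 after year 1
(five- and ten-fold bottlenecks), for 100 simulated years. Census size is
equated with $N_e$ since scenarios are parameterized directly in $N_e$.

The yearly event order needed one deliberate choice. Ages increment;
**parents for the year's recruits are drawn (uniformly, two distinct
parents per recruit, polygamy across recruits allowed) from the mature
pool *before* mortality**; individuals at the age limit die; excess
survivors are culled uniformly in a bottleneck year; recruits (age 0,
unable to reproduce in their birth year) restore the target size.
Drawing parents pre-mortality means a cohort that dies this year can
still parent the recruits that replace it — the natural reading of a
spawn-then-die year for a broadcast spawner — and it makes two useful
limits exact: a population entirely at the age limit is replaced in one
step, and setting longevity 1 / maturity 0 collapses the model to
non-overlapping Wright–Fisher generations. In that special case the
simulated gene-diversity decay matches $H_0 (1 - \frac{1}{2N})^t$ within
5% at $N = 50$, $t = 20$ over 2000 replicates (the exact no-selfing decay
factor is $1 - 1/(2N+1)$, a 0.2% difference at this size — far inside the
tolerance). Replicate $r$ runs on a seed derived from `(seed, r)`, so
results are reproducible regardless of execution order.

## Divergence simulators and power

**Drift-only divergence.** Every population starts from the same baseline
frequency pool and drifts independently: $t$ rounds of multinomial
resampling of $2N_e$ gene copies per locus ($N_e = 1000$ by default), then
$S$ diploids per population are sampled under HWE. The drift expectation
$F_{ST}(t) = 1 - (1 - \frac{1}{2N_e})^t$ is the oracle: realized mean
multilocus $\theta$ matches it within 10% across $t \in \{20, 50, 102\}$
in our tests. Divergence levels quoted on a $G'_{ST}$-like scale are
mapped to drift durations by inverting this closed form; since Hedrick's
standardization multiplies a small $\theta$ by
$\frac{k-1+H_S}{(k-1)(1-H_S)}$ ($\approx 2.7$ for 14 populations at
$H_S \approx 0.6$), the realized mean $G'_{ST}$ of each power-grid cell is
computed and reported alongside the generative knob rather than assumed
equal to it.

**Finite-island model.** Ten demes of $N_e$ diploids exchange migrants
symmetrically (each gene copy immigrates with probability $m$ from a
uniformly chosen other deme — gamete-level migration, so the
$n/(n-1)$ finite-island correction is emergent, not imposed), with strict
stepwise mutation (rate $\mu = 5\times10^{-4}$ by default, $\pm 1$ repeat
unit, reflecting at 5 and 60 repeats — dinucleotide-microsatellite
behaviour). Default burn-in is $10 N_e$ generations — an order of
magnitude beyond the $F_{ST}$ equilibration time scale
$\approx 1/(1/(2N_e) + 2m)$ for the parameter grid of interest — with
optional monitoring that flags a still-trending $F_{ST}$. At
$N_e = 100$, $m = 0.01$, $\mu \approx 0$ the realized equilibrium
$\theta$ sits within 25% of the classical
$1/(1 + 4 N_e m (n/(n-1))^2) = 0.168$ (our 200-replicate mean is
$\approx 0.185$; the classical formula is itself a small-$m$
approximation).

**Detection criterion.** Both power pipelines call a dataset
differentiated when the Fisher-combined per-locus genic p (floored at
$10^{-4}$) falls below $\alpha = 0.05$ — one criterion for both the
chi-square and exact variants keeps the two power surfaces comparable.
The exact variant defaults to 2000 Monte-Carlo tables per locus inside
power loops: a p-resolution of $5\times10^{-4}$ is ample for decisions at
$\alpha = 0.05$, and the conventional 100,000 tables remain the default
for one-shot analyses (`exact_genic_test`). At zero divergence both
variants reject at $\approx \alpha$ (the exact variant by construction;
the asymptotic chi-square runs conservative on sparse tables at
$S \approx 10$, which is worth remembering when reading its small-sample
power).

## The synthetic baseline

The generator emulates the structure of the empirical limpet panel the
package was designed around: 8 loci whose allele counts sum to 84 (at
least 5 per locus so every locus is informative), allele sizes on a
`min_size + motif × k` ladder with per-locus motif lengths of 2 bp (one
4 bp locus) and size ranges matching the panel (within 3-digit Genepop
encoding), 14 populations with right-skewed sample sizes on 8–16 (mean
≈ 9.4), and mean gene diversity 0.62 with per-locus targets spread in
[0.4, 0.8]. Frequencies are drawn as symmetric-Dirichlet weights and then
*tempered* — raised to a power chosen by bisection — until each locus
hits its gene-diversity target exactly; tempering is monotone in the
exponent, so the tuning is deterministic given the seed.

What the generator does *not* emulate: linkage between loci, null
alleles, genotyping error, spatial structure among the 14 sites, or the
exact (unpublished) per-locus allele-count breakdown of the empirical
panel — the composition is drawn randomly and recorded. Tests passing on
these synthetic data therefore validate the estimators and the
simulation machinery, not any claim about a particular wild population.

## Numerical choices and degenerate inputs

Rarefaction uses `lchoose` differences (no overflow to at least
$N = 2000$ gene copies, with $\binom{a}{b} = 0$ for $a < b$ handled by
$e^{-\infty}$). Monomorphic loci: excluded from $\theta$'s component sums,
`NA` for $F_{IS}$, flagged-undefined for $G'_{ST}$ when $H_T = 0$.
Missing genotypes are dropped locus-wise (pairwise-complete), and
gene-copy counts are tracked per locus. Half-missing calls are treated as
fully missing. Monte-Carlo p-values use the $+1$ correction so the
$10^{-4}$ floor is meaningful. Table-probability comparisons use an
additive $10^{-9}$ log-space tolerance to absorb floating-point ties.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run at deliberately moderate
sizes chosen so every tolerance is stated in binomial standard errors or
relative error and remains valid: 500 replicates for the α-calibration
and drift-expectation checks, 2000 replicates for the Wright–Fisher decay
check, 10 forward-simulation replicates per bottleneck scenario with
100-resample subsampling curves, 200-replicate power cells, and a
400-generation island-model burn-in at $N_e = 100$ (ten times the
equilibration time scale). The full-fidelity configuration of the
emulated study — 1000 replicates everywhere, 10,000-replicate bootstraps,
100,000-table exact tests — is reachable through the same functions by
changing the corresponding arguments.

## Known limitations

* The life-cycle model is monoecy without selfing with a hard age limit —
  a deliberate proxy for protandric sequential hermaphroditism; real
  male-biased sex ratios would lower $N_e$ further and accelerate
  diversity loss relative to these simulations.
* The island model has non-overlapping generations; only the bottleneck
  simulator overlaps them.
* No mutation in the drift-only and bottleneck simulators (closed allele
  sets), so they understate diversity over very long horizons.
* The asymptotic chi-square genic test is conservative for very small
  samples; prefer the exact variant when $S \lesssim 15$.
* Power under the synthetic baseline is specific to its 84-allele,
  $H_E \approx 0.62$ spectrum; more polymorphic panels detect the same
  divergence with fewer individuals.
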