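---
title: "Methods: simulating and evaluating E&R studies under truncating selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating E&R studies under truncating selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`erpower` simulates replicated evolve-and-resequence (E&R) experiments
on a quantitative trait under truncating selection and evaluates their
statistical power to identify the causative loci. This vignette
documents the model, the default parameters, the realism and the known
limitations of the synthetic data generators, and the numerical choices
made in the statistics. All quantitative statements below are either
analytic or verified by the package's test suite; none are new
empirical claims.

# The model

## Founders

A study starts from a pool of `n` founder haplotypes over biallelic
loci (0 = ancestral, 1 = derived allele) placed uniformly at random on
chromosomes of configurable physical length. Derived-allele counts are
drawn from a truncated neutral-like site frequency spectrum with weight
proportional to $i^{-\gamma}$ for count $i$ (default $\gamma = 1$, the
standard neutral spectrum, so singletons are twice as common as
doubletons), restricted to counts whose frequency lies in
$[\mathrm{maf}, 1 - \mathrm{maf}]$ (default `maf_min = 0.05`). Loci are
generated in linkage equilibrium; see *Generator realism* below.

## Recombination

Recombination rates are piecewise constant on windows (default 100 kb)
in cM/Mb. By default the supplied rates are halved (`halve = TRUE`) to
represent a hermaphroditic or both-sex-recombining organism calibrated
against systems where only one sex recombines. Gamete formation follows
the Haldane model: for each chromosome the number of crossovers is
Poisson with mean equal to the chromosome's genetic length in Morgans,
crossover positions are uniform on the genetic scale, there is no
interference, and chromosomes assort independently. The two-locus
recombinant fraction therefore follows Haldane's map function
$r = (1 - e^{-2d})/2$ at genetic distance $d$; the test suite checks
this at $d = 0.1$ Morgan to within $\pm 0.005$.

## Trait architecture

A trait is defined by `n_qtn` loci (default 100) drawn uniformly among
loci whose pool frequency lies within `freq_bounds` (default
$[0.05, 0.95]$). Effect sizes $a$ are gamma distributed (default shape
0.42, scale 1) with a random sign, or equal in the `effect_equal()`
mode. The genotypic value is purely additive,
$G = \sum_j d_j a_j$ with dosage $d_j \in \{0, 1, 2\}$, and the
phenotype is $P = G + e$, $e \sim N(0, V_e)$ with

$$V_e = V_{G,0}\,\frac{1 - h^2}{h^2}, \qquad
  V_{G,0} = \sum_j 2 p_j (1 - p_j) a_j^2,$$

so the configured narrow-sense heritability $h^2$ (default 1) holds in
the founder pool under linkage equilibrium. In the E&R simulations
$V_{G,0}$ is computed from pool frequencies; in the GWAS benchmark
$V_e$ is instead calibrated against the realized genotypic variance of
the largest cohort, so the target $h^2$ holds in the cohort actually
analyzed. $V_e$ is fixed at the start and *not* re-calibrated as
selection erodes genotypic variance — realized heritability therefore
declines over generations, which is the biologically correct behavior.

## Selection regimes and the life cycle

A selection regime is a schedule of selected fractions
$p_0, \dots, p_{T-1}$. Constant regimes keep $p$ fixed; linear regimes
interpolate so that both endpoints are attained:
$p_g = p_{\text{start}} + (p_{\text{end}} - p_{\text{start}})\,g/(T-1)$.
A decreasing fraction means *increasing* selection strength. The
default grid at step 0.1 contains 9 constant regimes and the 36
increasing-strength linear regimes (all ordered pairs), including the
90% → 20% schedule. The linear 90% → 10% regime selects the same total
number of individuals as constant 50% up to rounding (matched-effort
design; asserted within $T/2$ individuals).

Each generation: phenotypes are computed for all $N$ diploids, the top
$\lfloor N p_g + 0.5\rfloor$ (at least 2, phenotype ties broken at
random) are retained, and $N$ offspring are produced by drawing two
distinct parents uniformly with replacement from the selected set and
combining one gamete from each. There is no mutation, so allele counts
are absorbing at 0 and $2N$; heterozygosity under pure drift decays as
$(1 - 1/2N)^t$ (verified at $N = 100$, $t = 50$).

All replicates of an experiment are founded from a *single* shared
base population of $N$ diploids sampled with replacement from the
founder pool, mirroring the common experimental practice of splitting
one ancestral population; the recorded generation-0 counts are the base
counts used by the test statistic (see *Calibration* below).

## Scoring: the CMH test

Each locus is scored with the Cochran–Mantel–Haenszel chi-square over
$k$ 2×2 tables (one per replicate): rows = (base, evolved), columns =
(major, minor allele in the base). With stratum cells
$(a_r, b_r; c_r, d_r)$, row sums $R_{1r}, R_{2r}$, column sums
$C_{1r}, C_{2r}$ and total $n_r$,

$$T = \frac{\left(\sum_r a_r - E_r\right)^2}{\sum_r V_r},\quad
E_r = \frac{R_{1r} C_{1r}}{n_r},\quad
V_r = \frac{R_{1r} R_{2r} C_{1r} C_{2r}}{n_r^2 (n_r - 1)},$$

with 1 df and **no continuity correction** (the correction is
anti-conservative to invert and unnecessary at Pool-Seq depths; the
implementation is cross-checked against
`stats::mantelhaen.test(correct = FALSE)` to 10⁻¹²). Strata with a zero
margin contribute nothing; a locus with $\sum_r V_r = 0$ gets $p = 1$.
The statistic is invariant to swapping the column labels in all strata.
Optional Pool-Seq sequencing noise replaces exact counts by
$\mathrm{Binomial}(\text{coverage}, f)$ draws per sample.

## Power evaluation

Loci are ranked by $-\log_{10} p$; QTNs are positives. The ROC curve
sweeps thresholds over distinct score values, so tied scores form
diagonal segments; the partial AUC integrates TPR over
FPR $\in [0, f_{\max}]$ (default 0.01) by the trapezoid rule with
linear interpolation at $f_{\max}$. A perfect ranking attains
pAUC $= f_{\max}$; fully tied scores give the chance value
$f_{\max}^2/2$. Curves from repetitions (independent QTN sets) are
combined by vertical averaging on a common FPR grid; regime
comparisons use the *mean of per-repetition pAUCs*, which is exact,
rather than the pAUC of the averaged curve, which carries a small
grid-resolution bias.

Diagnostics: a non-causative locus is a *hitchhiker* when its
frequency change has the same nonzero sign in all $k$ replicates,
*drift-like* when the majority direction holds in 40–60% of
replicates, otherwise *inconsistent*. Fixation times of QTNs are
polarized to the selected allele (derived if $a > 0$, ancestral
otherwise) and reported at the recording resolution (`record_every`);
unfixed trajectories are censored and excluded from class means.

## GWAS benchmark

Nested cohorts are drawn from the same founder pool: the largest
samples $2 \times \text{size}$ haplotypes with replacement; each
smaller cohort subsamples the next larger one without replacement, so
segregating sites are nested and power comparisons across sizes are
not confounded by different site sets. The scan is per-locus ordinary
least squares of phenotype on dosage with an intercept; the $t$-test
of zero slope equals the Pearson correlation test (cross-checked
against `stats::cor.test` to 10⁻¹⁰). Monomorphic loci are flagged
non-testable with $p = 1$.

# Calibration of the pipeline null

With a shared founded base, the generation-0 counts *are* the base
sample, so founding noise cancels from the base-vs-evolved contrast
and only post-founding drift remains. For a locus at frequency $p$,
after $t$ generations of pure drift in $N$ diploids, the variance of
the observed count difference between the evolved sample (depth $2N$)
and the base is approximately $2N p q\, t$ (drift accumulates $pq/2N$
per generation on the frequency scale, times $(2N)^2$). The CMH null
variance for two exact-count samples of depth $2N$ each is
$\sum_r V_r \approx 4N p q$ per stratum. The statistic is therefore
calibrated — empirical false positive rate equal to the nominal
$\alpha$ — precisely at $t = 2$ drift generations, anticonservative
beyond, and conservative below. The acceptance suite verifies
FPR $= 0.01 \pm$ binomial CI at $t = 2$ over 10⁴ loci. Practical
reading: at realistic experimental durations the exact-count CMH test
is anticonservative for *hypothesis testing*, which is why the package
evaluates designs by *ranking* (ROC/pAUC) — rank-based power is
unaffected by the common inflation of the statistic.

# Generator realism and limitations

* **Linkage equilibrium founders.** Real founder haplotypes carry LD
  blocks; LE placement understates hitchhiking and overstates mapping
  resolution. The regime *comparisons* (which regime yields more
  hitchhikers, later fixation, higher pAUC) are directional statements
  that survive this simplification; absolute pAUC values do not
  transfer to real genomes.
* **Scaled problem sizes.** The package's own validation runs use a
  2 × 5 Mb genome with 10⁴ loci, $N = 500$, $k = 5$, 40 generations and
  50 QTNs — a deliberate desk-scale choice. Defaults
  (`er_config()`: $N = 1000$, 100 QTNs, 90 generations, $k = 10$,
  10 repetitions) reflect the canonical design for real studies.
* **No mutation, no migration, discrete generations, hermaphroditic
  random mating with no selfing.** Standard Wright–Fisher-with-
  selection simplifications.
* **Additivity.** No dominance or epistasis; $h^2$ refers to the
  additive model.
* **Pool-Seq model.** Binomial sampling per locus and sample,
  independent across loci; no reference bias, mapping error or
  overdispersion.
* **Fixation timing resolution.** Fixation generations are known only
  up to `record_every` (default 10).
* **Low-recombination windows.** Loci in windows below
  `min_recomb_rate` can be masked from scoring, mirroring the common
  practice of excluding low-recombination regions where association
  signals smear.

# Numerical choices

* Haplotypes are stored as an integer matrix (loci × 2N) with
  column-contiguous haplotypes; gamete formation is implemented in
  C++ (Rcpp) using R's RNG, so `set.seed()` gives bit-identical
  trajectories.
* Seeds for repetition $i$ are derived as `derive_seed(seed, i, 1)`
  (architecture), `(seed, i, 2)` (experiment) and `(seed, i, 3)`
  (sequencing noise), so different regimes run at the same master seed
  share QTN sets and founding randomness — regime comparisons are
  paired.
* $-\log_{10} p$ scores clamp $p$ at the smallest positive double to
  avoid infinities.
* Phenotype ties at the truncation threshold are broken uniformly at
  random, which matters only for tiny $N$ or $V_e = 0$ with few QTNs.
* Run artifacts (score tables, JSON summary) are listed in a manifest
  with MD5 digests; re-running with the same seed reproduces the
  digests bit-for-bit.

# Reproducing the headline comparison

The test suite (`tests/testthat/test-acceptance.R`) verifies, on the
scaled synthetic genome, that mean pAUC orders
increasing(0.9→0.1) > constant(0.5) > decreasing(0.1→0.9) with
one-sided paired rank tests at $p < 0.05$ per gap, and that the
increasing regime yields fewer hitchhikers and later strong-effect
fixation than the constant regime. `scripts/acceptance.R` writes the
package's acceptance measurement (the analytic perfect-classifier pAUC)
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
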