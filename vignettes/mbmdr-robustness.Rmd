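---
title: "Quantitative MB-MDR: model, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MB-MDR: model, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(qmbmdr)
```

## The screening problem

Epistasis screening asks whether the joint genotype at a pair of SNPs is
associated with a quantitative trait beyond anything either locus does on
its own. For two bi-allelic SNPs coded as minor-allele counts 0/1/2 there
are nine multilocus genotype cells, so a naive per-pair ANOVA spreads the
signal over eight degrees of freedom and loses power for the patterned
interactions one actually expects. Model-Based Multifactor Dimensionality
Reduction (MB-MDR) is a two-step remedy:

1. **Dimensionality reduction (labeling).** Each of the nine cells is
   compared against the pooled remaining individuals with a two-group
   association test. Cells significantly *above* the rest (two-sided
   p ≤ `alphaLabel`, default 0.1) are labeled **H**, significantly below
   **L**, everything else — including every cell with fewer than `minCell`
   (default 10) individuals on either side of its comparison — **O**.
2. **Step-2 test.** The pooled H individuals are tested against all others,
   likewise the pooled L individuals, and the pair's evidence is the
   *maximum* of the two squared test statistics (a two-group ANOVA F
   scale). A branch with no labeled cells, or whose pooled group violates
   the minimum-size rule, contributes 0, so a fully "O" pair scores 0 and
   never breaks the ranking.

Because labeling is data-driven, the step-2 statistic has no tractable null
distribution; `runMbmdr()` calibrates it by permutation. For each of B
(default 999) shuffles of the trait across individuals the *entire*
analysis — labeling included — is redone, and the Westfall–Young step-down
maxT construction converts the per-permutation statistics into adjusted
p-values: hypotheses are ordered by decreasing observed statistic, each rank
is compared against the permutation distribution of successive maxima over
itself and all lower ranks, counts use the +1 convention (so adjusted
p-values live in `[1/(B+1), 1]`), and running maxima enforce step-down
monotonicity. This controls the familywise error rate across all
`m(m-1)/2` pairs under subset pivotality, at any panel size.

### Internal association tests

Both tests compare a group A of size $n_A$ against its complement B:

* **Student (pooled variance)**: $t = (\bar y_A - \bar y_B) /
  \sqrt{s_p^2 (1/n_A + 1/n_B)}$ with $n_A + n_B - 2$ df. Since the two
  groups always partition the full cohort, every labeling test in a
  complete-data scan has the same df ($n - 2$), which is why the null
  cell-versus-rest statistics should track $F(1, n-2)$.
* **Welch (unequal variance)**: unpooled standard error with
  Welch–Satterthwaite df. The cell-versus-rest design is extremely
  unbalanced (a cell of a few dozen against several hundred), which drives
  the Welch df toward the small group's and makes the combination
  conservative — the phenomenon the study harness quantifies.

A comparison in which both group variances vanish is reported as
`valid = FALSE` with F = 0 and p = 1 rather than an error, so degenerate
cells never abort a genome scan.

### Trait transformations

`traitTransform()` implements the pre-analysis options: identity, natural
log, standardization, pooled average-tie ranks, and rank-to-normality
(normal quantiles of percentile ranks). Two exactness properties are worth
stating because the test suite asserts them literally:

* standardization is affine, so every t statistic, label, step-2 value and
  adjusted p-value is *identical* to the raw-trait scan;
* ranks depend only on the ordering, so the rank and rank-to-normality
  pipelines are invariant under any strictly increasing pre-transform
  (e.g. a prior log).

Two conventions were genuinely open. The log arm must accept traits with
non-positive values (normal residuals produce them); we shift by
$-\min(x) + 1$ before taking logs, the only choice that keeps the arm
defined without discarding data, and a monotone one, so it cannot change
rank-based results. For rank-to-normality we use the symmetric plotting
position $(r - 0.5)/n$, which never reaches 0 or 1 and therefore never
produces infinities; the van der Waerden position $r/(n+1)$ is exposed as
an option.

## The two-locus simulator

`simulateReplicate()` emulates the study conditions: 500 unrelated
individuals; two causal SNPs at minor allele frequency 0.5; 98 noise SNPs
with MAFs drawn from U(0.05, 0.5); all SNPs in Hardy–Weinberg equilibrium
(minor-allele counts Binomial(2, MAF)) and linkage equilibrium (independent
columns). Genetic architecture is the checkerboard ("M170") pattern: the
trait is elevated if and only if an individual is heterozygous at exactly
one causal locus. With both MAFs at 0.5 the high cells have total
probability 0.5 in every row and column of the 3×3 grid, so the model has
no marginal effects — pure epistasis.

Residuals come from one of three families, each with an equal- and an
unequal-variance variant drawn fresh per replicate:

| scenario | homoscedastic | heteroscedastic |
|---|---|---|
| normal | common variance = mean of 9 draws from U(1, 10) | 9 cell variances ~ U(1, 10) |
| chi-square | central, df = 2 (mean 2, variance 4) | df ~ U(2, 10), ncp = 10 − df: every cell mean 10, variance 2df + 4ncp ∈ (20, 36) |
| Student t | t(3), variance 3 | target variances v ~ U(3, 10), imposed by scaling t(3) by $\sqrt{v/3}$ |

The heteroscedastic t case deserves a note: a U(3, 10) heterogeneity
specification could in principle parameterize either per-cell degrees of
freedom or per-cell variances. We implement variances — 3 is exactly the
variance of t(3), making U(3, 10) a natural variance range, whereas
df > 3 would *shrink* all variances below the homoscedastic case rather
than disperse them — and expose the choice through the scenario object
should a df reading be wanted. All df draws are continuous (the
noncentral chi-square is defined for real df).

### Signal injection and calibration

The epistatic signal is an additive shift $\beta$ on the high cells, the
only mechanism that yields a prescribed "fraction of phenotypic variance"
interpretation uniformly across all three residual families. With
high-cell probability $p$ and expected residual variance $\sigma^2$,

$$\beta = \sqrt{\frac{g^2}{1 - g^2}\,\frac{\sigma^2}{p(1-p)}},$$

so that $\mathrm{Var}(\beta \cdot \mathbb 1_{high}) / \mathrm{Var}(y) = g^2$
(`calibrateEffect()`). For $\sigma^2$ we use the unweighted mean of the
nine cell variances — the same averaging the homoscedastic normal scenario
uses to flatten its variances. Under heteroscedasticity the
HWE-probability-weighted mean would differ slightly, so the realized $g^2$
deviates from nominal by a correspondingly small amount there; the
homoscedastic settings, where the two coincide, are the ones used for the
quantitative calibration checks.

Per-replicate reproducibility comes from deterministic stream derivation:
a 32-bit mix of (master seed, setting id, replicate index) seeds each
replicate, and a further salt seeds its permutation stream, so any
replicate can be regenerated in isolation, bit-identically.

### What the simulator does not emulate

Linkage disequilibrium, related individuals, missing genotypes, main
effects, covariates, and any penetrance pattern other than the
checkerboard. Passing tests therefore demonstrate error control and power
under idealized panels of independent SNPs with complete data; they say
nothing about LD-induced subset-pivotality violations, which real panels
do exhibit.

## Numerical and implementation choices

* The per-pair scan (cell accumulation, labeling, step-2, over all
  permutations) runs in compiled code; the exported R functions
  `partitionPair()`, `labelCells()` and `step2Statistic()` are the
  readable reference path, and the test suite asserts exact agreement
  between the two on random instances, plus agreement with an independent
  loop-written oracle including the step-down adjustment.
* Labeling in the compiled path compares $t^2$ against
  $t^2_{1-\alpha/2}(df)$ instead of computing a p-value per test — the
  same decision, without a quantile/CDF evaluation per cell. For Welch the
  critical value depends on the data through df, so the kernel brackets it
  between the df = `minCell` − 1 and df = n − 2 values and evaluates the
  exact quantile only inside the bracket.
* Ties among observed statistics are broken by the stable lexicographic
  pair order; permutation comparisons use ≥; p-values use the +1
  numerator/denominator convention.
* `alphaLabel` defaults to 0.1 (a software convention of the method's
  lineage, not derivable from first principles) and is exposed in
  `analysisConfig()`.
* The minimum-size rule is enforced on *both* sides of every comparison —
  cell vs rest, H vs rest, L vs rest — reading "each group" literally.
* The false-positive rate of an effect setting is reported familywise (the
  fraction of replicates with at least one significant non-causal pair),
  which matches the magnitude of a nominal-level check; the per-replicate
  mean count is available via `fpMode = "mean_count"`.

## Study sizes

The full grid (3 distributions × 2 variance regimes × 3 effect sizes × 2
tests × 5 transforms, 1000 replicates of 500 individuals and 100 SNPs,
B = 999) is an overnight batch; `runStudy(preset = "paper")` reproduces it
with per-cell checkpointing. The package's own tests and the bundled
acceptance script use the desk preset — B = 199 permutations and 100–200
replicates per cell, with 25-SNP panels for null-rate estimation (maxT
correction makes the familywise rate insensitive to panel size) — chosen
so a complete verification pass runs on a laptop in minutes while keeping
binomial standard errors small enough for three-sigma comparisons against
the full-scale reference values.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(g2 = 0.1, scenario = "chi_square", seed = 42)
d <- simulateReplicate(cfg, replicate = 1)
y <- traitTransform(d$trait, "rtn")
res <- runMbmdr(d$genotypes, y,
                analysisConfig(nPermutations = 199, seed = 42))
significantPairs(res)
```

The causal pair occupies columns 1–2 of every simulated genotype matrix,
so `pairResults(res)[1, ]` is the causal pair's row.

## Known limitations

Binary traits (score-test MB-MDR), adjustment for main effects or
covariates, 3+ locus models, bootstrap-based multiple testing and the
gammaMAXT approximation are out of scope. FWER control rests on subset
pivotality of the permutation null; with strong LD or multiple true
signals that assumption can fail, and this package makes no claim there.
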