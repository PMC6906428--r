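---
title: "Logistic seed-filling analysis: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logistic seed-filling analysis: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedfillr)
```

## The model

Dry matter accumulation in a developing maize seed follows a sigmoid
trajectory. seedfillr describes the 50-seed dry weight $w$ (g) at $t$ days
after pollination (DAP) with the three-parameter logistic

$$w(t) = \frac{k}{1 + a e^{-bt}},$$

where $k$ is the asymptotic final dry weight (g), $b$ (per DAP) the relative
filling rate, and $a$ a dimensionless shape parameter placing the curve in
time. The instantaneous filling rate is the derivative

$$v(t) = \frac{k\,a\,b\,e^{-bt}}{(1 + a e^{-bt})^2},$$

maximal at the curve's inflexion $t_{mid} = \ln a / b$, where $w = k/2$ and
$v_{max} = kb/4$.

Because the curve is fully determined by $(k, a, b)$, a handful of
biologically meaningful quantities follow in closed form and can themselves
be treated as heritable traits. The inflexions of the *rate* curve fall where
$a e^{-bt} = 2 \pm \sqrt3$, giving the phase boundaries

$$t_1 = -\frac{\ln\!\big((2+\sqrt3)/a\big)}{b}, \qquad
  t_2 = -\frac{\ln\!\big((2-\sqrt3)/a\big)}{b},$$

which delimit the gradual (lag), fast and slow growth phases. Filling is
considered complete when $w = 0.99k$ (an asymptote is never reached), so the
filling duration is $t_3 = \ln(99a)/b$. The dry matter accumulated in each
phase is

$$w_1 = \frac{k}{3+\sqrt3}, \qquad w_2 = \frac{\sqrt3}{3}k, \qquad
  w_3 = \Big(\frac{49}{100} - \frac{\sqrt3}{6}\Big)k,$$

together with the average rate $\bar v = kb/6$, the active filling period
$T = 6/b$ and $v_{max} = kb/4$. Three identities hold for *every* parameter
combination and are enforced at machine precision by the test suite:
$w_1 + w_2 + w_3 = 0.99k$, $v_{max} = 1.5\bar v$, and $T \bar v = k$. The
phase shares are constants of the logistic family: $w_1/k = 21.13\%$,
$w_2/k = 57.74\%$, $w_3/k = 20.13\%$ — rounding to 21%, 58% and 20%.

The completion fraction 0.99 is exposed as an argument
(`derive_parameters(completion = )`); the identities then hold with $0.99$
replaced by the chosen fraction. One curve is fitted per line per
environment.

A note on $\bar v$: it can be read either as the closed form $kb/6$ or as the
average of $v(t)$ over the active period $T$; the closed form is what the
package implements, and the two agree by the identity $T\bar v = k$ up to the
small mass of the curve outside the active window.

## Fitting

`fit_logistic()` minimises $\sum_i (w_i - w(t_i))^2$ by Levenberg–Marquardt
(via minpack.lm), with positivity bounds on all three parameters. Starting
values are self-generated: $k_0 = 1.05\max w$, then the logit transform
$\ln(k_0/w - 1)$ regressed on $t$ gives $b_0$ (negative slope) and
$a_0 = e^{\text{intercept}}$ — a standard self-start for sigmoid data that
needs no user input. Convergence is reported honestly
(`converged = FALSE` on failure, never silent estimates), trajectories need
at least 4 points, and degenerate inputs (all-equal or all-zero weights) are
errors. $R^2 = 1 - SS_{res}/SS_{tot}$ may legitimately be negative for a
mismatched curve and is then reported as computed, with a warning.

Numerical cross-checks: the closed-form $t_1, t_2$ are verified in the tests
against sign-change roots of a 6th-order finite-difference second derivative
of $v(t)$ (step scaled as $1/b$ so accuracy is time-scale invariant), and
$t_3$ against root-finding on $w(t) - 0.99k$, both to $10^{-8}$ DAP over
1,000 random parameter draws.

## Multi-environment statistics

With one observation per line per environment (the entry-mean design), the
two-way decomposition sets $\hat\sigma^2 = MS_{G\times E}$: the
genotype-by-environment interaction is confounded with error, which is the
standard convention for entry-mean heritability. Then

$$\hat\sigma^2_g = \frac{MS_G - MS_{G\times E}}{e}, \qquad
  H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2/e}$$

over $e$ environments. Negative moment estimates are truncated at zero and
flagged. BLUPs use the closed-form shrinkage
$\hat\mu + \lambda_i(\bar y_i - \hat\mu)$ with
$\lambda_i = \sigma^2_g / (\sigma^2_g + \sigma^2/e_i)$ after removing
environment means — identical to a genotype-random-intercept mixed model
under balance, deterministic and dependency-free; with missing cells, $e_i$
is the per-line environment count. Whether a G×E term should additionally be
modelled is left out deliberately: under the entry-mean design it is not
separable. Pool comparisons use the Welch (unequal-variance) t-test, the
default two-sample test in this field's scripts. Pearson correlations carry
t-distribution p-values and 0.05/0.01 stars.

## Marker QC, bin map, genetic distances

Markers are tested for segregation distortion against the 1:1 ratio expected
in a RIL population (chi-square, 1 df) and removed at $p < 0.001$; markers
with fewer than 20 informative calls are flagged untested. Residual
heterozygote calls are recoded missing at load time and counted.

The sliding-window bin map uses a window of 15 SNPs calling a genotype when
at least 11 informative SNPs agree — the published settings of the approach
the window method follows, exposed as options. Breakpoints are placed midway
between the centres of the flanking discordant windows, and SNP columns
identical across all lines collapse into bins. Marker order is trusted as
given (no order verification step).

Adjacent-bin discordance $R$ relates to the meiotic recombination fraction by
the selfing-RIL accumulation $R = 2r/(1+2r)$, inverted as $r = R/(2(1-R))$;
distances are Kosambi, $d = 25\ln\big((1+2r)/(1-2r)\big)$ cM, accumulated
along the chromosome. Intervals with $R$ at or beyond the unlinked
expectation are capped with a warning.

## QTL scanning

`cim_scan()` is a Haley–Knott-style composite interval mapping for RILs:

1. **Cofactors** — forward stepwise marker regression, at most 5 markers.
   The entry test is selection-adjusted: the best candidate enters only if
   its partial-F p-value times the number of screened candidates is below
   0.01. With an unadjusted rule the best of several hundred markers enters
   essentially always under a null trait, deflating the residual variance and
   inflating genome-wide false positives (measured 16% against the ~5%
   nominal); with the adjusted rule the null exceedance is ~2% while a real
   QTL (p-values many orders below the cutoff) always enters.
2. **Positions** — every 1 cM (configurable). The expected genotype score at
   a position comes from the flanking bins through Kosambi-based conditional
   probabilities on the observed RIL scale; missing flanks fall back to the
   single informative side.
3. **Test** — residual sums of squares with and without the position term,
   always excluding cofactors within half a 10 cM window of the tested
   position: $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$. The additive effect is half
   the parent-2 minus parent-1 homozygote difference;
   $PVE = 100(1 - RSS_1/RSS_0)$ against the cofactor-only model.

The genome-wide threshold is a Bonferroni correction over the effective
number of markers: the eigenvalues $\lambda_i$ of the marker correlation
matrix are mapped through $f(\lambda) = I(\lambda \ge 1) +
(\lambda - \lfloor\lambda\rfloor)$ and summed to $M_{eff}$, and the LOD
cutoff is $-\log_{10}(\alpha/M_{eff})$ — with 35 effective markers at
$\alpha = 0.05$ this is 2.845, i.e. 2.8 at one decimal. The decomposition is
genome-wide by default with a per-chromosome option (`chr =`); the two agree
closely on realistic LD structure. A caveat discovered while testing: this
$f$ is discontinuous at integer $\lambda \ge 2$, so $M_{eff}$ is *not*
invariant under duplicating a whole marker panel on sample correlation
matrices, although a single marker repeated $m$ times does carry exactly one
effective test.

Supra-threshold runs become QTL with 1.5-LOD support intervals; peaks within
10 cM on a chromosome (configurable) collapse into one nonredundant locus
across traits and environments. Combined-environment scans use per-line
trait means across environments.

## Bulked-segregant statistics

Extreme pools (13 lines each by default) are ranked on BLUP $v_{max}$, with
an optional eligibility band on $t_{mid}$ so both pools reach their maximum
rate at a similar time; ties break deterministically by line id.

Expression counts (one pooled library per bulk) are TMM-normalised — the
reference is the sample with the upper-quartile ratio closest to the mean,
M values are trimmed 30% and A values 5% from each tail, and the factor is
the inverse-variance weighted mean of the surviving M values, rescaled to
geometric mean 1. The genewise test is the conditional negative-binomial
exact test at fixed dispersion $BCV^2 = 0.2^2 = 0.04$ — with one library per
bulk this fixed dispersion is what makes the test well-defined. Counts are
first rescaled to the geometric mean of the effective library sizes and
rounded to the nearest integer (a documented simplification of the reference
implementation's pseudo-count scheme; the package's p-values are validated
against a direct split-enumeration oracle to $10^{-10}$ and rank-agree with
the reference implementation). A gene is a DEG when the Bonferroni-adjusted
p-value is below 0.05 *and* $|\log_2 FC| > 2$, with a 0.125-count prior per
bulk stabilising zero counts.

Per-SNP bulk statistics are the SNP index (alternate-allele read fraction per
bulk) and its difference $\Delta$, the likelihood-ratio $G = 2\sum n
\ln(n/\hat e)$ on the 2×2 bulk-by-allele table (reported unsmoothed, per
site), and a two-sided Fisher exact test, FDR-adjusted by Benjamini–Hochberg
(Hochberg step-up available by option) at the 0.05 level. Candidate genes
are the intersection: DEGs inside a QTL support interval carrying at least
one FDR-significant SNP, optionally restricted to an externally supplied
enrichment list (GO/KEGG enrichment itself is out of scope as it needs
external annotation databases). All physical coordinates are 1-based
inclusive; genetic (cM) intervals must be projected with
`qtl_to_physical()` against explicit anchors — the package refuses to guess
a cM-to-bp mapping.

## The synthetic study

`simulate_study()` generates every input so the whole pipeline is testable
without external data:

* **Genotypes** — 208 RILs on 10 chromosomes of 160 cM with 33 evenly spaced
  bin markers (~330 bins; a desk-scale caricature of a 3,000-bin map).
  Parental origin follows a two-state Markov chain at the F$_\infty$
  expectation, with transition probability $R = 2r/(1+2r)$ from the inverse
  Kosambi of each gap — this matches the analysis model exactly and is far
  faster than meiosis-by-meiosis selfing; no interference is modelled beyond
  what Kosambi encodes between adjacent markers.
* **Phenotypes** — parents contrast as a small fast filler
  ($k = 13$ g, $b = 0.16$) against a large slow one ($k = 17$ g, $b = 0.10$),
  both reaching $v_{max}$ near 30 DAP, so midparent $v_{max} \approx 0.5$
  g/DAP. QTL act additively on $k$, $a$ and $b$ (effects summing to half the
  parental difference per parameter; one locus on chromosome 7 is pleiotropic
  on all three, so derived traits inherit correlated effects by
  construction). Environment and G×E deviates are Gaussian per parameter;
  non-positive draws are resampled with a warning. Weights are sampled at
  the 14-point schedule 10–61 DAP with additive Gaussian weighing noise
  (sd 0.5 g, truncated at zero; a proportional-noise flag exists).
* **Calibration** — the defaults were set once so the realized statistics
  resemble a real trial: line CV of $k$ ≈ 10%, median relative error of
  $\hat k$ ≈ 1.6%, fit $R^2 > 0.99$, and realized $H^2(k)$ between 0.73 and
  0.80 across seeds. The residual variance that caps $H^2$ is dominated by
  G×E rather than weighing error: with much larger weighing noise the fits
  degrade non-uniformly (slow lines are far from plateau at 61 DAP and $k$
  becomes unidentifiable), which is not how real multi-environment noise
  behaves. Real data differ from this generator in ways the tests therefore
  cannot vouch for: real trajectories deviate from the logistic form (the
  generator's only noise is Gaussian around a true logistic, so simulated
  $R^2$ runs higher than the ~0.95 typical of field data), maps have uneven
  marker density, and segregation distortion, missingness and heterozygote
  residues occur at real rates (the generator's defaults set them to zero;
  both are options).
* **Bulks and expression** — bulk allele depths are binomial (depth 40 per
  site and bulk) around each pool's true allele frequency; expression counts
  are negative binomial (dispersion 0.04) around log-normal baselines with
  30 designated DE genes at 8-fold change among 1,030 genes, one library per
  bulk at ~2M reads. Physical positions are assigned at 1 Mb per cM,
  consistently across the study.

Everything is reproducible: a fixed seed yields byte-identical tables.

## Problem sizes in the tests

The test suite exercises the statistical claims at sizes chosen to give
stable Monte-Carlo answers while staying desk-scale: 1,000 random parameter
draws for the closed-form-vs-oracle comparison; 100 lines at default noise
for parameter recovery; 50 replicates of 500 lines × 3 environments at
$H^2 \in \{0.3, 0.75\}$ for heritability recovery (±0.05 on the mean); 200
null genomes and 50 single-QTL genomes (20% PVE, 208 lines) for scan
calibration and power; enumeration oracles on 50-gene tables; three seeded
null replicates each for the FDR and DEG null controls.

## Known limitations

* No segmented/bilinear filling models and no alternative sigmoids
  (Gompertz, Richards): the logistic family is the point of the design.
* No REML mixed models, multi-trait models, or spatial field-trend
  correction; the entry-mean shrinkage BLUP assumes (near-)balance.
* No multiple-QTL model fitting, epistasis scan, or permutation thresholds;
  the Meff-Bonferroni threshold is the method implemented.
* The ΔSNP-index statistic is reported descriptively; significance flows
  through the Fisher/FDR route (simulation-based confidence bands for Δ are
  not specified and not implemented).
* No read alignment, FPKM quantification, or GO/KEGG enrichment computation.
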