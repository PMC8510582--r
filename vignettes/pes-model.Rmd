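---
title: "Modeling outcomes of polygenic embryo screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling outcomes of polygenic embryo screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pesrisk)
```

## The model

pesrisk predicts the change in complex-disease risk when an in vitro
fertilization (IVF) embryo is chosen for implantation on the basis of its
polygenic risk score (PRS).  The framework is the liability threshold
model (LTM): each individual carries a latent liability
$y \sim N(0, 1)$ (in population-SD units), and is affected exactly when
$y > z_K = \Phi^{-1}(1-K)$, where $K$ is the population prevalence.  The
PRS $s$ explains a fraction $r^2_{ps}$ of the liability variance, so

$$y = s + e, \qquad s \sim N(0, r^2_{ps}), \qquad e \sim N(0, 1 - r^2_{ps}),$$

with $e$ collecting the environment and the genetic variation the score
does not capture.  Within a couple, full-sibling embryos share half the
score variance: writing $c$ for the mean parental PRS,

$$s_i = c + x_i, \qquad c \sim N(0, r^2_{ps}/2), \qquad
  x_i \sim N(0, r^2_{ps}/2) \ \text{iid across embryos } i = 1,\dots,n.$$

Two selection strategies are modeled.  Under *lowest-risk prioritization*
(LRP) the embryo with the minimum PRS is implanted.  Under *high-risk
exclusion* (HRE) embryos whose PRS falls in the top $q$ of the population
score distribution (above $z_q \sqrt{r^2_{ps}}$) are set aside and a
random remaining embryo is implanted; if every embryo is high-risk, a
random embryo is used.  A variant of HRE instead falls back to the
lowest-scoring embryo in that case, and smoothly becomes LRP as
$q \to 1$.

Outcomes are reported as the probability $P$ that the selected embryo
becomes affected, the relative risk reduction $RRR = 1 - P/P_0$ and the
absolute risk reduction $ARR = P_0 - P$, where $P_0$ is the risk of a
randomly selected embryo under the same conditioning (the prevalence $K$
in the unconditional case).

## Analytic engine

Conditional on $c$, the score of the LRP-selected embryo is
$c + \min(x_1,\dots,x_n)$, whose density follows from order statistics:
$f_{\min}(x) = n\,\sigma_x^{-1}\phi(x/\sigma_x)\,[1-\Phi(x/\sigma_x)]^{n-1}$
with $\sigma_x^2 = r^2_{ps}/2$.  The disease probability is then the
residual tail integral

$$P(\text{disease}\mid c) \;=\; \int f_{\min}(x)\,
  \bar\Phi\!\left(\frac{z_K - c - x}{\sqrt{1-r^2_{ps}}}\right) dx,$$

and the population-averaged risk integrates over
$c \sim N(0, r^2_{ps}/2)$.  For HRE, conditioning on $c$ makes the
eligibility cutoff on $x$ deterministic ($x < z_q\sqrt{r^2_{ps}} - c$):
with probability $1-(1-\Phi(u))^n$ (at least one eligible embryo) the
selected $x$ is an upper-truncated normal, and otherwise a lower-truncated
normal (plain HRE) or the minimum of $n$ lower-truncated normals
(fallback variant); the mixture is integrated the same way.

Numerical choices:

* adaptive quadrature (`stats::integrate`) with absolute tolerance
  `1e-10` on probabilities, integration limits at $\pm 8$ SD (neglected
  normal tail mass $< 10^{-15}$, far below tolerance);
* the LRP kernel is implemented twice -- the order-statistic density
  route above and an equivalent form that conditions on the residual
  instead, $\int \phi_e \, [1-\Phi((z_K - c - e)/\sigma_x)]^n\,de$ -- and
  the test suite requires the two to agree to `1e-8`, guarding the
  numerics at large $n$;
* dense per-couple curves use a fixed 257-node Gauss--Legendre rule,
  vectorized across the grid, checked against the adaptive route;
* the near-singular mixture weight $(1-(1-\Phi(u))^n)/\Phi(u)$ is
  evaluated with `expm1`/`log1p` and its $n$ limit as $\Phi(u)\to 0$;
* ties in scores have probability zero under the continuous model; the
  simulators break them by lowest index, making runs deterministic.

### Conditioning on the couple

Given the mean parental PRS (`risk_given_c()`), the formulas above apply
directly with $c$ fixed; parental PRSs given as population percentiles are
lower-tail quantiles of $N(0, r^2_{ps})$, so a "98th-percentile parent"
belongs to the top 2%.  The per-couple RRR curve
(`pcrrr_distribution()`) evaluates $1 - P_s(\cdot\mid c)/P_r(\cdot\mid c)$
on mid-quantile grid points $(i-\tfrac12)/m$ of the $c$ distribution --
an unbiased equal-mass discretization -- and the law of total probability
(grid average = unconditional risk, to $10^{-3}$ on a $10^4$ grid) is a
standing test.

Conditioning on parental disease status additionally needs the
narrow-sense heritability $h^2 \ge r^2_{ps}$.  Parent $j$ has liability
$t_j + e_j$ with $t_j = s_j + g_j \sim N(0, h^2)$ collecting the score and
the non-score genetic component, and $e_j \sim N(0, 1-h^2)$.  Offspring
receive the mid-parent value of both heritable components plus segregation
noise of half the population variance each, so the embryo risk depends on
the parents only through $T = (t_1+t_2)/2$ (for LRP; HRE also needs the
score part $c$, whose conditional distribution given $T$ is normal and is
integrated out).  The posterior of each $t_j$ given the parent's affection
status is handled by a 201-node Gauss--Legendre product rule, with the
smooth risk-vs-$T$ curve evaluated on a 401-point spline grid.  A
rejection-sampling Monte-Carlo route (`simulate_selection()` with
`condition_status`) implements the identical generative model directly and
the two are required to agree within Monte-Carlo error; the simulator
refuses conditionings with acceptance rates below $10^{-5}$ and points to
the quadrature instead.

## Monte-Carlo engine

`simulate_selection()` draws embryo batches exactly as the generative
model states, vectorized over couples and chunked (default $10^5$ couples
per chunk) to bound memory.  Every stochastic entry point takes an
explicit integer seed, produces bit-identical output for equal seeds, and
restores the caller's RNG state, so no global state leaks between calls.
Random picks among eligible embryos use a uniform random-key argmax,
which is exactly uniform and fully vectorized.

For the two-disease pleiotropy analysis (`simulate_pleiotropy()`), the
genetic covariance $\rho\sqrt{r^2_1 r^2_2}$ between the disease scores
must be split between the shared and the embryo-specific components.  The
split is not dictated by the single-disease model; we assign half to
each, mirroring the variance split of a single score, and treat the
residual (environmental) liabilities as independent across diseases,
since the mechanism modeled is genetic correlation only.  The target
disease's random-number stream is constructed independently of $\rho$, so
the target-disease risk reduction is identical across $\rho$ values at a
fixed seed, isolating the pleiotropic effect.

## Dichotomized quantitative traits

A disease defined by thresholding a normal quantitative trait (IQ below
70, LDL cholesterol above a clinical cutoff) *is* the LTM: the implied
prevalence is the tail mass beyond the threshold, and selecting the
embryo with the most favorable trait PRS is LRP on the equivalent
disease (by reflection for upper-tail traits).  `rrr_dichotomized()`
therefore delegates to the disease engine rather than duplicating the
integration; `tail_retention_fraction()` quantifies the intuition that
most affected individuals sit just beyond the threshold.  Published trait
PRS accuracies are shipped as illustrative configuration files
(`inst/extdata/`), not hardcoded constants.

## Genome-level simulator

The genome module validates the statistical model on synthetic phased
cohorts rather than on real case-control genomes.  The generator emulates:

* independent biallelic variants in Hardy--Weinberg equilibrium with
  uniform minor-allele frequencies (default 0.1--0.5), spread in
  contiguous blocks over several chromosomes;
* an additive score with normal per-variant weights, rescaled so the
  score explains a requested fraction of liability variance;
* case/control status from the liability threshold, with sampling
  continued until the requested numbers of each are collected;
* a piecewise-linear genetic map (default 1 cM/Mb, 1 Mb variant
  spacing, so chromosomes are of order one Morgan and score loci
  segregate nearly independently, as for a genome-wide score).

It deliberately does **not** emulate linkage disequilibrium, allele
frequency/effect-size coupling, A/T-C/G strand ambiguity, genotyping
error, assortative mating, or sex-specific maps -- passing pipeline tests
therefore validates the modeling chain, not robustness to those
real-data features.

Downstream, `mate_virtual_couples()` pairs individuals (regardless of
sex) so the couple composition matches random mating at prevalence $K$;
`simulate_offspring()` draws per-chromosome crossover counts from a
Poisson distribution with the map length in Morgan as mean, places them
uniformly in genetic distance, interpolates to physical coordinates
(1-based positions; a crossover landing exactly on a variant leaves it on
the left segment), and transmits a random strand per chromosome.
`fit_logistic_risk()` regresses status on score and shifts the intercept
by $-\log[P(1-K)/((1-P)K)]$ to undo case oversampling;
`calibrate_score_percentiles()` reweights cases and controls by
$K/P$ and $(1-K)/(1-P)$ to define the population score normal used for
HRE percentile cutoffs; and the observed-scale status-score $R^2$ is
converted to the liability scale with the ascertainment-corrected
transformation of Lee et al. (2012, Eq. 15).  Scores are raw weighted
allele-dosage sums by default, with the per-allele average dialect
available (`average = TRUE`); relative risk reductions are invariant to
this rescaling.

The packaged experiment (`run_genome_experiment()`) and its test use a
cohort of 500 cases and 1000 controls, 600 variants on 10 chromosomes,
5000 virtual couples and 20 embryos per couple with 5 used for selection
-- sizes chosen so the within-couple variance diagnostics (pooled embryo
score variance $\approx$ half the parental population variance, flat in
the mean parental score) estimate their targets with small error while
the whole pipeline stays desk-scale.  Because the cohort is far smaller
than the number of couples, individuals are reused across (unique)
couples, with a warning.

## Worked example

```{r example, eval = FALSE}
scn <- pes_scenario(K = 0.01, r2 = 0.08, n = 5)
analytic_risk(scn)
#> Embryo screening risk result
#>   P(disease), selected : 0.4821%
#>   P(disease), baseline : 1%
#>   relative risk reduction : 51.8%
#>   absolute risk reduction : 0.52 percentage points
```

A rare disease with a realistic score: the relative reduction is large
(half the risk), the absolute reduction small (half a percentage point)
-- the two metrics answer different questions, and both are reported
everywhere.

## Known limitations

Single-disease selection only; an infinitesimal architecture is assumed
throughout (no large-effect variants); $r^2_{ps}$ is treated as the
within-family accuracy actually achievable in the target population,
which published values tend to overstate, so results are upper bounds in
that respect; the within-couple, across-batch variability of the risk
reduction is out of scope (the per-couple RRR is itself an average over
batches); and `n` counts embryos that would lead to live birth, not
fertilized oocytes.
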