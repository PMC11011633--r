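---
title: "Modelling cold-treatment efficacy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cold-treatment efficacy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldtreat)
```

This vignette documents the statistical model behind `coldtreat`, the
choices made where the design was genuinely open, and the limits of
what the shipped tests demonstrate.

## The time–mortality model

Cold disinfestation bioassays count survivors (pupae) in boxes of
infested fruit removed from a cold store after different treatment
durations. `coldtreat` models the probability that an insect of life
stage $s$ is dead after $t$ days as

$$ g(p_{st}) = \alpha_s + \beta_s t, $$

where $g$ is a probit or logit link. Counts of dead insects in a box
are beta-binomial: conditional on a Beta-distributed box-level death
probability with mean $p_{st}$ and intraclass correlation $\rho$, the
count is binomial. The overdispersion has its own submodel on the
logistic scale,

$$ \rho_{st} = \mathrm{logit}^{-1}(d_s + e\,t), $$

with per-stage intercepts and a single shared time slope by default
(`bb_model_spec(disp_stage_slopes = TRUE)` switches to per-stage
slopes; `dispersion = "binomial"` forces $\rho = 0$). The shared slope
is the minimal structure that lets between-box heterogeneity shrink or
grow along the treatment, which the data demand: binomial fits to
overdispersed boxes produce badly anti-conservative intervals, which is
why the dispersion submodel exists at all.

Replicates (infestation batches treated together) can receive Gaussian
random intercepts on the link scale (`random = "replicate"` or
`"replicate_cultivar"`). The marginal likelihood integrates these out
with a Laplace approximation per cluster; when the curvature at the
conditional mode is ill-conditioned the code falls back to 9-point
adaptive Gauss–Hermite quadrature. A variance estimate pinned near the
zero boundary is flagged (`boundary`), not treated as an error.

### Responses and bookkeeping

The modelled response is the number dead, `round(E - P)` clipped at
zero, out of `round(E)` trials, where `P` is the pupae retrieved from a
box and `E` the *estimated number treated*: the mean pupal yield of the
control (duration 0) boxes for the same cultivar, replicate, and life
stage (`estimate_treated()`). Controls enter the fit as data points —
their observed "mortality" is small but not exactly zero because `E` is
an estimated denominator — and no correction for natural control
mortality is applied, since the published summaries report control
medians of 0–6.6% without one. Mortalities are clipped into $[0, 1]$:
a box that out-yields its control expectation counts as 0% mortality.

### Fitting and numerics

Maximum likelihood by BFGS on the negative log-likelihood, restarted
once from its own optimum, with empirical-link starting values: a
least-squares line through $g((\text{dead}+0.5)/(\text{total}+1))$ per
stage, which is robust to all-dead and all-alive boxes. Mean
probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ and $\rho$ to
$[0, 1-10^{-10}]$ before evaluating the likelihood; $\rho < 10^{-8}$
uses the binomial limit to avoid precision loss in `lbeta` at extreme
shape parameters. The covariance is the inverse observed information
(finite-difference Hessian at the optimum); fits report `converged`
honestly and a complete-separation heuristic flags stages with no
interior response and an exploded slope. With `link = "auto"` both
links are fitted and the smaller AIC wins, with both AICs recorded.

`dispersion_check()` is a simulation-based residual diagnostic: the
mean squared residual scaled by the fitted model's own beta-binomial
variance is compared with its distribution over datasets simulated from
the fit. That scaling makes the statistic near-pivotal (close to 1
under a correct model). With `refit = TRUE` every simulated dataset is
refitted before computing its statistic — the exact parametric
bootstrap, whose p-value is uniform under a well-specified model; the
faster default keeps the original fit and is slightly conservative.

## Lethal times and Fieller intervals

Inverting the mean model gives the lethal time
$LT_p = (g(p) - \hat\alpha_s)/\hat\beta_s$; at $p = 0.999968$ (the
exported `probit9` constant, stored at full precision) this is the
quarantine-security lethal time. Confidence limits use Fieller's
theorem on the $(\hat\alpha_s, \hat\beta_s)$ covariance block with
$g = z^2\,\mathrm{var}(\hat\beta)/\hat\beta^2$: for $g < 1$ the finite
interval (a roundoff-negative discriminant is clamped to zero, since
real roots always exist in this case); for $g \ge 1$ an explicitly
flagged unbounded or exclusive result — never a clipped finite
interval. The default uses the fixed-effects covariance block even in
mixed fits; the full joint covariance is stored on the fit for users
who prefer to propagate the variance-component uncertainty.

## Efficacy arithmetic

The number of insects treated in a large-scale trial is never observed;
it is extrapolated from per-replicate control yields
$(\mu \pm t_{0.975, r-1}\, s/\sqrt{r}) \times n_l/n_c$, the two-sided
95% CI of the control mean scaled by the ratio of treated fruit $n_l$
to control fruit $n_c$. Two published alternatives are provided for
comparison: the lower limit of a one-sided 95% t-interval, and a
one-sided variant substituting the standard deviation for the standard
error (labelled approximate, since the exact constant in the
plant-protection-convention recommendation is not fixed here). Scaled
counts are reported unrounded and rounded half-away-from-zero.

Given $n$ treated and $s$ survivors, the confidence that true
mortality is at least $m$ is the upper binomial tail
$C = 1 - \sum_{i=0}^{s}\binom{n}{i}(1-m)^i m^{n-i}$, evaluated via
`pbinom(..., lower.tail = FALSE)` so that $n \sim 10^5$–$10^6$ and
near-zero tails keep full precision. `efficacy_report()` takes the
**minimum** across available treated-number estimates by default — the
conservative policy, configurable — and `required_n()` inverts the
zero-survivor bound ($\lceil \ln(1-C)/\ln m \rceil$ with an exact
integer check at the boundary; 93,616 insects for 95% confidence at the
probit-9 standard).

## Thermal QA

Probe offsets are ice-bath means negated, so corrected ice-bath means
are zero by construction. Cool-down time uses the large-scale rule by
default: the first logged timestamp at which *strictly more than half*
of the fruit-core probes read below 3.5 °C (6 of 10 probes), at the
resolution of the 30-minute sampling interval; the small-scale
alternative (`rule = "mean"`) triggers when the mean fruit-core reading
crosses the threshold. Constancy is the percentage of post-cool-down
fruit-core readings within 3 ± 0.5 °C, both band edges inclusive, with
air probes excluded from the denominator. A threshold never reached is
a flagged result, not an exception.

## The synthetic-data generator

`gen_cold_tolerance()` emulates the two bioassay designs: the
2018-style factorial (4 stages × 2 cultivars × durations 0/5/6/7/8/10 d
× 4 replicates, 3 boxes of 5 fruit per cell) and the 2019-style
third-instar extension (durations 0/8/10/11/13/14/16/18 d, 5 boxes of
10 fruit, 810 fruit per replicate counting the 10 dissection fruit).
Defaults were fixed once from published summaries and are not
tuned: per-stage mortality curves back-solved from the 'Hayward'
lethality table (so the generating LT$_{50}$/LT$_{99.9968}$ are 4.05
and 17.31 d for third instars), a +0.5 link-scale susceptibility shift
for 'Zesy002', egg loads of 90 per fruit (SD 21.7, back-solved from the
printed 95% CI at $n = 30$; 105 and SD 8.3 for the large-scale design),
survival-to-pupa rates of 0.70 ('Hayward') and 0.27 ('Zesy002') implied
by control yields, and 51 pupae per fruit (SD 5.4) in large-scale
controls. Between-box $\rho \approx 0.05$ and a replicate SD of 0.2 on
the link scale are synthetic choices — the study publishes no
between-box variance — set large enough that dispersion diagnostics
must detect non-binomial variance.

What the generator does *not* emulate: larval development timing and
stage misclassification, fruit-to-fruit covariance within a box,
temperature excursions during treatment (temperature logs are clean
exponential decays plus Gaussian reading noise), and any dependence of
mortality on cool-down rate. Passing tests therefore demonstrate that
the *statistical machinery* is correct under the declared model, not
that the model captures every feature of real bioassays.

One structural subtlety is deliberate: control boxes yield their full
treatable count (they are never treated), so the generated control
points do not lie on the link-model curve, whose intercept implies a
small nonzero baseline mortality at $t = 0$. The estimated-denominator
bookkeeping largely offsets this — clipping `round(E - P)` at zero
produces a small apparent control mortality, as in real data — leaving
a residual downward bias in probit-9 lethal-time estimates of a few
percent at the 2019 design scale. For this reason the interval
*calibration* test fits treated durations with the bookkept treatable
totals (where the fitted model is exactly the generating process),
while the *recovery* test runs the full pipeline, controls, estimated
denominators and all, and asks only for 10% accuracy.

## Problem sizes in the shipped tests

The suite checks, among others: beta-binomial normalisation by
exhaustive summation for $n \le 30$ across a $(\mu, \rho)$ grid;
agreement of the binomial-data fit with an independent IRLS fit to
$10^{-4}$; agreement of the duration-level beta-binomial optimum with
glmmTMB to $10^{-3}$; Fieller endpoints against a 10,000-draw
parametric bootstrap within 0.05 d; 95% Fieller coverage within 92–98%
over 300 simulated 2019-scale datasets; probit-9 lethal-time recovery
within 10% in at least 90% of 100 full-pipeline runs; p-value
uniformity of the refitting dispersion diagnostic over 100 seeds (119
simulations each); replicate-SD recovery over 12 mixed fits; and
cool-down detection within one 30-minute sample of the analytic
crossing. These sizes were chosen to keep Monte-Carlo error small
relative to each acceptance band.

## Known limitations

* **Duration-level refits are not box-level fits.** The published
  probit-9 estimates come from box-level mixed models; only
  duration-level totals are public (`cold_tolerance_totals()`).
  Refitting those totals with the default model yields third-instar
  LT$_{99.9968}$ values about 1–2 days *below* the published box-level
  estimates, and plausible variants (constant dispersion) land 1–2 days
  *above*: aggregation destroys the between-box information that
  locates the estimate, and no setting of this model on the public
  totals should be expected to reproduce it exactly. The package
  reports what the totals support.
* Fieller intervals use the asymptotic observed-information covariance;
  at small design scales they run a few points below nominal coverage
  (95% is reached by roughly three times the 2019 design size in the
  shipped calibration experiments).
* The treated-number extrapolation assumes control fruit are
  exchangeable with treated fruit up to the scaling factor; infestation
  drift between replicates enters only through the control variance.
* `required_n()` and `mortality_confidence()` treat insects as
  independent Bernoulli survivors; clustering of survivors within fruit
  would make the stated confidence optimistic.
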