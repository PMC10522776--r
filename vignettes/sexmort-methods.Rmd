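---
title: "Modelling sex ratios of mortality at ages 0-24: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sex ratios of mortality at ages 0-24: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmort)
```

## The estimation problem

Sex-disaggregated mortality for children, adolescents, and young
people is observed unevenly: rich countries have near-complete vital
registration, while most deaths at these ages occur in countries where
mortality must be measured through survey birth histories, sibling
histories, or census reports on household deaths.  Each source carries
sampling error (few deaths, small samples) and its own systematic
error (recall, misreporting, coverage).  The quantity of interest — the
male:female ratio of the probability of dying in an age interval — must
therefore be estimated for every country-year, including country-years
with no usable data at all, with honest uncertainty.

The package models the country-year sex ratio as the product of two
components:

$$S(c,t,a) = f_a\bigl(Q(c,t,a)\bigr)\,\exp\bigl(\delta(c,t,a)\bigr)$$

where $Q$ is the total (both-sex) probability of dying, $f_a$ is a
global curve mapping total mortality to the *expected* sex ratio for
age group $a$, and $\delta$ is a country-specific log multiplier.  The
curve expresses the robust aggregate regularity — the ratio rises as
mortality declines, because surviving deaths concentrate in early
infancy and in causes that disadvantage boys, and may flatten or
reverse at very low mortality — while the multiplier absorbs each
country's persistent deviation from that benchmark.  The deviation is
exactly what the excess-female-mortality analysis interrogates.

## Model components and priors

**Global curve.**  $\log f_a$ is piecewise linear in $\log Q$ on a knot
grid, flat beyond the end knots.  By default six knots are placed at
equally spaced quantiles of the observed log-mortality values, so every
segment is supported by data; the grid spans the observed range and the
flat tails make extrapolation explicit rather than accidental.  Knot
values get a Normal(0, 1) prior on the first knot, weak Normal(0, 5)
on the others, and a second-difference (random-walk-2 style) smoothness
prior with SD 0.1 on the log-ratio scale.  The smoothness SD is the
main stiffness control: 0.1 allows the curve to bend by a few percent
per segment, which matches the curvature seen in empirical sex-ratio
databases, without chasing single observations.  Piecewise-linear
interpolation keeps every conditional Gaussian and makes the curve
auditable point by point; it deliberately trades a small amount of
smoothness for exactness of the conditional updates.

**Country multipliers.**  $\delta(c,\cdot,a)$ follows a stationary
AR(1) with mean zero, stationary SD $\tau$, and lag-1 correlation
$\rho$, with one $(\tau, \rho)$ per age group shared across countries.
Mean zero encodes "multipliers fluctuate around 1"; stationarity keeps
countries without data anchored to the curve with an honest prior
width of $\tau$; the AR(1) is the lightest process that gives temporal
pooling and mean reversion.  Priors: half-Normal(0, 0.5) on $\tau$
(weakly informative on the log-ratio scale — a priori deviations of
50% are already unlikely), Uniform(0, 1) on $\rho$.

**Observation model.**  The observed log ratio is Normal around the
model log ratio with variance $v_i + \sigma_j^2$: $v_i$ is the
sampling variance carried by the observation (or derived from backing
death counts by the Poisson delta method $1/D_m + 1/D_f$), and
$\sigma_j$ is a non-sampling SD per source type (VR, FBH, SBH, census)
with half-Normal(0, 0.5) priors.  This is what makes the fit follow
high-quality observations more closely than noisy ones.  Observations
with decimal reference years inform the nearest model year; this
avoids interpolation inside the likelihood at the cost of up to half a
year of dating error, negligible against the multi-year smoothness of
the estimates.

A single model framework serves all three reporting age groups,
configured per age group; the under-5 configuration is the
reporting-level simplification of the classic under-5 sex-ratio model,
and the 5+ groups differ only in their inputs (direct estimates that
can be aggregated from fine age groups by conditional survival,
$q = 1 - \prod(1 - q_{\text{fine}})$).

## Posterior computation

The sampler is a blocked Gibbs scheme targeting exactly the joint
density exposed by `log_posterior()`:

1. each country's multiplier vector has a Gaussian full conditional
   with tridiagonal precision (AR(1) precision plus diagonal data
   precision), sampled by Cholesky factorisation;
2. the curve knot values have a Gaussian full conditional through the
   sparse interpolation design matrix;
3. $\tau$, $\rho$, and each $\sigma_j$ move by adaptive random-walk
   Metropolis on log / logit scales.  Because $\tau$ mixes poorly in
   the centered parameterisation when the data are informative, every
   scan adds an ancillarity–sufficiency interweaving move that
   rescales the whole multiplier field together with $\tau$; the
   cheap scalar updates are swept three times per scan.

Convergence is monitored with split-chain statistics (one chain cut
into four segments) for the hyperparameters; values above 1.05 set a
`warn` status in the output and run manifest rather than failing
silently.  Degenerate inputs are handled explicitly: $\tau = 0$ with a
nonzero multiplier has density $-\infty$; zero total observation
variance is an error (the likelihood would be a point mass); a single
model year skips the $\rho$ update.  Reduced runs for oracle testing
can fix the curve, $\tau$, $\rho$, or the $\sigma_j$, in which case
the remaining blocks sample their exact conditional posteriors — the
one-cell configuration reproduces the closed-form conjugate posterior
and is tested against it.

Interval summaries use the 5th, 50th, and 95th percentiles with the
linear-interpolation (type 7) quantile convention; fixing the
convention makes interval tests exact.

## Derived quantities

Sex-specific rates come from the exposure-weighted split
$q_f = Q / (w\,S + 1 - w)$, $q_m = S\,q_f$, with $w$ the male share of
exposure entering the age group — births ($\mathrm{SRB}/(1+\mathrm{SRB})$,
default SRB 1.05) for 0–4, population shares otherwise.  Weights are
fixed at interval entry; the within-interval survivorship composition
refinement is ignored as second-order at these mortality levels.
Male mortality is the reference for the excess computation: the male
rate implied by the estimated ratio is divided by the estimated and by
the expected ratio to give $q_f^{est}$ and $q_f^{exp}$, so
$q_f^{est}/q_f^{exp} = s^{exp}/s^{est}$ exactly, and the excess rate is
their difference.  Excess deaths convert through estimated female
deaths times $(1 - 1/R)$; whether the source analyses used a
person-years-based conversion is not documented at reporting level, so
the deaths-based form, consistent with reporting excess deaths as a
share of deaths, is used.  A country-year is flagged outlying when the
posterior probability of positive (or of negative) excess reaches 95%
and the median |excess| exceeds one death per 1000 — both conditions,
exactly as stated.

When totals carry uncertainty draws, sex-ratio draws are paired with
totals draws by index after an independent seeded shuffle: this
preserves both marginals without asserting a dependence between
total-mortality and sex-ratio uncertainty that nothing in the inputs
identifies (the independence assumption is deliberate and flagged
here).

Regional aggregation sums country death-count draws within draws
(preserving coherence), then summarises; regional sex-specific rates
apply regional death shares to the regional total rate divided by
exposure shares, which conserves the total exactly.  Crisis-related
deaths enter as a purely additive, user-supplied, sex-specific hook —
the identification and sex-splitting of crisis deaths is upstream
knowledge the package does not model; a 50/50 default split must be an
explicit caller choice.

## The synthetic-data generator

The generator emulates the full input stack with known truth: total
mortality declines exponentially per country (starting levels 0.02–0.25,
annual declines 1–5%, mild log noise, clipped to (10⁻⁶, 0.9));
a true curve with a rise to ~1.19 and a reversal at very low
mortality; AR(1) multipliers (defaults ρ = 0.9, τ = 0.1 — persistent
country deviations of ±10% scale); observations from a realistic
source mix (VR 50%, FBH 20%, SBH 20%, census 10%) with source-specific
sampling SEs (VR 0.01–0.05, surveys 0.05–0.15, census 0.02–0.10 on the
log scale — registration counts are nearly exact, survey histories are
not) and non-sampling SDs (VR 0.025, FBH 0.05, SBH 0.075, census
0.05).  Defaults give one observation per country-year in expectation
(~2000 records for 60 countries over 32 years).

The generator's noise is additive Normal on the log-ratio scale —
matching the model's own data-quality assumptions — so recovery tests
are well-posed: they verify inference, not robustness.  What the
generator does **not** emulate: HIV/crisis mortality shocks,
cause-of-death structure, age-misreporting heaping, source-specific
bias (the non-sampling error has mean zero, whereas real sibling
histories can be systematically biased), or correlated errors within
survey series.  Passing recovery tests therefore demonstrates the
estimator is correct under its own assumptions, not that real
databases satisfy them.

## Numerical and testing choices

Oracle tests pin the multiplier density to a dense multivariate-Normal
evaluation (lengths 1–5, 10⁻⁸), the reduced posterior to its conjugate
closed form, and the full `log_posterior()` to independently summed
components.  The headline recovery study uses 60 countries × 32 years
with the default generator, 1000 kept draws thinned by 3 after 800
warmup scans (about half a minute of sampling); the validation refit
uses 600 draws thinned by 2.  These sizes give Monte-Carlo error
comfortably inside the test bands (e.g. binomial SE ≈ 0.7% on 1920
coverage indicators) while keeping the default suite fast.  Curve
recovery is assessed over the knot range; the largest errors sit at
the boundary knots, where the extreme ~1% of observations provide the
only support — estimates beyond the bulk of the data should be read
with corresponding caution.

## Known limitations

* Countries enter symmetrically; there is no regional hierarchy in the
  multipliers, so information does not flow between neighbouring
  countries beyond the global curve.
* The curve is static in time: all secular change must travel through
  the total-mortality input.
* Totals are treated as error-free in the likelihood (bias in totals
  propagates into sex ratios); totals uncertainty enters only when
  splitting trajectories into sex-specific rates.
* The extreme-observation filter (default ratio bounds 0.2–5,
  symmetric on the log scale) is a blunt stand-in for source-specific
  inclusion criteria.
* Long-horizon projection is unsupported by design; the
  leave-last-years-out validation mode probes only short-term
  extrapolation.
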