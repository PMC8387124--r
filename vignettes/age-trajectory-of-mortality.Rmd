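---
title: "Modelling the age trajectory of child mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the age trajectory of child mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmort)
```

## The problem

The human mortality rate falls by more than three orders of magnitude
between the first day of life and the lifetime minimum around ages 5–10
years. In large pooled populations the decline is strikingly regular: in
log–log coordinates it is a straight line with slope close to −1, i.e. the
rate is close to inversely proportional to age,
$\mu(x) = \mu_1 / x$. `atmort` implements the full chain needed to
construct that trajectory from death registrations and census counts, to
test the inverse law formally, and to connect it to a
population-heterogeneity (frailty) mechanism that predicts it.

## Rates by Halley pooling

The unit of analysis is the **age-specific mortality rate per
person-year**: for age category $i$, $\mu_i = D_i / L_i$, where $D_i$ sums
deaths over every selected country and calendar year and $L_i$ sums the
corresponding person-years of exposure. Pooling many country-years into
one hypothetical population ("the Halley method") is not a convenience but
a requirement: per-country, per-year counts contain zero-death categories
whose log-rate does not exist, and only aggregation removes them. Pooling
is exact bookkeeping — it is additive, associative and invariant to how
the calendar period is split, and the test suite asserts all three
properties.

Exposure uses the stationary-population reading of census counts: a
mid-year mean population count is one person-year per person for a
whole-year band, and an infant subcategory receives the under-1 count
multiplied by its width in years. The four sub-year categories — (0,1)
day, (1,7) days, (7,28) days, (28,365) days — tile the first year exactly
under the conversion 365 days = 1 year and half-open `[lower, upper)`
bounds; both conventions follow the age labels of the source format
("28–365 days"), and using 365.25 instead would break the tiling. The
representative age of a category is the arithmetic mean of its endpoints.
Countries whose infant deaths are not split into the four subcategories
are rejected at load time: the infant decline carries most of the signal,
and a coarse first year cannot support it. When calendar coverage differs
between countries, explicit per-country year lists are required; the
package never intersects periods silently.

Cause-of-death groups are ICD-10 chapters or code ranges. The predefined
aggregate `OTHER_DISEASES` (chapters I–XV without chapter II) isolates
deaths not attributed to neoplasms, external causes or the
perinatal/congenital chapters; `CACNS` (congenital anomalies of the
central nervous system) defaults to codes Q00–Q07 — the literature does
not fix a single canonical list, so the codes are an argument, not a
constant.

## Three-stage model selection in log–log scale

All inference happens on the points $(\ln x_i, \ln \mu_i)$ for the
categories whose midpoints fall in the analysis range, by default the
first ten years of life (with the standard grid: six points). Every stage
decides at $\alpha = 0.05$.

1. **Curvature.** OLS of $\ln\mu$ on $\{1, \ln x, (\ln x)^2\}$; the
   two-sided t-test of the quadratic coefficient decides whether a line is
   an adequate description. Requires $n \ge 4$.
2. **Two-parameter line.** OLS of $\ln\mu$ on $\ln x$ gives the slope
   $\gamma$ and intercept $\ln\mu_1$ (the model rate at age 1 year), a
   t-based confidence interval for $\gamma$ (level configurable, default
   95% — the conventional reporting bounds are treated as such an
   interval), and the adjusted coefficient of determination
   $\bar R^2 = 1-(1-R^2)(n-1)/(n-2)$.
3. **Nested inverse-proportion test.** The law $\mu = \mu_1/x$ is the
   line with $\gamma$ pinned at −1; its single parameter has the
   closed-form least-squares solution
   $\ln\mu_1 = \overline{\ln\mu_i + \ln x_i}$. The hypothesis that the
   free line fits no better is tested with
   $F = (\mathrm{RSS}_{inv}-\mathrm{RSS}_{lin})/(\mathrm{RSS}_{lin}/(n-2))$
   on $(1, n-2)$ degrees of freedom — algebraically the square of the t
   statistic for $(\gamma+1)/\mathrm{se}(\gamma)$, an identity the tests
   check to $10^{-10}$ against an independent normal-equations oracle.
   $R_b^2 = 1 - \mathrm{RSS}_{inv}/\mathrm{TSS}$ is reported without a
   degrees-of-freedom adjustment; with one parameter against two this is
   the definition that can sit either above or below $\bar R^2$, the
   pattern seen in published per-population tables, which is why it was
   chosen over an adjusted variant.

Supporting checks: `test_zero_slope()` (t-test of $\gamma = 0$; the
age-independence pattern characteristic of neoplasm mortality after
infancy), `find_minimum()` (lowest-rate category, ties broken toward the
younger category so that a flat minimum is reported at its onset), and
`test_residual_independence()` — Spearman rank correlation between
residuals and $\ln x$, with the **exact permutation distribution** when
$n \le 8$ (720 permutations at $n=6$) and the asymptotic approximation
otherwise. Two properties of this last test deserve honesty: (i) at
$n = 6$ the permutation distribution is discrete, so the attainable size
is below the nominal 5% (about 2.7% in simulation); (ii) applied to the
residuals of the two-parameter fit it is *structurally conservative*,
because OLS residuals are orthogonal to the regressor by construction —
it is informative for the inverse-model residuals, where a slope
genuinely different from −1 leaves a monotone trend.

**Degenerate inputs.** Perfect fits arise legitimately (noise-free
generator profiles); every test guards them instead of dividing by zero:
$\mathrm{RSS}_{lin} = 0$ with an exact inverse fit returns $F = 0$,
$p = 1$; a perfect line with $\gamma \ne -1$ returns $p = 0$; all-zero
residuals give the permutation test $p = 1$. Zero-death categories are
never dropped silently: they are flagged, and log-scale fitting refuses
them with a message naming the categories, because the statistically
correct remedy is wider pooling.

## The congenital-frailty (TCIR) layer

The mechanism studied here assumes each newborn carries a **constant
lifelong risk** $r$ (individual ageing over childhood is neglected), with
severe risks rare in proportion to their severity. A cohort with risk
density $f(r) \propto 1/r$ on $(r_{\min}, r_{\max})$ has marginal hazard

$$h(x) = \frac{E[r e^{-rx}]}{E[e^{-rx}]}
       = \frac{e^{-r_{\min}x} - e^{-r_{\max}x}}
              {x\,[E_1(r_{\min}x) - E_1(r_{\max}x)]},$$

which scales as $1/x$ throughout the window
$1/r_{\max} \ll x \ll 1/r_{\min}$: sequential extinction of the
highest-risk individuals produces the inverse law without any individual
ageing. The local log–log slope in that window is
$-1 - 1/\ln(1/(r_{\min}x))$ up to constants — slightly *steeper* than −1
at finite truncation, which is why the simulator's fitted slope sits near
−1.02 rather than −1.00 with the default bounds; the property tests
bound the local slope in (−1.05, −0.95).

When $r_{\max}$ is small enough that $r_{\max} x \ll 1$ near birth, the
hazard bends: $\mu(x) = (\mu_1/x)\,(1 - e^{-r_{\max}x})$, with limit
$\mu_1 r_{\max}$ at $x = 0$ and the pure inverse law for
$r_{\max} x \gg 1$. This two-parameter form describes the "bending"
trajectories of most disease-specific groups: flat or slowly declining in
infancy, inverse-proportional over ages 1–10.

**Numerical choices.** `fit_bending()` minimises the log-scale residual
sum (log residuals stabilise variance across rates spanning four orders
of magnitude). Because $\ln\mu_1$ enters linearly given $r_{\max}$, the
level is profiled out in closed form and the optimisation is a
one-dimensional search over $\log r_{\max}$ (golden-section/parabolic,
tolerance $10^{-10}$, evaluation cap 500) on an interval that places the
bend anywhere from far below the youngest to far above the oldest
category. This is exact on noise-free data to ~$10^{-9}$, where a
two-dimensional simplex stalls near $10^{-6}$. On data with no bend the
estimate of $r_{\max}$ is unidentified upward; the fit reports the
boundary plateau honestly (`at_bound = TRUE`) rather than fabricating a
finite bend.

The simulator (`simulate_frailty()`) draws risks by inverse-CDF
($r = r_{\min}(r_{\max}/r_{\min})^U$), simulates exponential death times,
and accumulates **exact** per-category exposures — each individual
contributes $\min(t_{death}, \mathrm{upper}) - \mathrm{lower}$ within
each category — precisely so that it can audit the stationary
approximation used on census data rather than inherit it. The quadrature
oracle (`mixture_hazard_oracle()`) integrates on the log-risk scale,
split at the integrand's knee $s = -\ln x$, with relative tolerance
$10^{-10}$; tests cross-check it against the closed form above via the
exponential integral and against bin-level expected deaths and exposures.

## The synthetic-data generator

`generate_dataset()` emulates the tidy WHO layout: per country, year,
cause and category, expected deaths are
$\lambda = \mathrm{profile}(x_i) \cdot L_i$ with $L_i$ from the
stationary rule, and counts are Poisson draws under a mandatory seed.
Poisson (not binomial) noise is appropriate because rates are far below 1
per person-year everywhere except the first day of life; a binomial
switch is provided for that band. Profiles encode the four empirical
shapes: `inverse`, `bending`, `constant`, and `neoplasm` (inverse during
infancy, constant afterwards). A TOTAL cause is never drawn independently
— it is the sum of generated components, so conservation across cause
groups holds by construction. The truth record (every $\lambda$ and
parameter) is always emitted beside the data; tests compare against it
rather than re-deriving it.

What the generator deliberately does **not** emulate: secular trends,
seasonality, migration, cohort effects, age heaping, and
between-country differences in cause-of-death coding quality. Passing
tests therefore demonstrate that the inferential machinery is correct
under the stated sampling model, not that real registration data satisfy
that model.

**Default study conditions.** The frailty simulator's defaults are a
cohort of $2\times10^6$ individuals with reciprocal risks on
$(10^{-18}, 10^{4})$ per year — bounds wide enough that the inverse
window covers all of childhood, with the slope fitted over the six
categories below 10 years. Count-level experiments use one to two
countries with mean band populations of $10^5$–$10^6$ and inverse levels
of 2–4 per 1000 person-years at age 1 — infant categories then carry
counts of order $10^2$–$10^4$, comparable to a mid-sized country pooled
over a few years. Replicate counts are 60–200 in the module tests and
1000 for the type-I-error experiment; with these sizes the full suite
runs in well under a minute while leaving binomial error bars of
±1–2 percentage points on empirical rates.

## Reporting conventions

$\mu_1$ is reported per 1000 person-years by default; the scale is an
argument and shifts only $\ln\mu_1$, never $\gamma$, $R^2$, $R_b^2$ or
any p-value. (Published per-population tables print levels whose unit is
not stated; magnitudes suggest a per-100,000 scale for national
populations — another reason the scale is configurable rather than
fixed.) `format_report()` renders slopes to 3 decimals, interval bounds
to 2, levels to 1, coefficients of determination to 4 and p-values to 2,
the conventional printed precision. Post-infancy analyses (zero-slope and
bending-regime checks) use the range (1, 15) years: the open interval
(1, 10) contains only two category midpoints of the standard grid, too
few to fit, while (1, 15) supplies three.

## Known limitations

* Inference assumes homoscedastic Gaussian errors in log scale; Poisson
  sampling makes log-rate variances proportional to $1/\lambda_i$, which
  vary by a factor of a few across categories. The simulated type-I error
  of the nested F-test under an inverse truth is accordingly close to,
  but a shade above, the nominal 5%.
* The stationary-exposure rule is an approximation for the infant bands
  when mortality within the first year is very high; the frailty
  simulator's exact accounting exists precisely to quantify that gap.
* The bending fit estimates $r_{\max}$ only when the data span both
  regimes; with no category below the bend the parameter is unidentified
  and reported as such.
* Parsing raw fixed-column WHO dumps, ICD-8/9 coding, life-table
  construction and adult (Gompertz) mortality are out of scope.
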