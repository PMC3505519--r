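---
title: "The JZS Bayes factor for correlation and partial correlation: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The JZS Bayes factor for correlation and partial correlation: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jzscor)
```

## The testing problem

A Pearson correlation test asks whether two variables are linearly related
(`H1: ρ ≠ 0`) or not (`H0: ρ = 0`); the partial-correlation test asks the
same after the linear effect of a control variable has been removed. The
frequentist answer is a t statistic,

$$t = r\sqrt{\frac{n-2}{1-r^2}} \quad (df = n-2), \qquad
  t = r_{XY|Z}\sqrt{\frac{n-3}{1-r_{XY|Z}^2}} \quad (df = n-3),$$

whose p value can reject `H0` but can never support it. The Bayesian answer
is the Bayes factor
$BF_{10} = p(Y \mid H_1)/p(Y \mid H_0)$, the ratio of marginal likelihoods,
which updates prior into posterior model odds and quantifies evidence in
either direction.

## Model and prior

Both tests are cast as variable selection between nested linear regressions.
For the plain correlation, `M0` is intercept-only and `M1` adds the single
predictor; since $R^2 = r^2$ in simple regression, testing `ρ = 0` is
testing `β = 0`. The default prior is Zellner's g-prior on the regression
coefficients,
$\beta \mid \phi, g \sim N\!\big(0, \tfrac{g}{\phi}(X^TX)^{-1}\big)$, with
Jeffreys priors on intercept and error precision. A single fixed g is
hard to choose and exposes the Jeffreys–Lindley–Bartlett paradox (below);
the JZS resolution places an inverse-gamma(1/2, n/2) prior on g,
$p(g) = \frac{(n/2)^{1/2}}{\Gamma(1/2)} g^{-3/2} e^{-n/(2g)}$, which makes
the implied prior on β Cauchy with unit-information scale. The intercept,
coefficients and precision all marginalize analytically; what remains is a
one-dimensional integral over g:

$$BF_{10} = \frac{(n/2)^{1/2}}{\Gamma(1/2)} \int_0^\infty
  (1+g)^{(n-2)/2}\,\big[1+(1-r^2)g\big]^{-(n-1)/2} g^{-3/2} e^{-n/(2g)}\,dg.$$

The partial test compares the control-only model ($p_0$ coefficients, fit
$R_0^2$) with the model adding the tested variable ($p_1$ coefficients,
$R_1^2$); its Bayes factor is the ratio of two integrals of the same family
with exponent $(n-1-p)/2$ on $(1+g)$. With the dependent variable X and
control Z, $R_0^2 = r_{XZ}^2$ and
$R_1^2 = r_{XY|Z}^2(1-r_{XZ}^2) + r_{XZ}^2$, so the whole analysis runs from
the three pairwise sample correlations and n. With $p_0 = 0$ and
$R_0^2 = 0$ the denominator integral is exactly
$\Gamma(1/2)/(n/2)^{1/2}$ and the ratio reduces to the plain correlation
Bayes factor — an identity the test suite checks numerically across a grid.

## Numerical evaluation

The integrand underflows and overflows double precision long before n
reaches interesting sizes, so it is never evaluated directly:

* substitution `u = g/(1+g)` maps the domain to (0, 1);
* the integrand is computed in log space; its maximum M is located by a
  257-point grid scan plus golden-section refinement, and
  `exp(log f − M)` is integrated with `stats::integrate` (adaptive QAGS,
  `rel.tol = 1e-10`, `abs.tol = 0`), the result rescaled by `exp(M)` on the
  log scale.

Two decimals — the precision at which such Bayes factors are usually read —
need far less than `1e-10`, but the headroom keeps differences of log Bayes
factors meaningful downstream, and the achieved error estimate is reported
in every result. Log-scale evaluation keeps `log BF` finite for n at least
10⁴ (tested). Degenerate inputs are explicit: `|r| = 1` (or `R₁² = 1`) makes
the marginal-likelihood ratio genuinely unbounded, and is returned as `Inf`
with a `divergent` flag rather than a large number. A correlation triple
whose implied partial correlation falls outside [−1, 1] is not a
correlation matrix and is rejected, not clamped.

The suite cross-checks the quadrature against an independent
double-exponential integrator (`pracma::quadinf`) on the untransformed
integrand over a grid `|r| ≤ 0.9, n ≤ 200` at `1e-6` relative error, and
against values computed once with 50-digit multiprecision quadrature and
frozen as constants.

## Evidence categories and priors over hypotheses

`classify_bf()` maps `BF₁₀` onto Jeffreys' verbal scale (Anecdotal 1–3,
Substantial 3–10, Strong 10–30, Very Strong 30–100, Decisive > 100, mirror
reciprocals for `H0`, "No evidence" at exactly 1). The published scheme
leaves endpoint ownership unstated; here a boundary value belongs to the
stronger adjacent category (BF = 3 is Substantial) — a deterministic,
documented choice on a measure-zero set. `posterior_from_bf()` converts a
Bayes factor and a prior `p(H1)` (default 0.5) into posterior model
probabilities via the odds identity.

## Sequential monitoring

Because the Bayes factor conditions only on observed data, it may be
recomputed after every observation without sampling-plan corrections.
`sequential_bf()` reports the full trajectory from `min_n` to n; the final
entry equals the full-sample test by construction. `min_n` defaults to 5:
the integral is defined from n = 3, but 3–4-point windows produce noisy,
divergence-prone values (any near-collinear triple), and 5 is the smallest
window we consider worth displaying; it is overridable. No stopping rule is
imposed — the package reports evidence, policy is the analyst's.

## Synthetic data

`generate()` draws multivariate normal samples with a specified correlation
matrix (eigendecomposition transform via `MASS::mvrnorm`; positive
semidefiniteness checked at tolerance 1e-10). The named fixtures reproduce
the printed sample sizes, moments and correlation targets of the three
worked examples — a meditation-and-visual-acuity follow-up (n = 54,
r = −.36), a Facebook-friends-and-gray-matter study (n = 40, r = .48) and an
interrupted-search developmental study (n = 40, pairwise .51/−.78/−.66) —
because the original raw observations were never published. Where a study
printed no moments, plausible magnitudes are fixed and documented
(`?fixture_meditation`). The optional `exact = TRUE` mode rotates the draw
so the empirical moments and correlations equal the targets exactly, which
lets demonstrations recover printed statistics from raw columns.

The generator emulates correlation structure only: marginals are exactly
normal, with none of the skew, bounds (proportions, counts), or outliers of
the real measurements. Passing tests therefore certify the inferential
machinery, not robustness to non-normality.

Simulation-based checks in the suite use these problem sizes, chosen to make
sampling behaviour visible while staying desk-scale: 200 streams of n = 100
for sequential consistency (median final `BF₁₀ > 3` at ρ = 0.6, < 1 at
ρ = 0), and 100 seeds of n = 200 for parameter recovery (`BF₁₀ > 10` in at
least 90% of draws at ρ = 0.5; `BF₁₀ < 1` in at least 70% at ρ = 0).

## The fixed-g paradox

`fixed_g_bf_cor()` computes the Bayes factor conditional on one g — the JZS
integrand ratio with a point mass in place of the mixture,
$BF_{10}(g) = (1+g)^{(n-2)/2}[1+(1-r^2)g]^{-(n-1)/2}$ (no closed form is
printed in the source literature; this is the unique g-conditional version
consistent with the mixture formulation). Since the exponents sum to
−1/2 in the leading order, $BF_{10}(g) \sim c\,g^{-1/2} \to 0$ as
$g \to \infty$ for any fixed data: inflating the alternative's prior
vagueness manufactures support for the null. `paradox_curve()` traces this
decay over a g grid; the mixture prior on g is what removes the need to pick
g and avoids the paradox.

## Rounding and reproduction of printed values

All computation is at full floating precision; printed two-decimal values
are matched after rounding. The source examples mix rounded and unrounded
inputs: the meditation correlation is printed both as −.36 and as the ratio
−589/1629, and only the unrounded ratio reproduces the printed t = −2.80.
The same applies to its Bayes factor, so the package's reproduction script
uses the ratio there. The Facebook example prints only r = .48, which under
the integral above yields BF₁₀ = 16.12; the published 17.87 corresponds to
an unrounded data correlation near 0.484 that was never printed, and the
package reports the value computed from the available input rather than the
unreachable printed one. The partial-correlation example, whose inputs are
printed to seven decimals, reproduces exactly (BF₁₀ = 0.13).

## Known limitations

* Two-sided tests only; no one-sided Bayes factors, no posterior
  distribution over ρ, no confidence/credible intervals.
* One control variable in the partial test's convenience interfaces (the
  integral itself accepts any nested pair via `jzs_bf_pcor()`).
* Missing data are handled by complete-case deletion within the tested
  variable set, with a logged count — defensible as a default, not a
  substitute for thought about missingness.
* Normal-theory model: heavy tails or nonlinear association are outside the
  model for both the frequentist and the Bayesian branch.
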