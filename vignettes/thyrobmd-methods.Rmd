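---
title: "Methods: from serum hormones to model-averaged benchmark doses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from serum hormones to model-averaged benchmark doses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrobmd)
```

thyrobmd implements a complete analysis path for biomonitoring cohorts in
which a blood exposure (here nickel, in µg/L) is related to thyroid
function: derived homeostasis parameters, reference-range quantalization,
a Spearman screen, and a model-averaged quantal benchmark-dose (BMD)
analysis with bootstrap confidence limits. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical choices,
so that results can be interpreted — and distrusted — for the right
reasons.

## 1. SPINA structure parameters

Serum TSH, fT4 and fT3 are snapshots of a feedback loop, and single
hormone levels can be poor summaries of gland function. The structure
parameter inference approach (SPINA) inverts a small steady-state model of
the pituitary–thyroid axis to obtain two rate parameters:

* **GT** (secretory capacity, pmol/s) — the maximum T4 release rate at
  full TSH stimulation:
  $$ G_T = \frac{\beta_T\,(D_T + [TSH])\,(1 + K_{41}[TBG] + K_{42}[TBPA])\,[fT4]}{\alpha_T\,[TSH]} $$
* **GD** (sum activity of peripheral deiodinases, nmol/s) — the T3
  production capacity from T4:
  $$ G_D = \frac{\beta_{31}\,(K_{M1} + [fT4])\,(1 + K_{30}[TBG])\,[fT3]}{\alpha_{31}\,[fT4]} $$

The constants (dilution factors, clearance exponents, dissociation
constants, standard binding-protein concentrations) are the standard
published values and are exposed through `spina_constants()`, so a
laboratory using different binding-protein assumptions can override any of
them. Three unit conventions make the formulas dimensionally consistent,
and the implementation applies them internally: TSH in µIU/ml is
numerically identical to mIU/L; all dissociation-constant products are
evaluated in mol/L (TBG nmol/L, TBPA µmol/L, fT4/fT3 pmol/L, K~M1~
nmol/L); GT is reported in pmol/s and GD in nmol/s. With these
conventions the two plasma-binding factors are the dimensionless numbers
6901 and 601, and interquartile hormone panels map into the adult
reference ranges GT 1.4–8.7 pmol/s and GD 20–60 nmol/s. The *full*
in-range hormone rectangle does not: a low-normal TSH combined with
high-normal fT4 yields GT well above 8.7 pmol/s, which is exactly the
discordance the parameter is designed to flag.

Two deliberate choices: the T3 binding factor is implemented as
$1 + K_{30}[TBG]$, the form consistent with the parameter's derivation and
with the dimensionless-factor requirement; and the constant set carries a
logarithmic-model correction coefficient (`beta_corr = 0.1345`) that
neither equation uses — it is stored for completeness and provenance only.

Missingness is propagated, never imputed: GT is missing iff TSH or fT4 is,
GD iff fT4 or fT3 is (or fT4 = 0, where the quotient is undefined).

## 2. Quantalization

BMD analysis of this design treats each endpoint as quantal: an indicator
that the subject's value lies outside the clinical reference range.
`classify_quantal()` uses closed intervals (boundary values are in-range,
the usual clinical reading of a printed range such as 0.270–4.20), and
`quantalize_cohort()` drops missing values per endpoint rather than per
subject, because each assay has its own availability. Values below an
analytical limit of detection are used as reported; the package does no
LOD substitution. Reference ranges are a data frame
(`reference_ranges()`), overridable per endpoint.

## 3. Descriptive statistics and the Spearman screen

Quartiles use linear interpolation between order statistics (type 7, the
default convention of most statistical software); when comparing against
tables produced by other packages, allow a percentile-convention tolerance
of a couple of percent. Exceedance percentages use a strict inequality
(the fraction of subjects *above* a candidate BMDL).

The exposure–endpoint screen is Spearman's rank correlation on
pairwise-complete records (the choice between pairwise- and listwise-
complete is ambiguous in this design; pairwise keeps the most data and is
what `spearman_ci()` implements). Two-sided p-values use the
t approximation $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom;
the 95% CI uses the Fisher z transform with the Fieller-adjusted standard
error $\sqrt{1.06/(n-3)}$. For n ≤ 10 the t approximation is checked in
the test suite against exact permutation enumeration. No multiplicity
correction is applied across the endpoint × stratum grid — the screen is
descriptive, and consumers should treat marginal p-values accordingly.

## 4. The benchmark-dose engine

### Model suite and likelihood

`ma_bmd()` fits seven classical quantal dose-response families — logistic,
probit, log-logistic, log-probit, Weibull, gamma and two-stage — by
maximising the individual-level Bernoulli log-likelihood
$\sum_i [y_i \ln P(d_i) + (1-y_i)\ln(1-P(d_i))]$. Individual-level rather
than grouped-bin likelihood matches a biomonitoring design where every
subject carries a distinct exposure. Fits use box-constrained L-BFGS-B
with analytic gradients on internally rescaled doses (d/max d), from 10
starting points (a Latin-hypercube sample of the constraint box plus the
box centre); the best converged likelihood is kept. Constraints keep every
curve nondecreasing and the extra-risk inversion well posed: backgrounds
$a \in [0, 1-10^{-6}]$, slopes/shapes bounded below by $10^{-2}$ on the
scaled-dose axis, log-locations confined to a ±15 window around the
observed log-dose range. Dose-independent or single-outcome-class data
collapse to the background-only model and are flagged degenerate.

### BMD definition

The benchmark response is **extra risk**: the BMD solves
$P(BMD) = P_0 + BMR\,(1 - P_0)$ with $P_0$ the fitted background and
BMR = 0.10 by default ("10% increased risk"). Extra risk is the standard
choice for quantal data in regulatory BMD practice. The inversion is a
bisection on log-dose to relative tolerance $10^{-6}$ inside the window
[min dose × 10⁻⁶, max dose × 10⁶]; a curve too flat to reach the
benchmark inside the window is *censored* at the window bound, recorded as
such, never silently dropped.

### Model averaging and the bootstrap

Per-model AIC ($2k - 2\ln L$) gives Akaike weights
$w_k \propto e^{-\Delta_k/2}$; the averaged curve is
$\hat P(d) = \sum_k w_k P_k(d)$ and the point estimate inverts $\hat P$.
Confidence limits come from a parametric bootstrap of the averaged model
(Wheeler–Bailer style): each of 200 iterations redraws outcomes as
Bernoulli($\hat P(d_i)$) at the observed doses, refits the entire suite,
recomputes the weights and re-inverts. BMDL and BMDU are the 5th and 95th
percentiles of the bootstrap BMD distribution — one-sided 95% limits,
forming a two-sided 90% interval. Censored iterations enter the
percentiles at the window bound and are counted; more than 50% censoring
flags the result `unreliable`, because near-flat dose-response data
produce astronomically wide intervals that should be displayed as such
rather than hidden. The interval-width diagnostic `bmdi_ratio()` applies
the conventional rule that BMDU/BMDL < 10 marks a narrow (reportable)
interval.

Bootstrap refits are warm-started from the full-data fit plus one fresh
Latin-hypercube start, and tolerate a looser optimiser stop
(`factr = 1e8`): each refit's likelihood error is orders of magnitude
below the Monte-Carlo spread the percentiles integrate over. The full
10-start search is reserved for the point-estimate fit, where a missed
global optimum would bias everything downstream.

Everything is deterministic given (data, configuration, seed): the master
seed drives the multistarts and the bootstrap draws, and stratified runs
derive per-cell seeds from the master seed and the cell index.

### Covariates

Sex (and health status) enter as *stratified* runs — separate fits for
men, women, the pooled population, healthy and unhealthy — mirroring the
tabular layout such studies report. Joint covariate-parameterised fitting
(shared shape, stratum-specific background) is deliberately out of scope.

## 5. The synthetic cohort generator

`sim_cohort()` exists so every stage is testable without human data. It
emulates a mixed clinical/healthy adult cohort of 217 men and 218 women:

* **Exposure**: blood Ni is log-normal per sex, parameterised by the
  observed median and quartile ratio (men: median 8.278, p25 2.902,
  p75 14.20 µg/L). A two-parameter log-normal cannot match three
  quartiles exactly; matching the median and the p75/p25 spread preserves
  the right skew, which is the feature the BMD analysis is sensitive to.
* **Hormones**: independent log-normal marginals matched the same way.
  Only marginal quartiles are emulated — the generator makes no claim
  about the true joint dependence of exposure and hormones, so passing
  tests demonstrate the pipeline's correctness, not any real-world
  association.
* **Missingness**: per-endpoint, per-sex Bernoulli deletion at rates
  matching assay-availability totals (5–15%).
* **Dose-response link** (optional): the probability that a chosen
  hormone falls outside its reference range follows a configurable
  quantal model of Ni; the hormone value is then drawn from its marginal
  *truncated* to the in- or out-of-range region, so the continuous value
  and the quantal indicator stay mutually consistent. The link is
  restricted to measured hormones: the SPINA endpoints are deterministic
  functions of the hormone draws and are always computed, never drawn
  (the more so because the descriptive table this generator is calibrated
  against carries internally inconsistent SPINA columns, consistent with
  a column swap at its source).
* **SPINA values** are computed downstream with `add_spina()`.

`sim_quantal()` is the lower-level harness for the BMD engine: doses from
a log-uniform or log-normal specification (default: log-normal calibrated
to the pooled Ni quartiles), outcomes Bernoulli under a family whose true
BMD10 is known in closed form.

## 6. Verification strategy and problem sizes

The test suite checks every kernel against an independent route: the
SPINA equations against a separate transcription (agreement to 10
significant digits on random in-range panels), each family's maximum
likelihood against an iterated grid-refinement search on a 50-subject
dataset (agreement to 10⁻⁶), the BMD inversion against closed forms
(10⁻⁶ relative), Spearman p-values against exact permutation enumeration
at n = 7, and quartiles against the interpolation convention by hand. The
bootstrap interval's operating characteristics are measured directly: 100
replicate cohorts of n = 400 from a log-logistic link with true
BMD10 = 5 µg/L and 5% background, nominal two-sided 90% coverage,
accepted within the binomial band 82–96%. These sizes keep the full suite
within a half-hour single-core run while leaving the Monte-Carlo error
small relative to the bands being checked.

## 7. Known limitations

* Stratified BMD runs ignore between-stratum information; small strata
  give wide, often censored intervals — visible in the `unreliable` flag.
* The bootstrap percentile BMDL can undercover when the averaged curve is
  nearly flat at low doses; the censoring counts are the diagnostic.
* The generator's independence assumptions (hormones mutually
  independent, exposure independent of hormones unless a link is
  configured) are stronger than any real cohort; use the link and the
  stress knobs for sensitivity checks, not for inference about real data.
* No age adjustment, no LOD imputation, no multiplicity control — all
  deliberate scope choices described above.
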