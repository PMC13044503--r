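---
title: "Modelling metastasis-free survival under time-varying hormonal treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metastasis-free survival under time-varying hormonal treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natmets)
```

## The model

`natmets` implements a natural-history model for oestrogen receptor-positive
(ER+) breast cancer that connects four processes in a single likelihood:

1. **Primary tumour growth.** A tumour starts as one malignant cell of
   diameter $d_{cell} = 0.01$ mm and grows exponentially in volume,
   $V(t, r) = V_{cell} e^{t/r}$, where $r$ is the *inverse growth rate* in
   years (the tumour volume multiplies by $e$ every $r$ years; the volume
   doubling time is $r \log 2$). Across women, $r \sim
   \mathrm{Gamma}(\tau_1, \tau_2)$ (shape/rate), reparameterised as the mean
   $\mu = \tau_1/\tau_2$ and dispersion $\psi = 1/\tau_1$ for
   interpretability. Tumours are spherical; diameters are the external
   interface (registries record millimetres) and volumes are used
   internally.

2. **Detection of the primary.** Symptomatic detection has hazard
   proportional to current volume, $h_V(v) = \eta v$ above the minimum
   detectable volume $v_0$ (diameter 0.5 mm). Mammography detects a tumour
   of diameter $d$ with probability $\mathrm{expit}(\beta_0 + \beta_1 d)$
   above 0.5 mm and never below. Under the *stable-disease* assumption
   (onset and detection processes constant in calendar time), the size at
   symptomatic detection follows a closed-form Pareto-type law, the
   asymptomatic population's size law is proportional to it divided by
   $\eta v$, and the inverse growth rate given a tumour of size $v$ is
   $\mathrm{Gamma}(\tau_1 + 1,\ \tau_2 + \eta(v - v_0))$ — larger tumours at
   detection are evidence of faster growth.

3. **Metastatic seeding.** Viable seedings (deposits that will grow to
   clinical detection) form a non-homogeneous Poisson process whose
   intensity is a power $k$ of the number of cell divisions; on the
   transformed scale the cumulative intensity up to time $t$ since onset is
   $\sigma (t/r)^{k+1}$. Seeding stops at primary diagnosis (surgery).
   $k = 4$ is fixed; $\sigma$ is estimated.

4. **Metastasis growth and the treatment effect.** A seeded metastasis
   grows from one cell with the same $r$ as its primary (perfect
   correlation) and is detected at a fixed diameter $d_m$ (estimated).
   After primary diagnosis, follow-up is split into consecutive periods;
   during period $j$ the metastasis inverse growth rate is multiplied by
   $\phi_j$. The main analysis has three periods — an untreated lead-in, a
   treatment period with $\phi_2 > 1$ (hormonal therapy is cytostatic: it
   slows growth rather than killing cells), and an untreated tail — with
   $\phi_1 = \phi_3 = 1$. A four-period variant (`carryover_schedule()`)
   adds a carryover window after treatment ends.

The induced law of the time $W$ from primary diagnosis to metastasis
detection, given $r$ and the primary volume $v$ at diagnosis, is a **cure
model** with three mass components: an atom at $w = 0$ (metastasis already
detectable at diagnosis, probability $1 - \exp\{-\sigma \log(v/v_m)^{k+1}\}$
when $v > v_m$), a continuous part, and a terminal *cure fraction*
$\exp\{-\sigma \log(v/V_{cell})^{k+1}\}$ — the probability of no viable
seeding before diagnosis, which depends on neither $r$ nor the treatment
schedule. All three evaluations use the single clamped form
$S_W(w) = \exp\{-\sigma\,\mathrm{clamp}(A_j(w), 0, \log(v/V_{cell}))^{k+1}\}$
with $A_j(w) = \log(v/v_m) + g(w)/r$ and $g(w)$ the $\phi$-discounted time
since diagnosis. This form makes continuity at period boundaries, the atom,
and the cure value structural identities rather than case analysis; the
printed piecewise expressions for the later periods are recovered by
expanding $g$ and are verified in the test suite by probability-mass
accounting (atom + integrated density + cure mass = 1 to $10^{-6}$ across
randomised sizes, growth rates and schedules).

At a period boundary the later period's branch is used (right-continuity);
the two branches agree there by continuity, so the convention is cosmetic
but fixed for determinism.

## Likelihood

Each patient contributes the joint density of tumour size at diagnosis,
metastasis-free follow-up, and screening history, conditional on the mode of
detection:

* symptomatic: $f_{V_{det}}(v)\,\int T(w \mid r, v)\, H(r)\, f(r \mid v)\,dr$;
* screen-detected: $\mathrm{sens}(d)\, \frac{f_{V_{det}}(v)}{\eta v} \int
  T(w \mid r, v)\, H(r)\, f(r \mid v)\, dr$,

where $T$ is the $W$ density (metastasis observed), the $W$ survival
(right-censored) or the $r$-free atom (metastasis at diagnosis), and $H(r)$
is the product over the woman's negative screens of one minus the
sensitivity at the back-calculated diameter $d\,e^{-\Delta/(3r)}$.

Two points deserve emphasis because both are easy to get wrong and both were
caught here by simulation-based parameter recovery:

* **Mode weighting.** The screen-detected size factor is the *unnormalised*
  asymptomatic prevalence mass $f_{V_{det}}(v)/(\eta v)$. Normalising it to
  a proper density (dividing by the parameter-dependent sojourn constant
  $C(\theta)$) looks natural but mis-weights the two detection modes: the
  probability of carrying an asymptomatic tumour at a screen is itself
  proportional to $C(\theta)$, which cancels the normaliser. With the
  normalised version the likelihood rewards parameter values implying short
  sojourns and the optimiser runs away from the truth on simulated cohorts.

* **The regular-screener ladder.** Cohorts of regular screeners attended
  biennial screens long before the oldest *recorded* one. If $H$ includes
  only recorded screens, the likelihood never charges slow-growth parameter
  values for the many earlier screens a long-lived asymptomatic tumour must
  have survived, and the likelihood is improper along the slow-growth
  direction (we observed it diverge to $\mu \sim e^{10}$). By default the
  ladder is therefore extended beyond the oldest recorded screen at the
  screening interval; each older screen contributes its back-calculated
  negativity factor, reaching exactly 1 once the implied diameter falls
  below 0.5 mm, so the product is finite for every $r$. Predictions for a
  stated patient profile (`predict_mfs()`) condition on exactly the given
  finite history; `cohort_loglik(..., extend_history = FALSE)` gives the
  recorded-screens-only contribution.

### Numerical integration over the growth rate

The integrand of the $r$-integral is only piecewise smooth: the cure clamp
of the $W$ law produces a kink (and, for observed events, a genuine jump of
the density to zero) at $r^\ast = g(w)/\log(v_m/V_{cell})$, a second kink
exists when $v < v_m$, and each recorded screen has a kink where its
back-calculated diameter crosses 0.5 mm. A single smooth quadrature rule
converges poorly across such points (we measured $10^{-2}$ relative errors
for event records with a global 60-node rule). The likelihood therefore
splits the integral into Gauss–Legendre panels at the record's own
breakpoints plus fixed posterior quantiles (so the bulk of the gamma mass
lies in panels) and a shifted Gauss–Laguerre tail. With `quad_order = 60`
(15-node panels, 30-node tail) the per-record contributions agree with
adaptive Gauss–Kronrod integration to better than $10^{-6}$ relative for the
recorded-history integrand. The ladder extension adds one small kink per
unrecorded screen; those are not panel boundaries, which bounds accuracy at
roughly $10^{-4}$ relative — immaterial for estimation, and the recorded-
history path retains the tight guarantee. `posterior_quadrature()` exposes
the plain generalised Gauss–Laguerre rule for *smooth* functionals of $r$;
it is not used where the integrand has kinks.

Log-likelihood contributions that underflow to $-\infty$ (model-impossible
records, e.g. a metastasis at diagnosis with the primary smaller than
$d_m$) are reported with their record indices, never silently dropped.

## Estimation

`fit_natmets()` maximises the cohort log-likelihood over the 8 transformed
parameters $(\log\mu, \log\psi, -\log\eta, \beta_0, \beta_1, \log\sigma,
\log\phi_2, \log d_m)$ with Nelder–Mead: derivative-free, and robust to the
pronounced ridge between $\log\phi_2$ and $\log d_m$ (both delay metastasis
detection; their estimates are strongly negatively correlated, which the
test suite checks via the curvature of the likelihood surface). Parameters
are scaled by their starting magnitudes (`parscale`), and a degenerate
simplex triggers restarts from the terminal point. Invalid regions of the
transformed space (e.g. a non-positive sensitivity slope) are rejected with
a large objective value. For cohorts without screening information the
gamma shape and rate are not separately identifiable and
`restrict = "tau_equal"` imposes $\tau_1 = \tau_2$ (i.e. $\mu = 1$).

Confidence intervals come from a nonparametric bootstrap
(`bootstrap_natmets()`): patients are resampled with replacement, each
replicate refits from the point estimate under its own derived seed, and
percentile intervals are reported; 1500 replicates is the production
setting, while tests use single-digit counts to exercise the machinery.

## The synthetic-cohort generator

`simulate_cohort()` is the package's data-generating reference and the
source of every test fixture. For each woman it draws $r$, a symptomatic
detection time from the volume-proportional hazard, and biennial screen
outcomes with a uniform random phase relative to tumour onset; detection is
the earlier of the two. Because the screening phase is uniform per woman
and every onset is followed to detection, the incident cases are
distributed exactly as the stable-disease steady state — this replaces a
calendar onset window with burn-in, which would sample the same law at
higher cost. The first viable seeding is drawn by inversion and truncated
at diagnosis; metastasis detection times follow the deterministic
seeding-to-detection map under the woman's schedule.

Defaults define the emulated study conditions: biennial screening with
perfect attendance (regular screeners), treatment starting $t_1 = 0.25$
years after diagnosis (a typical surgery-to-adjuvant delay) for $t_2 = 5$
years, administrative censoring drawn uniformly on $(0, 15)$ years
(staggered registry entry with a fixed closing date), and a recorded
screening history spanning the 8 years before diagnosis (a registry-like
window; the likelihood's ladder extension reconstructs the older screens
exactly, since they lie on the same biennial grid). The generator keeps
latent columns (`r_true`, `t_det_years`, `ts_years`, `w_true_years`) for
validation; `write_cohort()` drops them.

What the generator does *not* emulate: imperfect attendance patterns of
real programmes (an `attendance` probability exists but the likelihood
treats unattended screens as absent), calendar trends in onset or detection,
measurement error in recorded diameters, competing mortality, and
treatment assignment that depends on unobservables. Passing the recovery
tests therefore demonstrates internal consistency of likelihood and model,
not robustness to these real-data features.

## Prediction and goodness of fit

`predict_mfs()` computes model-based metastasis-free survival conditional
on no metastasis at diagnosis for a given diameter, screening history and
hypothetical schedule, by integrating the $W$ survival against the
size-conditional growth-rate law weighted by the history factors, and
normalising by the same integral at $w = 0$. `compare_durations()` encodes
the standard scenario — treatment from diagnosis for 5 versus 10 years,
three biennial prior negative screens, the most recent one year before
diagnosis for symptomatic cases (two years for screen-detected) — and
reports the area between the paired curves as the expected metastasis-free
time gained. At the reference parameters the gain grows with diameter up to
roughly 25 mm and then turns over: for very large tumours most metastases
surface during the first five years, which both schedules share.

For observed cohorts with treatment switching, `extended_km()` implements
the product-limit estimator whose risk sets are re-evaluated at every event
time according to current treatment status, and `model_based_km()` its
model-based analogue: time is cut into `dt`-intervals (0.1 years by
default), the model-predicted conditional survival over each interval is
averaged within the observed at-risk groups, and the sequential products
are plotted against the extended Kaplan–Meier steps. Halving `dt` moves the
curves by well under 0.2% on simulated reference cohorts.

## Problem sizes and numerical settings used by the tests

The test suite and acceptance checks run at sizes chosen to exercise every
code path at interactive cost: simulator-versus-analytic distribution
checks at $n = 10^4$, parameter recovery at $n = 2000$ with `quad_order =
40`, bootstrap machinery at $n = 250$ with single-digit replicate counts.
Recovery intervals for the $n = 2000$ design were calibrated once from ten
independent simulate-and-refit replicates (mean ± $t_{0.975}$ prediction
bands on the transformed scale) and are frozen in the acceptance test.
Production analyses would use the full cohort, `quad_order = 60` (the
default) and 1500 bootstrap replicates.

## Known limitations

The model inherits its strong structural assumptions: exponential net
growth, spherical tumours, perfectly correlated primary and metastasis
growth rates, a single fixed detection volume for metastases, one common
multiplicative treatment effect for all patients (tamoxifen and aromatase
inhibitors pooled), no dormancy sub-process, and no chemotherapy effect on
seeded metastases. $\phi_2$ and $d_m$ are separately weakly identified —
interpret them jointly. The stable-disease assumption is structural: the
population distributions and the screen-detected likelihood are only exact
in steady state. Dates are continuous years throughout; day conversions use
365.25 days per year.
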