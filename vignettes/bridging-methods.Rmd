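---
title: "Robust Bayesian bridging of dose-toxicity information: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Bayesian bridging of dose-toxicity information: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgetox)
```

## The problem

A phase I oncology dose-escalation trial estimates the maximum tolerated
dose (MTD): the dose whose probability of a dose-limiting toxicity (DLT)
is closest to a target, here 25%.  When the trial is run sequentially in
several patient subgroups or geographic regions, two kinds of co-data are
available for the later trials: completed animal toxicology studies, and
the accumulating human data from the earlier region.  Both are useful and
both can mislead -- animal physiology may not translate, and regions may
differ intrinsically (genetics) or extrinsically (diagnostic practice,
environment).  `bridgetox` implements a Bayesian hierarchical model that
borrows from both sources while retaining the ability to discard either
quickly when the data contradict it, together with the escalation
machinery (overdose-controlled dose recommendations, safety stopping, MTD
declaration) and a simulator for operating-characteristics studies.

## The model

### Dose-toxicity curves and dose rescaling

Every study, animal or human, is described by a two-parameter logistic
curve on a common "average human" dosing scale.  For animal study $i$ of
species $A_i$ with dose $d$ (mg/kg, native scale):

$$\mathrm{logit}\, p = \theta_{1i} + e^{\theta_{2i}}
  \log(\delta_{A_i}\, d / d_{\mathrm{ref}}),$$

where $\delta_{A_i} > 0$ is a species-specific *translation* parameter
mapping animal doses onto the human scale, with a log-normal prior
(defaults: rat $LN(-1.820, 0.323^2)$, monkey $LN(-1.127, 0.273^2)$), and
$d_{\mathrm{ref}}$ (default 5 mg/kg) is a reference dose, conventionally
the most probable human MTD.  The slope is parameterised on the log scale
($e^{\theta_2}$), so every curve is strictly increasing in dose and the
sampler never needs a positivity constraint.

Human subgroup $\ell$ uses the same curve with parameters
$\gamma_\ell = (\gamma_{1\ell}, \gamma_{2\ell})$, the translation fixed
at 1, and a subgroup-specific *bridging* parameter $\epsilon_\ell$
rescaling doses for intrinsic/extrinsic differences between subgroups.
Its prior is $N(1, \nu^2)$ truncated to $(0, 2)$, symmetric about the
mode 1; the default $\nu = 0.255$ puts 95% of the mass on
$[0.5, 1.5]$, i.e. region-specific MTDs are a priori unlikely to differ
by more than half a fold.  Increase $\nu$ if larger differences are
plausible.

### Hierarchy and the exchangeability mixture

Study-level animal parameters are exchangeable within species,
$\theta_i \sim BVN(\mu_{A_i}, \Psi)$, and species means are exchangeable
across species, $\mu_{S_k} \sim BVN(m, \Sigma)$ (the "supra-species"
level).  Each covariance is parameterised by two standard deviations and
a correlation, exactly as the model is usually printed:
$\Psi(\tau_1, \tau_2, \rho)$, $\Sigma(\sigma_1, \sigma_2, \kappa)$.

Each human subgroup's $\gamma_\ell$ follows an
exchangeability/non-exchangeability (EXNEX) mixture with prespecified
weights: with probability $w_{\ell S_k}$ it is exchangeable with the
animal-species population $BVN(\mu_{S_k}, \Psi)$; with probability
$w_{\ell H}$ with a human-only population $BVN(\mu_H, \Phi)$,
$\Phi(\tau_3, \tau_4, \eta)$; and with probability $w_{\ell R}$ it is
non-exchangeable, following its own weakly-informative
$BVN(m_{0\ell}, R_{0\ell})$ (defaults: means $(-1.099, 0)$, sds
$(2, 1)$, zero correlation).  The robust component is what allows an
outlying subgroup to shrug off all co-data.

Hyperpriors (defaults, chosen so each human risk has a wide 95% prior
interval): $m_1, \mu_{1H} \sim N(-1.099, 1.98^2)$ -- note
$\mathrm{logit}^{-1}(-1.099) = 0.25$, centring the risk at
$d_{\mathrm{ref}}$ on the target; $m_2, \mu_{2H} \sim N(0, 0.99^2)$;
half-normal scales $\tau_1 \sim HN(0.5)$, $\tau_2 \sim HN(0.25)$
(moderate-to-substantial between-study heterogeneity within species),
$\tau_3 \sim HN(0.25)$, $\tau_4 \sim HN(0.125)$ (small-to-moderate
between-subgroup heterogeneity), $\sigma_1 \sim HN(1)$,
$\sigma_2 \sim HN(0.5)$; correlations uniform on $(-1, 1)$.  Slope
scales are half the intercept scales throughout because slopes of
dose-toxicity curves tend to be more similar across studies than
intercepts.

The normal priors on $m$ and $\mu_H$ are untruncated; nothing in the
model requires otherwise.

## Posterior computation

No general-purpose MCMC engine is assumed; the package ships a compiled
adaptive Metropolis-within-Gibbs sampler (`src/sampler.cpp`):

* componentwise Gaussian random walks with Roberts-Rosenthal step-size
  adaptation during burn-in (frozen afterwards, so the retained chain is
  a fixed Markov kernel), targeting 44% acceptance; parameters with
  bounded support (sds, correlations, $\epsilon$, $\delta$) reject
  out-of-support proposals;
* the heterogeneity sds and correlations receive extra sweeps per
  iteration -- they are cheap to evaluate and gate the mixing of
  everything above them;
* population means $\mu_{S_k}$, $m$, $\mu_H$ have conjugate bivariate
  normal full conditionals and are drawn exactly (Gibbs);
* each data-bearing subgroup's $(\gamma_1, \gamma_2)$ pair is updated
  jointly by an adaptive Metropolis step with empirical proposal
  covariance, against the *indicator-marginalised* mixture density; the
  latent component indicator $z_\ell$ is then immediately redrawn from
  its exact categorical conditional, keeping the collapsed move valid.
  Marginalising the indicator during the $\gamma$ update removes the
  slow mode-switching that a conditional-on-$z$ walk exhibits;
* for a subgroup with no observations (e.g. a trial that has not
  started), $\gamma_\ell$ and $\epsilon_\ell$ are drawn exactly from
  their conditional distributions.  This is also how meta-analytic
  predictive (MAP) priors arise: include the future subgroup in the fit
  with no data, or use `dlt_risk(..., map = TRUE)`, which generates
  fresh mixture draws from the hyperparameters -- the two routes target
  the same distribution.

Convergence is flagged with split-$\widehat R$ (each chain split in
half) on the subgroup parameters, bridging parameters and population
means; a fit with any $\widehat R > 1.05$ is marked `unconverged`.  The
threshold is a conservative default -- the reference analyses never
state a diagnostic.  Inside the simulator an unconverged interim fit is
retried once with doubled iterations and the trial is recorded as
*aborted* (never silently dropped) if the retry also fails.

Identical seeds and settings reproduce draws exactly.  The default
`mcmc_settings()` mirror the reference configuration (2 chains of
15,000 iterations, 5000 burn-in); `sim_mcmc_settings()` (1 chain,
6000/1500) is the simulator's reduced default, sized on this package's
convergence-flag behaviour, not on any operating characteristic.

## Decision rules

Per dose, interval probabilities classify the sampled risk into
under-dosing $[0, 0.16)$, the target band $[0.16, 0.33)$ and overdosing
$[0.33, 1]$; the overdose interval is closed on the left, so a risk of
exactly 0.33 counts as overdosing.

* **Starting dose** (bridging trial): the highest dose with
  $P(p < 0.16 \mid \text{co-data}) > 0.85$; if none qualifies the trial
  is not started and is recorded as stopped for safety at cohort 0 (a
  case the escalation literature leaves open).
* **Escalation** (cohorts of 3, maximum 24 patients): the next cohort
  receives the highest dose with
  $P(p \geq 0.33 \mid \text{data}) \leq 0.25$, capped at one level above
  the highest dose administered so far (no skipping).  De-escalation is
  permitted: the criterion is a maximum over the whole panel, not
  relative to the current dose.  If no dose, including the lowest,
  satisfies the constraint, the trial stops for safety -- this
  operationalises "the posterior risk of overdosing is too high", which
  is not otherwise quantified.
* **MTD declaration**: only trials treating all 24 patients declare an
  MTD -- the administered dose that satisfies the overdose constraint
  and whose posterior median risk is closest to 0.25.  Ties break to the
  lower dose (the conservative choice; the argmin rule is silent on
  ties).

All rules are pure functions of their numeric inputs, so the unit tests
enumerate their small-case behaviour exhaustively.

## The trial simulator

`run_trial_pair()` simulates trial T1 (region 1) to completion or stop,
then trial T2 (region 2), refitting the model from scratch after every
cohort (no sequential updating between cohorts) under one of five
analysis models:

* **A** the full bridging model: T1 weights (rat 0.2, monkey 0.6, H 0,
  R 0.2) -- the human-only component gets no weight while only one
  trial exists; T2 weights (0.1, 0.5, 0.2, 0.2) with the completed T1
  data in the fit.  T1's weights stay fixed during T2: later data never
  re-weight the earlier, finished analysis.
* **B** human data only, $w_{\ell H} = 1$ for both subgroups.
* **C** no co-data at all, $w_{\ell R} = 1$, trials analysed separately.
* **D** animal co-data only.  Implemented as two *separate* fits (animal
  + that trial's own data): a joint fit with $w_{\ell H} = 0$ would
  still leak information between subgroups through the species means,
  which contradicts this model's definition as "no borrowing across
  human subgroups".
* **E** T1 without co-data; T2 pools the T1 and T2 observations into a
  single subgroup with one shared $\gamma$, $\epsilon$ fixed at 1 and
  $w_R = 1$ (complete pooling; the reference description gives no finer
  detail, and this is the natural reading of "pooling data only from
  T1").

T1 always starts at the lowest dose.  T2's starting dose uses the
starting rule under A (animal + T1 co-data), B and E (T1 co-data only),
and is the lowest dose under C and D.  Operating characteristics
aggregate the percentage of correct selection (PCS: trials declaring the
region's true MTD), early stops, aborted analyses,
completed-without-declaration trials, per-dose declaration percentages,
mean allocation and mean DLT counts; the categories partition 100% of
trials, and aborted trials count against PCS by default.

## Synthetic animal co-data

The worked examples and the operating-characteristics study need animal
co-data, but only design fragments of the motivating preclinical package
are recoverable: monkeys were tested at 1, 10, 30, 100 mg/kg with 4-12
animals per group in two studies; rat dose levels, group sizes and
outcomes are unknown; and verbal anchors state that, after translation,
the monkey data should predict roughly 25% human DLT risk at 5 mg/kg and
the rat data the same at 1 mg/kg, with rat evidence projecting onto the
low end of the human panel.

`default_animal_fixture()` therefore *generates* five studies (two
monkey, three rat) from logistic curves calibrated exactly to those
anchors, with unit slope (the prior median; no information about animal
slopes survives in the source material) and binomial sampling at a fixed
seed.  Rat native doses are 0.5, 2, 5, 15 mg/kg: translated by the
median $\delta_{\mathrm{rat}} = e^{-1.820} \approx 0.162$ they span
0.08-2.4 mg/kg, so rat-informed predictions at 10-20 mg/kg are genuine
extrapolations and come out wider than monkey-informed ones (visible on
the log-odds scale, where the comparison is not compressed against 1).
An earlier candidate including 50 mg/kg rats was rejected: it translates
to 8.1 mg/kg, *above* the reference dose, making rat data informative
exactly where they should be diffuse.

What a green test does and does not establish: the calibration tests
show the fixture reproduces the anchors (median predictive risk near
25% at the right doses, prior effective sample sizes of a few patients
per dose, the diffuse-at-high-doses rat pattern).  They do not make the
fixture the original data; operating characteristics that depend on the
animal evidence (notably absolute PCS levels) therefore carry
Monte-Carlo *and* fixture uncertainty, and the simulator's checks are
calibrated as neighbourhoods around the reference values, not as exact
reproductions.

## Effective sample sizes

`beta_moment_match()` approximates a marginal predictive distribution
with mean $m$ and sd $s$ by the Beta$(a, b)$ with identical first two
moments; the prior ESS is $a + b = m(1-m)/s^2 - 1$.  Inputs with
$s^2 \geq m(1-m)$ admit no Beta and raise an error rather than clamp --
a clamped ESS would silently corrupt cross-dose comparisons.  Round-trip
exactness and monotonicity in $s$ are property-tested.  When checking
against published tables note a subtlety the test suite documents: a
printed ESS row may equal the sum of *printed* (rounded) $a$ and $b$
rather than the closed form evaluated at the printed (rounded) moments,
so recomputed values can differ from printed ones by a few tenths purely
through rounding propagation.

## Known limitations

* One trial per subgroup; the multi-trial-per-subgroup extension is out
  of scope.
* No per-animal covariates, continuous toxicity grades or
  pharmacokinetics; animal evidence enters only as dose/n/DLT tables.
* The sampler is a random-scan Metropolis-within-Gibbs; it is validated
  distributionally (quadrature oracle, prior recovery, forward-simulation
  checks) but is not gradient-based, so very large hierarchies would mix
  more slowly than an HMC implementation.
* Interim analyses refit from scratch; there is no particle-style
  updating between cohorts.
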