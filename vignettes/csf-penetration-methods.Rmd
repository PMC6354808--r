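---
title: "Modelling cefepime transit from plasma to CSF: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cefepime transit from plasma to CSF: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpk)
```

## The problem

Cefepime is a fourth-generation cephalosporin whose overdose is associated
with neurotoxicity, which makes the relationship between plasma exposure and
cerebrospinal-fluid (CSF) exposure clinically important. `csfpk` models that
relationship in a preclinical rat design: once-daily short intravenous
infusions (150 mg/kg over 2 minutes, four days), sparse plasma sampling from
a venous catheter and sparse CSF sampling from an intracisternal catheter.
The package estimates a population pharmacokinetic (PK) model
nonparametrically, computes each animal's posterior concentration profiles
in both matrices, and summarises CSF penetration as the CSF/plasma ratio of
exposure (AUC or Cmax).

## Structural models

Four nested linear compartment models are available through
`pk_structure()`. The full model (`four_compartment_lag`) has amounts
$X_1$ (central), $X_2$ (peripheral), $X_3$ (lag) and $X_4$ (CSF):

$$
\begin{aligned}
\dot X_1 &= u(t) - (k_{el} + K_{12} + K_{13})X_1 + K_{21}X_2 + K_{41}X_4\\
\dot X_2 &= K_{12}X_1 - K_{21}X_2\\
\dot X_3 &= K_{13}X_1 - K_{34}X_3\\
\dot X_4 &= K_{34}X_3 - K_{41}X_4
\end{aligned}
$$

with plasma concentration $X_1/V_c$ and CSF concentration $X_4/V_{CSF}$;
the lag compartment is unobserved and delays arrival into the CSF. The
simpler comparison structures are the minimal nestings of this diagram:
`two_compartment` keeps only central and CSF with direct
$K_{13}$/$K_{41}$ exchange; `three_compartment` adds the peripheral
compartment; `three_compartment_lag_constant` keeps three states but routes
drug into the CSF through the lag pathway ($K_{13}$, $K_{34}$). Units are
hours, milligrams, and liters throughout, so concentrations are mg/liter,
identical to the reported unit of ug/ml.

The 2-minute injection is modelled as a zero-order infusion of duration
1/30 h, not a bolus: with an elimination half-life of roughly 13 minutes at
the reported parameters, Cmax is sensitive to the administration duration.

`solveAmounts()` propagates the linear system exactly with the matrix
exponential of the augmented system over each interval on which the input
rate is constant. This is robust to repeated or near-repeated eigenvalues,
which arise naturally while a population search crosses parameter regions
where rate constants coincide; an eigendecomposition solver would need
special-casing there. The test suite verifies agreement with an adaptive
numeric integrator to better than $10^{-6}$ relative error on random
parameter draws, and checks mass conservation, superposition over doses and
monotone washout directly.

## Observation error model

The assay SD is a first-order polynomial per matrix, inflated by a shared
multiplicative factor:

$$\mathrm{SD}(Y) = \gamma\,(C_0 + C_1 Y),$$

with defaults $C_0 = 0.25, C_1 = 0.15$ for plasma and
$C_0 = 0.0625, C_1 = 0.15$ for CSF, evaluated at the observed concentration
$Y$, and $\gamma = 1$. Observations are independent Gaussians on the
concentration scale (the polynomial is defined on that scale, so a log-scale
density would distort the stated assay precision). $\gamma$ is shared by
both output channels and fixed during subject-level likelihood evaluation;
`fitPopulation(estimate_gamma = TRUE)` re-estimates it once per cycle by 1-D
maximum likelihood. The default keeps $\gamma = 1$: the residual summaries
are cached in a form that makes the $\gamma$ profile likelihood cheap, but
nothing in the packaged analyses requires estimating it.

Model comparison uses $AIC = -2LL + 2p$ with $p$ = the number of active
structural parameters plus one for $\gamma$ (`nFittedParams()`). Predictive
performance is summarised by bias (weighted mean prediction error),
imprecision (bias-adjusted weighted mean squared error) and $R^2$ of the
least-squares regression of predicted on observed. Weights are
$1/\mathrm{SD}^2$ by default; unit weights are available
(`weighting = "unit"`) because published bias/imprecision values do not
always state their weighting convention.

## Nonparametric population estimation

`fitPopulation()` estimates the population distribution as a discrete set of
support points with probabilities, in the spirit of the nonparametric
adaptive grid (NPAG) family. The support is initialised in two stages: a
log-scale Latin-hypercube grid fills the search box, and each subject's own
likelihood is then maximised by Nelder-Mead from its best grid point, the
resulting per-subject maximum-likelihood points joining the grid. The
second stage is cheap (one model solve per objective evaluation) and places
support in the basin the data favour before any population-level
refinement — without it, the population search repeatedly converged to
different near-equal local optima with very different parameter medians.
Each subsequent cycle:

1. evaluates every subject's likelihood at every new support point (the
   expensive step; compiled matrix-exponential propagation makes one
   evaluation a few tens of microseconds),
2. maximises the mixture likelihood over the probability simplex with
   multiplicative (EM) updates, iterated until the Karush-Kuhn-Tucker
   residual over supported weights falls below $10^{-8}$ — each update is
   monotone, so the population $-2LL$ never increases,
3. condenses points whose weight falls below `condense_tol`
   ($10^{-8}$ of total mass),
4. expands: every surviving point is perturbed along each parameter axis in
   both directions and the perturbed candidates join the grid, and
5. when the expansion stalls, relocates: each point carrying weight is
   moved toward the maximiser of its responsibility-weighted subject
   log-likelihood (a generalized-EM step, implemented as a short
   Nelder-Mead in log-parameter space), the relocated candidates joining
   the grid on the same accept-if-better terms. Relocation sweeps are the
   costly refinement, so their number is capped (`max_relocations`, 12).

Two search-geometry choices matter and were made once, deliberately:

* **Log-scale geometry.** The default search box spans $[0.1\times,
  10\times]$ each reported median — two decades per axis — so both the
  initial space-filling grid (a Latin hypercube) and the expansion
  perturbations live on the log scale, where the box is a simple cube.
  Additive perturbations on the natural scale cannot refine small rate
  constants sitting two decades below the box ceiling.
* **Pattern-search step schedule.** The perturbation fraction starts at 20%
  of the (log) box and halves only when a cycle fails to improve the
  population $-2LL$ by `convergence_tol` (0.01). Halving on a fixed
  schedule irrespective of progress freezes the search prematurely: on a
  two-subpopulation benchmark it stalled more than 290 $-2LL$ units above
  the optimum, while the failure-triggered schedule reached within one unit
  of the nonparametric maximum-likelihood bound computed from per-subject
  maximum-likelihood estimates.

The fit stops when a cycle improves $-2LL$ by less than `convergence_tol`
and the step has already shrunk through nine halvings, or at `max_cycles`
(100). All stochastic steps flow from a mandatory integer seed; two calls
with the same seed are bit-identical.

## Posterior profiles and exposure metrics

`bayesianPosterior()` applies discrete Bayes' rule: posterior weight
$\propto$ prior probability $\times$ subject likelihood at each support
point. A subject with no usable observations keeps the population prior
(with a warning) — this mirrors how animals whose intracisternal catheters
failed still receive model-based CSF exposure estimates, while the
penetration summaries exclude them.

`posteriorProfile()` predicts both matrices on a 12-minute grid (0.2 h; 121
points over 24 h) from every support point with the subject's own dose
history and aggregates across points with the posterior-weighted median.
The weighted median was chosen over the weighted mean as the default
aggregator because the posterior is a discrete distribution over parameter
vectors that is often multimodal, and the median of the predicted
concentrations is insensitive to a stray heavy point; the weighted mean and
the single maximum-posterior point are available via `aggregate =`.
The weighted median itself is the lower weighted quantile with midpoint
interpolation on exact 0.5 boundaries (`weightedQuantile()`), so a
single-point posterior reproduces that point's prediction exactly.

Exposure metrics on the profile grid (`exposureSummary()`):

* AUC$_{0-24}$ by the trapezoidal rule (0.5% accuracy against a
  closed-form single-compartment bolus at the 0.2-h grid, and exactly
  additive over adjacent windows);
* Cmax/Tmax as the grid maximum and the earliest time attaining it — with
  the 0.2-h grid and a 2-min infusion, plasma Tmax lands on the first
  post-infusion grid point (0.2 h) by construction;
* terminal half-life from the last three grid points of the first 8 h:
  $k$ is minus the least-squares slope of $\log$ concentration on time,
  $t_{1/2} = \ln 2 / k$, with an error when the tail is not decaying. The
  8-h window uses the predicted profile, not raw observations.

Penetration is $100 \times$ CSF/plasma exposure, rounded half-up to an
integer percent per animal (the convention of the printed per-animal
table); cohort medians are computed on the rounded integers by default
(`rounded_penetration = FALSE` summarises raw ratios — for the packaged
data both conventions give the same medians, 19% and 20%).

**Quantile convention.** Cohort summaries (`summarizeCohort()`) use the
$(n+1)$-based quantile (R `type = 6`, the convention of common biostatistics
GUIs). This is not cosmetic: the packaged per-animal table's printed
interquartile ranges reproduce exactly under type 6 for both $n = 11$ and
$n = 7$ subsets (for example 95.7-136.5 for plasma AUC), whereas R's default
type 7 would give 97.9 for that lower quartile. The type is an argument, so
other conventions remain testable.

## The synthetic-study generator

No raw concentration data are distributed with the package, so
`simulateStudy()` generates complete studies with the design's structure:

* parameters per animal are log-normal with median equal to the reported
  population medians and CV% from the reported table
  (`samplePopulation()`; median and CV fix `meanlog` and `sdlog` exactly);
* weights are normal with mean 306 g and SD 20 g (the study reports only
  the mean; 20 g is a typical spread for adult male Sprague-Dawley rats of
  that size), and each dose is weight/1000 x 150 mg;
* the default schedule emulates the staggered sparse design: plasma at 0.2,
  0.5, 1, 2, 4 h on day 1 plus four samples on days 2-4 (nine total, five
  in the first 24 h); CSF twice on day 1 and four later samples (six
  total), with later-day times staggered across animals in 0.25-h steps;
* noise is Gaussian with the error-model SD at the noise-free value; a
  negative draw is resampled once, then clamped at zero (a documented
  deviation from pure Gaussian noise that keeps concentrations valid);
  values under the assay quantitation limits (0.5 plasma / 0.125 CSF
  ug/ml) are flagged, not dropped, and enter the fit by default since the
  original analysis states no below-limit rule;
* `injectArtifacts()` reproduces the two artifact processes: each animal
  loses all CSF sampling with probability 4/11 (catheter failure) and each
  plasma sample is multiplied by 100 with probability 1/99 (one gross
  outlier was observed among the study's 99 plasma samples). Outliers are
  *not* pre-excluded: spotting them is downstream quality control.

Truth records (true parameters, noise-free concentrations) are returned
separately and never consulted by the fitting path.

What the generator does **not** emulate: assay calibration drift,
inflamed-meninges transit changes, dose-dependent (saturable) kinetics, and
any within-animal parameter variation over the four study days. Passing
recovery tests on synthetic data therefore demonstrates that the estimation
machinery inverts the generative model it assumes — not that the structural
model is correct for real rats.

## Validation conditions and identifiability

The recovery benchmarks fit 25 synthetic animals with rich sampling
(12 plasma + 8 CSF samples in 24 h, `validationDesign()`) and 25%
log-normal spread around the reported medians. Three identifiability facts
shaped the schedule and the claims:

* At the reported exchange rates ($K_{12} + K_{21} \approx 60\,h^{-1}$) the
  distribution phase has a half-time of about 40 seconds. A schedule whose
  first sample is at 12 minutes identifies only composites (clearance,
  steady-state volume, terminal slope), and the nonparametric likelihood is
  then genuinely *better* on a ridge far from the truth than at the truth.
  The validation schedule therefore samples plasma from 2.4 to 6 minutes
  after dose start (right after the 2-minute infusion). This is attainable
  in catheterised rats with automated sampling, but it is richer than the
  actual staggered study design — which is exactly why the package does not
  claim to re-estimate the original study's parameter table from sparse
  data.
* $K_{13}$ and $V_{CSF}$ are individually near-unidentifiable from
  concentration data alone: scaling both by $c$ leaves the CSF
  concentration unchanged and perturbs plasma only through the small
  CSF-return flow (about 1% of plasma turnover). Their ratio-fixed
  combination is identified; the individual values are kept near the centre
  of the flat ridge by the log-uniform grid rather than by the data.
* The CSF pathway's transfer function is invariant under exchanging
  $K_{34}$ and $K_{41}$ up to a gain factor that the free $K_{13}/V_{CSF}$
  scale absorbs (a flip-flop ambiguity). Washout-phase CSF samples at 6 and
  10 h — where the two branches' terminal slopes differ and the signal is
  still above the assay noise floor — and the centred two-stage
  initialization keep the fit on the branch of the generating values; a
  24-h CSF sample would be pure noise floor and was not used.

Problem sizes used by the packaged validation runs: 25 subjects, 320
initial grid points for the 8-parameter model, at most 100 cycles and 12
relocation sweeps — a fit of roughly ten minutes on one core, converging in
~30 cycles. The two-subpopulation benchmark uses 16 subjects and the
5-parameter structure (about three minutes).

## Numerical choices and degenerate inputs

* Likelihood underflow is avoided by per-subject scaling of the likelihood
  matrix before mixing (log-sum-exp).
* A dataset in which no support point gives any subject finite likelihood
  raises an error advising wider bounds rather than returning a degenerate
  fit.
* An empty dose list yields identically zero amounts; overlapping infusion
  windows sum their rates; a dose with zero duration is an instantaneous
  bolus, taken right-continuous at the dosing instant.
* Ties in Cmax resolve to the earlier time; the half-life estimator
  requires three positive tail concentrations and a positive slope.
* `roundHalfUp()` rounds half away from zero (printed-table convention),
  avoiding R's round-half-even.

## Known limitations

* The NP-MLE support is a local optimum of a non-convex search; different
  seeds give slightly different supports (the weighted medians are stable
  in the packaged benchmarks).
* Protein binding is not modelled (total concentrations throughout), no
  below-quantitation-limit likelihood correction is applied, and saturable
  kinetics are out of scope.
* AIC parameter counting includes $\gamma$; other bookkeeping conventions
  exist and published AIC gaps cannot always be reconciled to one rule.
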