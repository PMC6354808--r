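# csfpk

Population pharmacokinetics of cefepime transit from plasma to
cerebrospinal fluid (CSF) in the rat.

Cefepime is a broad-spectrum cephalosporin whose overexposure is linked to
neurotoxicity, so the relationship between plasma concentrations and CSF
concentrations matters both for dosing and for understanding toxicity. This
package implements the full analysis pipeline for a preclinical study design
in which catheterised rats receive 150 mg/kg intravenous cefepime over
2 minutes once daily for four days, with sparse staggered plasma and
intracisternal CSF sampling:

* **Compartment models** — nested linear structures up to a four-compartment
  model with an unobserved lag compartment feeding the CSF:
  plasma = X1/Vc, CSF = X4/V_CSF, with
  dX1/dt = u(t) − (kel + K12 + K13)·X1 + K21·X2 + K41·X4,
  dX2/dt = K12·X1 − K21·X2, dX3/dt = K13·X1 − K34·X3,
  dX4/dt = K34·X3 − K41·X4. Solutions are exact (matrix-exponential
  propagation over piecewise-constant infusion input).
* **Error model and likelihood** — per-matrix polynomial SD
  (SD = γ·(C0 + C1·Y); plasma 0.25/0.15, CSF 0.0625/0.15), Gaussian
  likelihood, AIC comparison, bias/imprecision/R² diagnostics.
* **Nonparametric population fit** — an adaptive-grid estimator (NPAG-style):
  discrete support points with probabilities optimised by monotone EM
  updates, log-scale pattern-search expansion, and generalized-EM point
  relocation. The population −2LL never increases across cycles.
* **MAP Bayesian exposure** — per-animal discrete posteriors, predicted
  concentration profiles on a 12-minute grid, AUC₀₋₂₄ (trapezoidal), Cmax,
  Tmax, terminal half-life (ln 2/k from the last three predicted points of
  the first 8 h), and CSF/plasma penetration percentages with cohort
  medians, IQRs and CV%.
* **Synthetic studies** — a generator that emulates the study design
  (sample counts and staggering, log-normal parameter spread,
  assay-informed noise, intracisternal catheter failures, 100-fold plasma
  outliers), with truth records kept apart from the fitting path.

The reported per-animal exposure table is packaged as a fixture, so the
study's summary statistics (median CSF/plasma penetration of 19% by AUC in
animals with CSF sampling, 20% across all animals, 3% by Cmax) can be
recomputed with one call.

## Worked example

```r
library(csfpk)

## the packaged per-animal exposure table: recompute every derived cell
rep <- reproduceExposureSummaries()
attr(rep, "all_pass")
#> [1] TRUE
subset(rep, cell %in% c("csf_sampled_pen_auc_pct_median",
                        "all_pen_auc_pct_median",
                        "all_pen_cmax_pct_median"))
#>                              cell computed printed pass
#> 41        all_pen_cmax_pct_median        3       3 TRUE
#> 44         all_pen_auc_pct_median       20      20 TRUE
#> 68 csf_sampled_pen_auc_pct_median       19      19 TRUE

## transit arithmetic from the reported median parameters
str(transitArithmetic(cefepimeMedianParams()))
#> List of 3
#>  $ combined_transit_rate: num 3.09
#>  $ time_to_steady_state : num 0.67
#>  $ kel_half_life        : num 0.22
```

The combined plasma-to-CSF transit rate K13 + K34 = 3.09 h⁻¹ means the CSF
approaches steady state within about 0.67 h (three half-times), while the
central elimination half-life ln(2)/kel is 0.22 h — much shorter than the
1.7 h terminal half-life read off the predicted profiles, which reflects
redistribution.

A full synthetic analysis — simulate, fit, summarise (about five minutes on
one core):

```r
design <- validationDesign(8)   # rich sampling: 12 plasma + 8 CSF per rat
study  <- simulateStudy(design, seed = 7)
fit <- fitPopulation(study$dataset, pk_structure("four_compartment_lag"),
                     seed = 7)
fit
#> <population_model> four_compartment_lag
#>   8 support point(s); -2LL = 630.115; AIC = 648.115; gamma = 1
#>   10 cycle(s); converged: TRUE
#>   weighted medians:
#>     kel      Vc   V_CSF     K12     K21     K13     K34     K41
#>  3.5537  0.1110  0.2101 28.7833 39.4345  0.1961  4.4910  0.4867

tab <- exposureTable(study$dataset, fit)
smry <- summarizeExposureTable(tab)
subset(smry, metric == "pen_auc_pct")
#>         metric       group median q25 q75 cv_pct n
#> 8  pen_auc_pct         all   31.5  21  52   93.5 8
#> 16 pen_auc_pct csf_sampled   31.5  21  52   93.5 8

summarizeCohort(trueExposureTable(study)$pen_auc_pct)$median  # known truth
#> [1] 28
```

The fitted median CSF penetration by AUC (31.5%) sits a few points from the
simulation's known truth (28%) at this small cohort size. `studyDesign()`
instead reproduces the original sparse staggered schedule, including
catheter failures and gross plasma outliers (flag those `excluded` before
fitting, as the original analysis did); note that individual rate constants
are only weakly identified from data that sparse — see the methods
vignette.

The command-line interface wraps the same functions:

```sh
Rscript exec/csfpk simulate --n 11 --seed 7 --out study.csv --truth truth.json
Rscript exec/csfpk fit --model four_compartment_lag --data study.csv --seed 17 --out fit.json
Rscript exec/csfpk reproduce-table3
Rscript exec/csfpk transit
```

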