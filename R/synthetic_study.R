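#' Study design of the synthetic rat cohort
#'
#' Emulates the preclinical design: once-daily 150 mg/kg intravenous
#' cefepime over 2 minutes for 4 days in rats of mean weight 306 g; nine
#' plasma samples per animal (five inside the first 24 h) and about six CSF
#' samples (two inside the first 24 h), staggered across animals; a risk of
#' intracisternal catheter failure that removes all CSF sampling for the
#' animal; a small per-sample probability of a gross (100-fold) plasma
#' outlier; and per-matrix lower limits of quantification.
#'
#' @param n_animals Number of animals.
#' @param weight_mean_g,weight_sd_g Body-weight distribution (g).
#' @param dose_mg_per_kg Daily dose.
#' @param n_days Number of once-daily doses.
#' @param infusion_h Infusion duration (h); 2 min = 1/30.
#' @param plasma_times Plasma sampling times (h after first dose).
#' @param csf_times CSF sampling times (h after first dose).
#' @param stagger_h Later-day samples are shifted by multiples of this
#'   amount cycled across animals, emulating the staggered schedule.
#' @param csf_failure_prob Per-animal probability of catheter failure.
#' @param outlier_prob Per-plasma-sample probability of a 100-fold outlier.
#' @param lloq_plasma,lloq_csf Lower limits of quantification (ug/ml).
#' @return Object of class `study_design`.
#' @export
studyDesign <- function(n_animals = 11, weight_mean_g = 306,
                        weight_sd_g = 20, dose_mg_per_kg = 150, n_days = 4,
                        infusion_h = 1 / 30,
                        plasma_times = c(0.2, 0.5, 1, 2, 4,
                                         24.2, 26, 48.2, 72.5),
                        csf_times = c(1, 2, 24.5, 26, 48.5, 72.5),
                        stagger_h = 0.25, csf_failure_prob = 4 / 11,
                        outlier_prob = 1 / 99, lloq_plasma = 0.5,
                        lloq_csf = 0.125) {
  horizon <- 24 * n_days
  stopifnot(all(plasma_times >= 0), all(plasma_times <= horizon),
            all(csf_times >= 0), all(csf_times <= horizon),
            csf_failure_prob >= 0, csf_failure_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1)
  d <- list(n_animals = n_animals, weight_mean_g = weight_mean_g,
            weight_sd_g = weight_sd_g, dose_mg_per_kg = dose_mg_per_kg,
            n_days = n_days, infusion_h = infusion_h,
            plasma_times = plasma_times, csf_times = csf_times,
            stagger_h = stagger_h, csf_failure_prob = csf_failure_prob,
            outlier_prob = outlier_prob, lloq_plasma = lloq_plasma,
            lloq_csf = lloq_csf)
  class(d) <- "study_design"
  d
}

#' Draw subject-level parameter vectors from a log-normal population
#'
#' Each parameter is log-normal with the given median and coefficient of
#' variation: `meanlog = log(median)`, `sdlog = sqrt(log(1 + cv^2))`.
#'
#' @param medians Named positive medians (e.g. [cefepimeMedianParams()]).
#' @param cv_percents Named CV% values (e.g. [cefepimeParamCV()]); a CV of 0
#'   returns the median for every draw.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return Matrix `n x p` of parameter draws, columns named.
#' @export
samplePopulation <- function(medians = cefepimeMedianParams(),
                             cv_percents = cefepimeParamCV(), n, seed) {
  m <- unclass(medians)
  m <- m[!is.na(m)]
  cv <- cv_percents[names(m)] / 100
  stopifnot(all(m > 0), all(cv >= 0))
  set.seed(as.integer(seed))
  draws <- sapply(names(m), function(pn) {
    if (cv[pn] == 0) rep(m[pn], n)
    else stats::rlnorm(n, meanlog = log(m[pn]),
                       sdlog = sqrt(log(1 + cv[pn]^2)))
  })
  matrix(draws, nrow = n, dimnames = list(NULL, names(m)))
}

# staggered copy of the design schedule for animal i: samples after the first
# day shift by stagger_h * (i mod 3), clamped to the dosing horizon
stagger_times <- function(times, i, design) {
  shift <- design$stagger_h * ((i - 1) %% 3)
  late <- times > 24
  times[late] <- pmin(times[late] + shift, 24 * design$n_days)
  times
}

#' Simulate one animal: noisy observations plus the noise-free truth
#'
#' The dose is `weight/1000 * dose_mg_per_kg` mg per administration.
#' Observation noise is Gaussian with SD from the error model evaluated at
#' the noise-free concentration; a negative draw is resampled once and then
#' clamped at zero. Values below the channel's LLOQ are flagged (`bloq`),
#' not removed.
#'
#' @param params Named parameter vector (a [pk_params()] or a row of
#'   [samplePopulation()]).
#' @param design A [studyDesign()].
#' @param weight Body weight (g).
#' @param seed Integer seed.
#' @param id Subject label.
#' @param animal_index Index used for schedule staggering.
#' @param structure A [pk_structure()] (default the full model).
#' @param errmod Error model for the noise; `noise_scale` multiplies every
#'   SD (0 gives noise-free observations).
#' @param noise_scale Scalar noise multiplier.
#' @return List with `subject` (a [subjectRecord()]) and `truth` (list with
#'   the true `params` and the noise-free concentrations at the sampled
#'   times).
#' @export
simulateSubject <- function(params, design, weight, seed, id = "1",
                            animal_index = 1,
                            structure = pk_structure("four_compartment_lag"),
                            errmod = errorModel(), noise_scale = 1) {
  doses <- standardRegimen(weight, design$dose_mg_per_kg, design$n_days,
                           design$infusion_h)
  sched <- data.frame(
    time = c(stagger_times(design$plasma_times, animal_index, design),
             stagger_times(design$csf_times, animal_index, design)),
    output = c(rep("plasma", length(design$plasma_times)),
               rep("csf", length(design$csf_times))))
  sched <- sched[order(sched$time), , drop = FALSE]
  truth_conc <- vapply(seq_len(nrow(sched)), function(k) {
    predictConcentrations(params, structure, doses, sched$time[k],
                          sched$output[k])
  }, 1)
  set.seed(as.integer(seed))
  sds <- noise_scale * observationSD(truth_conc, sched$output, errmod)
  noisy <- truth_conc + stats::rnorm(nrow(sched), 0, sds)
  neg <- noisy < 0
  if (any(neg)) {
    noisy[neg] <- truth_conc[neg] + stats::rnorm(sum(neg), 0, sds[neg])
    noisy <- pmax(noisy, 0)
  }
  lloq <- ifelse(sched$output == "plasma", design$lloq_plasma,
                 design$lloq_csf)
  obs <- data.frame(time = sched$time, value = noisy, output = sched$output,
                    excluded = 0L, bloq = as.integer(noisy < lloq))
  subject <- subjectRecord(id, weight, doses, obs)
  truth <- list(id = as.character(id), params = params, times = sched$time,
                output = sched$output, conc = truth_conc)
  list(subject = subject, truth = truth)
}

#' Inject study artifacts: catheter failures and gross plasma outliers
#'
#' Each animal loses all its CSF observations with probability
#' `csf_failure_prob` (intracisternal catheter failure); each plasma
#' observation is multiplied by 100 with probability `outlier_prob`. Outlier
#' rows keep `excluded = 0`: spotting and excluding them is downstream
#' quality control, as in the original analysis.
#'
#' @param dataset List of [subjectRecord()]s.
#' @param csf_failure_prob,outlier_prob Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified dataset.
#' @export
injectArtifacts <- function(dataset, csf_failure_prob = 4 / 11,
                            outlier_prob = 1 / 99, seed) {
  stopifnot(csf_failure_prob >= 0, csf_failure_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1)
  set.seed(as.integer(seed))
  lapply(dataset, function(s) {
    obs <- s$observations
    if (stats::runif(1) < csf_failure_prob) {
      obs <- obs[obs$output != "csf", , drop = FALSE]
    }
    is_pl <- obs$output == "plasma"
    hit <- is_pl & stats::runif(nrow(obs)) < outlier_prob
    obs$value[hit] <- obs$value[hit] * 100
    s$observations <- obs
    s
  })
}

#' Generate a complete synthetic study
#'
#' Draws per-animal parameters and weights, simulates every animal under the
#' design, and injects the design's artifact processes. The truth records
#' (true parameters and noise-free concentrations) are returned separately
#' from the dataset and are never consulted by the fitting path.
#'
#' @param design A [studyDesign()].
#' @param medians,cv_percents Population location and spread passed to
#'   [samplePopulation()].
#' @param seed Integer seed for all stochastic steps.
#' @param structure,errmod,noise_scale Passed to [simulateSubject()].
#' @return List with `dataset` (list of [subjectRecord()]s), `truth` (list
#'   of truth records) and `design`.
#' @export
simulateStudy <- function(design = studyDesign(),
                          medians = cefepimeMedianParams(),
                          cv_percents = cefepimeParamCV(), seed,
                          structure = pk_structure("four_compartment_lag"),
                          errmod = errorModel(), noise_scale = 1) {
  if (missing(seed)) stop("simulateStudy requires an explicit seed")
  seed <- as.integer(seed)
  params <- samplePopulation(medians, cv_percents, design$n_animals, seed)
  params <- params[, pk_structure(structure$name)$active_params,
                   drop = FALSE]
  set.seed(seed + 1L)
  weights <- pmax(stats::rnorm(design$n_animals, design$weight_mean_g,
                               design$weight_sd_g), 100)
  sims <- lapply(seq_len(design$n_animals), function(i) {
    simulateSubject(params[i, ], design, weights[i], seed = seed + 1L + i,
                    id = as.character(i), animal_index = i,
                    structure = structure, errmod = errmod,
                    noise_scale = noise_scale)
  })
  dataset <- injectArtifacts(lapply(sims, `[[`, "subject"),
                             design$csf_failure_prob, design$outlier_prob,
                             seed = seed + 1000L)
  list(dataset = dataset, truth = lapply(sims, `[[`, "truth"),
       design = design)
}

#' Rich-sampling validation design
#'
#' The study design used by the package's recovery benchmarks: a single dose
#' day with 12 plasma and 8 CSF samples per animal and no artifact
#' processes. Plasma sampling starts minutes after the 2-minute infusion
#' (2.4-6 min) so the fast distribution phase - whose half-time is under a
#' minute at the reported exchange rates - is observed and kel and Vc are
#' identified individually; CSF sampling covers the rise (15-120 min) and
#' the washout (4-10 h) of the CSF compartment.
#'
#' @param n_animals Number of animals.
#' @return A [studyDesign()].
#' @export
validationDesign <- function(n_animals = 25) {
  studyDesign(n_animals = n_animals, n_days = 1,
              plasma_times = c(0.04, 0.05, 0.067, 0.083, 0.1, 0.2, 0.5, 1,
                               2, 4, 8, 24),
              csf_times = c(0.25, 0.5, 1, 1.5, 2, 4, 6, 10),
              stagger_h = 0, csf_failure_prob = 0, outlier_prob = 0)
}

#' Noise-free exposure truth of a simulated study
#'
#' Exposure metrics computed from each animal's true parameters on the
#' reporting grid, for checking pipeline recovery against known truth.
#'
#' @param study A [simulateStudy()] result.
#' @param structure A [pk_structure()].
#' @param grid_step,horizon Reporting grid.
#' @return Data frame like [exposureTable()] (all animals, `csf_sampled`
#'   reflecting the post-artifact dataset).
#' @export
trueExposureTable <- function(study,
                              structure = pk_structure("four_compartment_lag"),
                              grid_step = 0.2, horizon = 24) {
  rows <- lapply(seq_along(study$truth), function(i) {
    tr <- study$truth[[i]]
    s <- study$dataset[[i]]
    times <- grid_step * 0:round(horizon / grid_step)
    prof <- data.frame(
      time = times,
      plasma = predictConcentrations(tr$params, structure, s$doses, times,
                                     "plasma"),
      csf = predictConcentrations(tr$params, structure, s$doses, times,
                                  "csf"))
    ex <- exposureSummary(prof, window = c(0, horizon))
    has_csf <- any(s$observations$output == "csf" &
                     s$observations$excluded == 0)
    data.frame(animal = tr$id,
               cmax_plasma = ex$plasma$cmax, auc_plasma = ex$plasma$auc,
               cmax_csf = ex$csf$cmax, tmax_csf = ex$csf$tmax,
               auc_csf = ex$csf$auc, t_half = ex$plasma$t_half,
               pen_cmax_pct = ex$penetration_cmax$pct,
               pen_auc_pct = ex$penetration_auc$pct,
               csf_sampled = as.integer(has_csf))
  })
  do.call(rbind, rows)
}
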