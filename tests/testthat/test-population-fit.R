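st2 <- pk_structure("two_compartment")
p_true <- pk_params(kel = 1.2, Vc = 0.45, V_CSF = 0.25, K13 = 0.4,
                    K41 = 0.6)

# hand-assembled population model over given support points / weights
manual_model <- function(pts, w, structure = st2, gamma = 1) {
  m <- list(structure = structure, support = pts, weights = w,
            gamma = gamma, errmod = errorModel(gamma = gamma))
  class(m) <- "population_model"
  m
}

test_that("the initial grid fills the box reproducibly with equal weights", {
  b <- paramBounds(st2, p_true)
  g1 <- initializeGrid(b, 1, seed = 7)
  expect_equal(nrow(g1$points), 1)
  expect_equal(g1$weights, 1)

  g <- initializeGrid(b, 100, seed = 7)
  expect_identical(g, initializeGrid(b, 100, seed = 7))
  expect_equal(g$weights, rep(0.01, 100))

  big <- initializeGrid(b, 1000, seed = 8)$points
  for (pn in colnames(big)) {
    expect_true(all(big[, pn] >= b$lower[pn] & big[, pn] <= b$upper[pn]))
  }
  expect_error(makeBounds(c(a = 2), c(a = 1)))
})

test_that("a noiseless subject concentrates the fit on the true grid point", {
  s <- toy_subject(p_true, st2)
  b <- paramBounds(st2, p_true)
  grid <- initializeGrid(b, 30, seed = 1)$points
  pts <- rbind(grid, unclass(p_true)[colnames(grid)])
  fit <- fitPopulation(list(s), st2, b, seed = 1, init_points = pts,
                       expansion_frac = 0)
  on_truth <- apply(fit$support, 1, function(r) {
    all(abs(r - unclass(p_true)[colnames(fit$support)]) < 1e-9)
  })
  expect_true(any(on_truth))
  expect_gte(sum(fit$weights[on_truth]), 0.99)
})

test_that("accepted -2LL is non-increasing, weights stay on the simplex, fits are reproducible", {
  set.seed(42)
  dataset <- lapply(1:4, function(i) {
    pars <- random_params(st2)
    simulateSubject(pars, rich_design(1), 306, seed = 100 + i,
                    id = as.character(i), structure = st2)$subject
  })
  b <- paramBounds(st2, p_true)
  fit <- fitPopulation(dataset, st2, b, n_init = 60, seed = 5,
                       max_cycles = 8)
  expect_true(all(diff(fit$cycle_log$neg2ll) <= 1e-6))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$weights >= 0))
  # support stays inside the box
  for (pn in colnames(fit$support)) {
    expect_true(all(fit$support[, pn] >= b$lower[pn] - 1e-12 &
                      fit$support[, pn] <= b$upper[pn] + 1e-12))
  }
  fit2 <- fitPopulation(dataset, st2, b, n_init = 60, seed = 5,
                        max_cycles = 8)
  expect_identical(fit$support, fit2$support)
  expect_equal(fit$neg2ll, fit2$neg2ll)

  # the fitted -2LL agrees with a direct recomputation from the public API
  expect_equal(direct_population_neg2ll(dataset, fit$support, st2,
                                        fit$weights),
               fit$neg2ll, tolerance = 1e-8)
})

test_that("zero expansion reduces the fit to fixed-grid weight optimization", {
  s <- toy_subject(p_true, st2, noise_sd = 0.3, seed = 2)
  b <- paramBounds(st2, p_true)
  pts <- initializeGrid(b, 25, seed = 3)$points
  fit0 <- fitPopulation(list(s), st2, b, seed = 3, init_points = pts,
                        expansion_frac = 0)
  # support is a subset of the supplied grid
  expect_true(all(apply(fit0$support, 1, function(r) {
    any(apply(pts, 1, function(g) all(abs(g - r) < 1e-12)))
  })))
  # no better than the grid optimum found by a long EM run, and no worse
  # than equal weights
  eq_w <- rep(1 / nrow(pts), nrow(pts))
  expect_lte(fit0$neg2ll,
             direct_population_neg2ll(list(s), pts, st2, eq_w) + 1e-8)
})

test_that("Bayes updates follow the prior-times-likelihood rule", {
  # two equal-prior points engineered to a 4:1 likelihood ratio
  pA <- p_true
  pB <- p_true; pB["Vc"] <- 0.9
  doses <- standardRegimen(306, n_days = 1)
  t_obs <- 1
  predA <- predictConcentrations(pA, st2, doses, t_obs, "plasma")
  predB <- predictConcentrations(pB, st2, doses, t_obs, "plasma")
  em <- errorModel(plasma_c0 = 1, plasma_c1 = 0)
  # solve (y-predA)^2 - (y-predB)^2 = -2 log(4) for y (sd = 1)
  y <- (predA^2 - predB^2 + 2 * log(4)) / (2 * (predA - predB))
  expect_gte(y, 0)
  s <- subjectRecord("a", 306, doses,
                     data.frame(time = t_obs, value = y, output = "plasma"))
  pts <- rbind(unclass(pA)[st2$active_params],
               unclass(pB)[st2$active_params])
  model <- manual_model(pts, c(0.5, 0.5))
  model$errmod <- em
  post <- bayesianPosterior(s, model)
  expect_equal(post, c(0.8, 0.2), tolerance = 1e-9)

  # single support point
  m1 <- manual_model(pts[1, , drop = FALSE], 1)
  m1$errmod <- em
  expect_equal(bayesianPosterior(s, m1), 1)

  # 5-point case against hand normalization from the public likelihoods
  s5 <- toy_subject(p_true, st2, noise_sd = 0.4, seed = 6)
  pts5 <- initializeGrid(paramBounds(st2, p_true), 5, seed = 9)$points
  prior <- c(0.1, 0.3, 0.2, 0.25, 0.15)
  m5 <- manual_model(pts5, prior)
  logL <- vapply(1:5, function(j) {
    pj <- pts5[j, ]; class(pj) <- "pk_params"
    -0.5 * subjectNeg2LL(pj, s5, st2)
  }, 1)
  hand <- prior * exp(logL - max(logL))
  hand <- hand / sum(hand)
  expect_equal(bayesianPosterior(s5, m5), hand, tolerance = 1e-12)

  # zero prior stays zero
  m0 <- manual_model(pts5, c(0, 0.4, 0.2, 0.25, 0.15))
  expect_equal(bayesianPosterior(s5, m0)[1], 0)

  # a subject with no observations falls back to the prior with a warning
  s_none <- s5
  s_none$observations <- s5$observations[0, , drop = FALSE]
  expect_warning(post0 <- bayesianPosterior(s_none, m5), "no usable")
  expect_equal(post0, prior)
})

test_that("posterior profiles aggregate support-point predictions on the 12-min grid", {
  s <- toy_subject(p_true, st2, noise_sd = 0.2, seed = 12)
  truth_pt <- matrix(unclass(p_true)[st2$active_params], 1,
                     dimnames = list(NULL, st2$active_params))
  m1 <- manual_model(truth_pt, 1)
  prof <- posteriorProfile(s, m1)
  expect_equal(nrow(prof), 121)
  expect_equal(prof$time, seq(0, 24, by = 0.2))
  direct <- predictConcentrations(p_true, st2, s$doses, prof$time, "plasma")
  expect_equal(prof$plasma, direct, tolerance = 1e-9)
  expect_true(all(prof$csf >= 0))

  # 3-point weighted median against direct evaluation at one time
  pts3 <- rbind(truth_pt, truth_pt * 1.4, truth_pt * 0.7)
  colnames(pts3) <- st2$active_params
  w3 <- c(0.2, 0.5, 0.3)
  m3 <- manual_model(pts3, w3)
  prof3 <- posteriorProfile(s, m3, posterior = w3)
  k <- which(prof3$time == 2)
  vals <- vapply(1:3, function(j) {
    pj <- pts3[j, ]; class(pj) <- "pk_params"
    predictConcentrations(pj, st2, s$doses, 2, "plasma")
  }, 1)
  expect_equal(prof3$plasma[k], weightedQuantile(vals, w3, 0.5))

  # weighted mean option
  prof_m <- posteriorProfile(s, m3, posterior = w3,
                             aggregate = "weighted_mean")
  expect_equal(prof_m$plasma[k], sum(vals * w3))

  expect_error(posteriorProfile(s, m1, grid_step = 0.7, horizon = 24),
               "multiple")
})

test_that("population diagnostics are computed per channel and are channel-separable", {
  s <- toy_subject(p_true, st2)  # noiseless
  truth_pt <- matrix(unclass(p_true)[st2$active_params], 1,
                     dimnames = list(NULL, st2$active_params))
  m1 <- manual_model(truth_pt, 1)
  d <- populationDiagnostics(m1, list(s))
  expect_equal(d$plasma$bias, 0, tolerance = 1e-8)
  expect_equal(d$plasma$r2, 1, tolerance = 1e-8)
  expect_equal(d$csf$imprecision, 0, tolerance = 1e-10)

  # permuting CSF values never changes plasma diagnostics
  s_noisy <- toy_subject(p_true, st2, noise_sd = 0.3, seed = 8)
  d1 <- populationDiagnostics(m1, list(s_noisy))
  s_perm <- s_noisy
  is_csf <- s_perm$observations$output == "csf"
  set.seed(1)
  s_perm$observations$value[is_csf] <-
    sample(s_perm$observations$value[is_csf])
  d2 <- populationDiagnostics(m1, list(s_perm))
  expect_equal(d2$plasma, d1$plasma)
})

test_that("two well-separated subpopulations are both recovered", {
  pA <- p_true; pA["kel"] <- 1.5
  pB <- p_true; pB["kel"] <- 5
  design <- rich_design(1)
  dataset <- c(
    lapply(1:8, function(i) {
      simulateSubject(pA, design, 306, seed = 200 + i, id = paste0("a", i),
                      structure = st2)$subject
    }),
    lapply(1:8, function(i) {
      simulateSubject(pB, design, 306, seed = 300 + i, id = paste0("b", i),
                      structure = st2)$subject
    }))
  b <- paramBounds(st2, p_true)
  fit <- fitPopulation(dataset, st2, b, n_init = 120, seed = 17,
                       max_cycles = 10)
  mid <- sqrt(1.5 * 5)
  lo <- fit$support[, "kel"] < mid
  expect_gt(sum(fit$weights[lo]), 0.25)
  expect_gt(sum(fit$weights[!lo]), 0.25)
  med_lo <- weightedQuantile(fit$support[lo, "kel"], fit$weights[lo], 0.5)
  med_hi <- weightedQuantile(fit$support[!lo, "kel"], fit$weights[!lo], 0.5)
  expect_lt(abs(med_lo - 1.5) / 1.5, 0.15)
  expect_lt(abs(med_hi - 5) / 5, 0.15)
})
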