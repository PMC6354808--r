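test_that("observation SD follows the per-channel polynomial scaled by gamma", {
  em <- errorModel()
  expect_equal(unname(observationSD(100, "plasma", em)), 15.25)
  expect_equal(unname(observationSD(4, "csf", em)), 0.6625)
  em2 <- errorModel(gamma = 2)
  expect_equal(unname(observationSD(0, "plasma", em2)), 2 * 0.25)
  expect_equal(unname(observationSD(0, "csf", em2)), 2 * 0.0625)
  expect_error(observationSD(-1, "plasma", em), "negative")
  # vectorised across channels
  expect_equal(unname(observationSD(c(100, 4), c("plasma", "csf"), em)),
               c(15.25, 0.6625))
})

test_that("subject -2LL matches the direct Gaussian density product", {
  st <- pk_structure("two_compartment")
  p <- pk_params(kel = 1.2, Vc = 0.5, V_CSF = 0.3, K13 = 0.4, K41 = 0.6)
  # a single observation exactly at the prediction with SD 1 gives log(2*pi)
  doses <- doseEvent(0, 10, 0)
  pred <- predictConcentrations(p, st, doses, 1, "plasma")
  em <- errorModel(plasma_c0 = 1, plasma_c1 = 0)
  s1 <- subjectRecord("a", 300, doses,
                      data.frame(time = 1, value = pred, output = "plasma"))
  expect_equal(subjectNeg2LL(p, s1, st, em), log(2 * pi), tolerance = 1e-12)

  # additivity over independent observations
  set.seed(11)
  s_all <- toy_subject(p, st, plasma_times = c(0.5, 2), csf_times = c(1),
                       noise_sd = 0.5, seed = 11)
  parts <- vapply(seq_len(3), function(k) {
    obs <- s_all$observations[k, , drop = FALSE]
    subjectNeg2LL(p, subjectRecord("a", 300, doses2 <- s_all$doses, obs),
                  st)
  }, 1)
  expect_equal(subjectNeg2LL(p, s_all, st), sum(parts), tolerance = 1e-10)

  # brute-force density oracle on a random small case
  obs <- s_all$observations
  preds <- vapply(seq_len(nrow(obs)), function(k) {
    predictConcentrations(p, st, s_all$doses, obs$time[k], obs$output[k])
  }, 1)
  sds <- observationSD(obs$value, obs$output, errorModel())
  oracle <- -2 * sum(log(stats::dnorm(obs$value, preds, sds)))
  expect_equal(subjectNeg2LL(p, s_all, st), oracle, tolerance = 1e-10)
})

test_that("excluded observations are skipped without touching the rest", {
  st <- pk_structure("two_compartment")
  p <- pk_params(kel = 1, Vc = 0.5, V_CSF = 0.3, K13 = 0.4, K41 = 0.6)
  s <- toy_subject(p, st, plasma_times = c(0.5, 2), csf_times = c(1),
                   noise_sd = 0.3, seed = 3)
  keep_only <- s
  keep_only$observations <- s$observations[-2, , drop = FALSE]
  excl <- s
  excl$observations$excluded[2] <- 1L
  expect_equal(subjectNeg2LL(p, excl, st), subjectNeg2LL(p, keep_only, st))
  all_out <- s
  all_out$observations$excluded <- 1L
  expect_error(subjectNeg2LL(p, all_out, st), "excluded")
})

test_that("-2LL decreases as a prediction approaches its observation", {
  st <- pk_structure("two_compartment")
  true_p <- pk_params(kel = 1, Vc = 0.5, V_CSF = 0.3, K13 = 0.4, K41 = 0.6)
  s <- toy_subject(true_p, st)
  vals <- vapply(c(2, 1.4, 1.15, 1), function(f) {
    p <- true_p
    p["Vc"] <- 0.5 * f
    subjectNeg2LL(p, s, st)
  }, 1)
  expect_true(all(diff(vals) < 0))
})

test_that("a line search over a linear-in-parameter toy is minimised at the weighted LS solution", {
  st <- pk_structure("two_compartment")
  p0 <- pk_params(kel = 1, Vc = 0.5, V_CSF = 0.3, K13 = 0.4, K41 = 0.6)
  s <- toy_subject(p0, st, csf_times = numeric(0), noise_sd = 2, seed = 21)
  obs <- s$observations
  # plasma prediction is (amount profile) * c with c = 1/Vc: weighted LS in c
  amounts <- vapply(obs$time, function(t) {
    solveAmounts(p0, st, s$doses, t)[1, "central"]
  }, 1)
  w <- 1 / observationSD(obs$value, obs$output)^2
  c_star <- sum(w * obs$value * amounts) / sum(w * amounts^2)
  at <- function(vc) {
    p <- p0
    p["Vc"] <- vc
    subjectNeg2LL(p, s, st)
  }
  best <- at(1 / c_star)
  for (f in c(0.9, 0.97, 1.03, 1.1)) expect_gt(at(f / c_star), best)
})

test_that("AIC adds twice the parameter count and prefers parsimony on ties", {
  expect_equal(modelAIC(100, 9), 118)
  expect_error(modelAIC(0, 0))
  st_small <- pk_structure("two_compartment")
  st_big <- pk_structure("four_compartment_lag")
  expect_lt(modelAIC(500, nFittedParams(st_small)),
            modelAIC(500, nFittedParams(st_big)))
  expect_equal(nFittedParams(st_big), 9)
})

test_that("predictive diagnostics reproduce the direct formulas and are order-invariant", {
  obs <- c(1, 2, 3, 4)
  d <- predictiveDiagnostics(obs, obs, sds = rep(1, 4))
  expect_equal(d$bias, 0)
  expect_equal(d$imprecision, 0)
  expect_equal(d$r2, 1)

  d2 <- predictiveDiagnostics(obs, obs + 0.7, weighting = "unit")
  expect_equal(d2$bias, 0.7)
  expect_equal(d2$imprecision, 0, tolerance = 1e-12)

  set.seed(5)
  o <- runif(10, 1, 50)
  pr <- o + rnorm(10)
  sds <- 0.25 + 0.15 * o
  d3 <- predictiveDiagnostics(o, pr, sds)
  w <- (1 / sds^2) / sum(1 / sds^2)
  bias <- sum(w * (pr - o))
  expect_equal(d3$bias, bias)
  expect_equal(d3$imprecision, sum(w * ((pr - o) - bias)^2))
  expect_equal(d3$r2, stats::cor(o, pr)^2)

  idx <- sample(10)
  d4 <- predictiveDiagnostics(o[idx], pr[idx], sds[idx])
  expect_equal(d4, d3)

  expect_error(predictiveDiagnostics(rep(1, 3), c(1, 2, 3), rep(1, 3)),
               "zero variance")
})
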