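test_that("rate matrix has the conservation structure of the compartment diagram", {
  st2 <- pk_structure("two_compartment")
  A <- buildRateMatrix(pk_params(kel = 1, Vc = 1, V_CSF = 1, K13 = 1e-300,
                                 K41 = 1e-300), st2)
  expect_equal(unname(A), matrix(c(-1, 0, 0, 0), 2, 2), tolerance = 1e-12)

  st4 <- pk_structure("four_compartment_lag")
  A4 <- buildRateMatrix(cefepimeMedianParams(), st4)
  expect_equal(unname(colSums(A4)), c(-3.15, 0, 0, 0))
  expect_true(all(A4[row(A4) != col(A4)] >= 0))

  for (nm in c("two_compartment", "three_compartment",
               "three_compartment_lag_constant", "four_compartment_lag")) {
    st <- pk_structure(nm)
    set.seed(7)
    p <- random_params(st)
    A <- buildRateMatrix(p, st)
    expect_equal(sum(colSums(A)), -unclass(p)[["kel"]])
  }
})

test_that("rate matrix rejects missing or non-positive parameters", {
  st <- pk_structure("four_compartment_lag")
  expect_error(buildRateMatrix(pk_params(kel = 1, Vc = 1), st), "missing")
  bad <- cefepimeMedianParams()
  bad["K34"] <- -1
  expect_error(buildRateMatrix(bad, st), "non-positive")
})

test_that("amount solution matches closed forms and handles empty dosing", {
  st <- pk_structure("two_compartment")
  p <- pk_params(kel = 1, Vc = 1, V_CSF = 1, K13 = 1e-12, K41 = 1e-12)
  # one-compartment limit, bolus: X1(t) = D exp(-kel t)
  am <- solveAmounts(p, st, doseEvent(0, 100, 0), c(log(2), 2 * log(2)))
  expect_equal(am[, "central"], c(50, 25), tolerance = 1e-9)
  # no doses
  none <- solveAmounts(cefepimeMedianParams(),
                       pk_structure("four_compartment_lag"),
                       standardRegimen()[0, ], c(0, 1, 5))
  expect_true(all(none == 0))
})

test_that("matrix-exponential propagation matches the adaptive ODE oracle", {
  st <- pk_structure("four_compartment_lag")
  doses <- standardRegimen(306)
  times <- c(0.2, 1, 2, 8)
  ours <- solveAmounts(cefepimeMedianParams(), st, doses, times)
  orc <- oracle_amounts(cefepimeMedianParams(), st, doses, times)
  expect_lt(max(abs(ours - orc) / pmax(abs(orc), 1e-9)), 1e-6)

  # concentration route agrees too
  conc <- predictConcentrations(cefepimeMedianParams(), st, doses, 0.2,
                                "plasma")
  expect_equal(conc, orc[1, 1] / 0.11, tolerance = 1e-6)
})

test_that("solution is linear in dose and obeys superposition", {
  st <- pk_structure("four_compartment_lag")
  p <- cefepimeMedianParams()
  times <- c(0.5, 3, 26, 70)
  doses <- standardRegimen(306)
  base <- solveAmounts(p, st, doses, times)
  doubled <- doses
  doubled$amount <- doubled$amount * 2
  expect_equal(solveAmounts(p, st, doubled, times), 2 * base,
               tolerance = 1e-12)

  shifted <- Reduce(`+`, lapply(seq_len(nrow(doses)), function(i) {
    solveAmounts(p, st, doses[i, ], times)
  }))
  expect_equal(base, shifted, tolerance = 1e-9)
})

test_that("mass is conserved without elimination and decays monotonically with it", {
  st <- pk_structure("four_compartment_lag")
  p <- cefepimeMedianParams()
  p["kel"] <- 1e-300  # elimination off
  doses <- standardRegimen(306, n_days = 2)
  times <- seq(25, 72, by = 2)  # after the last infusion ends
  am <- solveAmounts(p, st, doses, times)
  expect_equal(rowSums(am), rep(2 * 45.9, length(times)), tolerance = 1e-9)

  p2 <- cefepimeMedianParams()
  am2 <- solveAmounts(p2, st, doses, times)
  expect_true(all(diff(rowSums(am2)) <= 1e-12))
  expect_true(all(am2 >= 0))
})

test_that("concentrations scale amounts by channel volume and validate the channel", {
  st <- pk_structure("four_compartment_lag")
  p <- cefepimeMedianParams()
  doses <- doseEvent(0, 45.9)
  am <- solveAmounts(p, st, doses, 0.5)
  expect_equal(predictConcentrations(p, st, doses, 0.5, "plasma"),
               unname(am[1, "central"]) / 0.11)
  expect_equal(predictConcentrations(p, st, doses, 0.5, "csf"),
               unname(am[1, "csf"]) / 0.14)
  expect_error(predictConcentrations(p, st, doses, 0.5, "brain"),
               "no output channel")
  expect_equal(predictConcentrations(p, st, doses[0, ], c(1, 2), "plasma"),
               c(0, 0))
})

test_that("overlapping infusions are summed, and the 45.9 mg dose follows from 306 g", {
  reg <- standardRegimen(306)
  expect_equal(unique(reg$amount), 45.9)
  st <- pk_structure("two_compartment")
  p <- pk_params(kel = 0.5, Vc = 1, V_CSF = 1, K13 = 0.2, K41 = 0.3)
  two <- rbind(doseEvent(0, 10, 1), doseEvent(0.5, 10, 1))
  one_wide <- solveAmounts(p, st, two, c(0.25, 0.75, 1.25, 2))
  orc <- oracle_amounts(p, st, two, c(0.25, 0.75, 1.25, 2))
  expect_lt(max(abs(one_wide - orc) / pmax(orc, 1e-9)), 1e-6)
})
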