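#' Candidate compartmental model structures
#'
#' The package fits four nested linear compartment models of cefepime
#' disposition. All have a central (plasma) compartment with first-order
#' elimination `kel` and a CSF compartment observed through its volume
#' `V_CSF`; they differ in whether a peripheral distribution compartment
#' (rates `K12`/`K21`) and an unobserved lag compartment on the way into the
#' CSF (`K13` into the lag, `K34` lag to CSF) are present:
#'
#' * `two_compartment`: central + CSF, direct exchange `K13` (central to CSF)
#'   and `K41` (CSF to central).
#' * `three_compartment`: adds the peripheral compartment to the above.
#' * `three_compartment_lag_constant`: central + lag + CSF; drug reaches the
#'   CSF only through the lag compartment (`K13`, `K34`), returning via `K41`.
#' * `four_compartment_lag`: the full model; states are X1 central,
#'   X2 peripheral, X3 lag, X4 CSF. Plasma concentration is X1/Vc and CSF
#'   concentration X4/V_CSF; the lag state has no output.
#'
#' @param name One of `"two_compartment"`, `"three_compartment"`,
#'   `"three_compartment_lag_constant"`, `"four_compartment_lag"`.
#' @return An object of class `pk_structure` with elements `name`, `states`
#'   (state labels), `n_state`, `active_params`, and `outputs`, a named list
#'   mapping each output channel to its state index and volume parameter.
#' @export
pk_structure <- function(name = c("four_compartment_lag", "two_compartment",
                                  "three_compartment",
                                  "three_compartment_lag_constant")) {
  name <- match.arg(name)
  def <- switch(name,
    two_compartment = list(
      states = c("central", "csf"),
      active = c("kel", "Vc", "V_CSF", "K13", "K41"),
      outputs = list(plasma = list(state = 1L, volume = "Vc"),
                     csf = list(state = 2L, volume = "V_CSF"))),
    three_compartment = list(
      states = c("central", "peripheral", "csf"),
      active = c("kel", "Vc", "V_CSF", "K12", "K21", "K13", "K41"),
      outputs = list(plasma = list(state = 1L, volume = "Vc"),
                     csf = list(state = 3L, volume = "V_CSF"))),
    three_compartment_lag_constant = list(
      states = c("central", "lag", "csf"),
      active = c("kel", "Vc", "V_CSF", "K13", "K34", "K41"),
      outputs = list(plasma = list(state = 1L, volume = "Vc"),
                     csf = list(state = 3L, volume = "V_CSF"))),
    four_compartment_lag = list(
      states = c("central", "peripheral", "lag", "csf"),
      active = c("kel", "Vc", "V_CSF", "K12", "K21", "K13", "K34", "K41"),
      outputs = list(plasma = list(state = 1L, volume = "Vc"),
                     csf = list(state = 4L, volume = "V_CSF"))))
  structure(list(name = name, states = def$states,
                 n_state = length(def$states),
                 active_params = def$active, outputs = def$outputs),
            class = "pk_structure")
}

#' @export
print.pk_structure <- function(x, ...) {
  cat("<pk_structure>", x$name, "\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  parameters:", paste(x$active_params, collapse = ", "), "\n")
  invisible(x)
}

#' Pharmacokinetic parameter vector
#'
#' Rate constants in 1/h, volumes in liters. Only the parameters active in a
#' given structure are required when the vector is used with that structure.
#'
#' @param kel Elimination rate constant from the central compartment (1/h).
#' @param Vc Volume of the central compartment (liters).
#' @param V_CSF Volume of the CSF compartment (liters).
#' @param K12,K21 Central/peripheral exchange rate constants (1/h).
#' @param K13 Rate constant out of the central compartment toward the CSF
#'   pathway (1/h).
#' @param K34 Lag-to-CSF rate constant (1/h).
#' @param K41 CSF-to-central return rate constant (1/h).
#' @return Named numeric vector of class `pk_params`.
#' @export
pk_params <- function(kel = NA_real_, Vc = NA_real_, V_CSF = NA_real_,
                      K12 = NA_real_, K21 = NA_real_, K13 = NA_real_,
                      K34 = NA_real_, K41 = NA_real_) {
  p <- c(kel = kel, Vc = Vc, V_CSF = V_CSF, K12 = K12, K21 = K21,
         K13 = K13, K34 = K34, K41 = K41)
  class(p) <- "pk_params"
  p
}

#' Reported median population parameters of the final cefepime model
#'
#' @return A `pk_params` vector of the reported median values.
#' @export
cefepimeMedianParams <- function() {
  pk_params(kel = 3.15, Vc = 0.11, V_CSF = 0.14, K12 = 18.20, K21 = 41.98,
            K13 = 0.13, K34 = 2.96, K41 = 0.47)
}

#' Reported CV% of the population parameters of the final cefepime model
#'
#' @return Named numeric vector of coefficients of variation in percent.
#' @export
cefepimeParamCV <- function() {
  c(kel = 7.5, Vc = 22.9, V_CSF = 64.4, K12 = 40.2, K21 = 10,
    K13 = 23.4, K34 = 116.3, K41 = 54.9)
}

check_active_params <- function(params, structure) {
  need <- structure$active_params
  p <- unclass(params)[need]
  if (anyNA(p)) {
    stop("missing active parameter(s) for structure '", structure$name,
         "': ", paste(need[is.na(p)], collapse = ", "), call. = FALSE)
  }
  if (any(p <= 0)) {
    stop("non-positive active parameter(s): ",
         paste(need[p <= 0], collapse = ", "), call. = FALSE)
  }
  p
}

#' Assemble the first-order rate matrix of a model structure
#'
#' Column j holds the flows out of state j: `A[i, j]` is the rate constant
#' from state j into state i and `A[j, j]` minus the total outflow. Only the
#' central compartment loses mass to the outside (at rate `kel`), so every
#' column sums to zero except the first, which sums to `-kel`.
#'
#' @param params A [pk_params()] vector; all parameters active in `structure`
#'   must be present and positive.
#' @param structure A [pk_structure()].
#' @return A square numeric matrix over the structure's states.
#' @export
buildRateMatrix <- function(params, structure) {
  p <- check_active_params(params, structure)
  n <- structure$n_state
  A <- matrix(0, n, n, dimnames = list(structure$states, structure$states))
  link <- function(from, to, rate) {
    A[to, from] <<- A[to, from] + rate
    A[from, from] <<- A[from, from] - rate
  }
  A[1, 1] <- -p[["kel"]]
  switch(structure$name,
    two_compartment = {
      link(1, 2, p[["K13"]]); link(2, 1, p[["K41"]])
    },
    three_compartment = {
      link(1, 2, p[["K12"]]); link(2, 1, p[["K21"]])
      link(1, 3, p[["K13"]]); link(3, 1, p[["K41"]])
    },
    three_compartment_lag_constant = {
      link(1, 2, p[["K13"]]); link(2, 3, p[["K34"]]); link(3, 1, p[["K41"]])
    },
    four_compartment_lag = {
      link(1, 2, p[["K12"]]); link(2, 1, p[["K21"]])
      link(1, 3, p[["K13"]]); link(3, 4, p[["K34"]]); link(4, 1, p[["K41"]])
    })
  A
}

#' One intravenous dose event
#'
#' @param start_time Hours since the first dose.
#' @param amount Dose amount in mg.
#' @param infusion_duration Duration of the zero-order input in hours; `0`
#'   means an instantaneous bolus. The study's 2-minute injection is `1/30`.
#' @return A one-row data frame with columns `start`, `amount`, `duration`.
#' @export
doseEvent <- function(start_time, amount, infusion_duration = 1 / 30) {
  stopifnot(start_time >= 0, amount >= 0, infusion_duration >= 0)
  data.frame(start = start_time, amount = amount,
             duration = infusion_duration)
}

#' Standard multi-dose regimen of the study design
#'
#' One short intravenous infusion per day.
#'
#' @param weight_g Body weight in grams.
#' @param mg_per_kg Dose in mg per kg body weight.
#' @param n_days Number of once-daily doses.
#' @param infusion_h Infusion duration in hours.
#' @return Data frame of dose events (see [doseEvent()]).
#' @export
standardRegimen <- function(weight_g = 306, mg_per_kg = 150, n_days = 4,
                            infusion_h = 1 / 30) {
  amount <- weight_g / 1000 * mg_per_kg
  do.call(rbind, lapply(24 * (seq_len(n_days) - 1),
                        function(t0) doseEvent(t0, amount, infusion_h)))
}

#' One animal's record: weight, dose events and observations
#'
#' @param id Subject label.
#' @param weight Body weight in grams.
#' @param doses Data frame of dose events (columns `start`, `amount`,
#'   `duration`), e.g. from [standardRegimen()].
#' @param observations Data frame with columns `time` (h), `value` (ug/ml),
#'   `output` (`"plasma"` or `"csf"`), and optionally `excluded` (0/1) and
#'   `bloq` (below the assay's lower limit of quantification, 0/1).
#' @return An object of class `subject_record`.
#' @export
subjectRecord <- function(id, weight, doses, observations) {
  stopifnot(is.data.frame(doses), nrow(doses) >= 1, weight > 0)
  if (is.null(observations) || nrow(observations) == 0) {
    observations <- data.frame(time = numeric(), value = numeric(),
                               output = character(), excluded = integer(),
                               bloq = integer())
  }
  if (is.null(observations$excluded)) observations$excluded <- 0L
  if (is.null(observations$bloq)) observations$bloq <- 0L
  bad <- !observations$output %in% c("plasma", "csf")
  if (any(bad)) stop("unknown output channel: ",
                     paste(unique(observations$output[bad]), collapse = ", "))
  if (any(observations$value < 0 & observations$excluded == 0)) {
    stop("negative concentration in non-excluded observation")
  }
  structure(list(id = as.character(id), weight = weight, doses = doses,
                 observations = observations),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  n_pl <- sum(x$observations$output == "plasma")
  n_csf <- sum(x$observations$output == "csf")
  cat("<subject_record>", x$id, sprintf("(%g g)", x$weight), "\n")
  cat(sprintf("  %d dose(s); %d plasma + %d CSF observation(s)\n",
              nrow(x$doses), n_pl, n_csf))
  invisible(x)
}

as_dose_matrix <- function(doses) {
  as.matrix(doses[, c("start", "amount", "duration"), drop = FALSE])
}

#' Exact amounts in every compartment over time
#'
#' Solves the linear system of the chosen structure under the given dose
#' events by matrix-exponential propagation over the piecewise-constant
#' input, which is exact up to the accuracy of the matrix exponential.
#' Overlapping infusion windows are summed.
#'
#' @inheritParams buildRateMatrix
#' @param doses Data frame of dose events; may have zero rows.
#' @param times Sorted non-negative vector of times (h).
#' @return Matrix `length(times) x n_state` of amounts (mg), columns named
#'   after the structure's states.
#' @export
solveAmounts <- function(params, structure, doses, times) {
  stopifnot(all(times >= 0), !is.unsorted(times))
  A <- buildRateMatrix(params, structure)
  if (is.null(doses) || nrow(doses) == 0) {
    out <- matrix(0, length(times), structure$n_state)
  } else {
    out <- solve_amounts_cpp(A, as_dose_matrix(doses), as.numeric(times))
    out[out < 0 & out > -1e-12] <- 0  # clip matrix-exponential round-off
  }
  colnames(out) <- structure$states
  out
}

#' Predicted concentration-time course for one output channel
#'
#' Concentration is the compartment amount divided by the channel's volume;
#' with amounts in mg and volumes in liters the result is mg/liter, i.e.
#' ug/ml.
#'
#' @inheritParams solveAmounts
#' @param output Output channel, `"plasma"` or `"csf"`.
#' @return Numeric vector of concentrations (ug/ml) at `times`.
#' @export
predictConcentrations <- function(params, structure, doses, times,
                                  output = "plasma") {
  out <- structure$outputs[[output]]
  if (is.null(out)) {
    stop("structure '", structure$name, "' has no output channel '", output,
         "'", call. = FALSE)
  }
  amounts <- solveAmounts(params, structure, doses, times)
  unname(amounts[, out$state]) / unclass(params)[[out$volume]]
}
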