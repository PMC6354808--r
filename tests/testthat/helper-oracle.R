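# Independent adaptive-step numeric integration of the compartment system,
# used as the oracle against the package's matrix-exponential propagation.
# Integrates segment-by-segment between dose boundaries so short infusion
# windows are never stepped over.
oracle_amounts <- function(params, structure, doses, times) {
  A <- buildRateMatrix(params, structure)
  n <- nrow(A)
  bps <- sort(unique(c(0, doses$start, doses$start + doses$duration, times)))
  x <- rep(0, n)
  out <- matrix(NA_real_, length(times), n)
  for (k in seq_along(bps)) {
    t0 <- bps[k]
    bol <- doses$duration == 0 & abs(doses$start - t0) < 1e-12
    x[1] <- x[1] + sum(doses$amount[bol])
    hit <- which(abs(times - t0) < 1e-12)
    if (length(hit) > 0) out[hit, ] <- matrix(x, length(hit), n, byrow = TRUE)
    if (k == length(bps)) break
    t1 <- bps[k + 1]
    act <- doses$duration > 0 & doses$start <= t0 + 1e-12 &
      doses$start + doses$duration >= t1 - 1e-12
    rate <- sum(doses$amount[act] / doses$duration[act])
    deriv <- function(t, y, parms) list(A %*% y + c(rate, rep(0, n - 1)))
    sol <- deSolve::ode(x, c(t0, t1), deriv, NULL, rtol = 1e-10,
                        atol = 1e-12)
    x <- as.numeric(sol[nrow(sol), -1])
  }
  out
}

# random positive parameter draw around the reported medians (log-normal,
# sdlog 0.5), restricted to a structure's active parameters
random_params <- function(structure, medians = cefepimeMedianParams()) {
  m <- unclass(medians)[structure$active_params]
  p <- stats::rlnorm(length(m), meanlog = log(m), sdlog = 0.5)
  names(p) <- names(m)
  class(p) <- "pk_params"
  p
}

# small noiseless subject for likelihood/fit toys
toy_subject <- function(params, structure, id = "t1", weight = 306,
                        doses = standardRegimen(weight, n_days = 1),
                        plasma_times = c(0.2, 0.5, 1, 2, 4, 8),
                        csf_times = c(0.5, 1, 2, 4),
                        noise_sd = 0, seed = NULL) {
  times <- c(plasma_times, csf_times)
  outs <- c(rep("plasma", length(plasma_times)),
            rep("csf", length(csf_times)))
  conc <- vapply(seq_along(times), function(k) {
    predictConcentrations(params, structure, doses, times[k], outs[k])
  }, 1)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    conc <- pmax(conc + stats::rnorm(length(conc), 0, noise_sd), 0)
  }
  subjectRecord(id, weight,
                doses, data.frame(time = times, value = conc, output = outs))
}

# rich-sampling validation design (12 plasma + 8 CSF samples in 24 h)
rich_design <- function(n_animals = 25) validationDesign(n_animals)

# exhaustive mesh search over the probability simplex: minimum population
# -2LL over all weight vectors with components that are multiples of 1/mesh.
# The last two coordinates are vectorized; the rest are enumerated.
bruteforce_simplex_neg2ll <- function(logL, mesh) {
  k <- ncol(logL)
  m_i <- apply(logL, 1, max)
  P <- exp(logL - m_i)
  best <- Inf
  rec <- function(prefix, m_left, depth) {
    if (depth == k - 2) {
      b <- 0:m_left
      W <- cbind(matrix(rep(prefix, each = length(b)), nrow = length(b)),
                 b, m_left - b) / mesh
      lik <- W %*% t(P)
      vals <- -2 * (rowSums(log(lik)) + sum(m_i))
      best <<- min(best, vals)
    } else {
      for (i in 0:m_left) rec(c(prefix, i), m_left - i, depth + 1)
    }
  }
  rec(integer(0), mesh, 0)
  best
}

# subject-by-point log-likelihood matrix through the public API
public_loglik_matrix <- function(dataset, points, structure,
                                 errmod = errorModel()) {
  logL <- sapply(seq_len(nrow(points)), function(j) {
    p <- points[j, ]
    class(p) <- "pk_params"
    vapply(dataset, function(s) {
      -0.5 * subjectNeg2LL(p, s, structure, errmod)
    }, 1)
  })
  matrix(logL, nrow = length(dataset))
}

# population -2LL recomputed directly from subject likelihoods (independent
# of the package's weight optimizer)
direct_population_neg2ll <- function(dataset, points, structure, w,
                                     errmod = errorModel()) {
  logL <- sapply(seq_len(nrow(points)), function(j) {
    p <- points[j, ]
    class(p) <- "pk_params"
    vapply(dataset, function(s) {
      -0.5 * subjectNeg2LL(p, s, structure, errmod)
    }, 1)
  })
  logL <- matrix(logL, nrow = length(dataset))
  m <- apply(logL, 1, max)
  -2 * sum(log(exp(logL - m) %*% w) + m)
}
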