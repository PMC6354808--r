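#' Parameter search box for the population fit
#'
#' @param structure A [pk_structure()].
#' @param medians Named centre values; defaults to the reported medians of
#'   the final cefepime model.
#' @param lower_mult,upper_mult Multipliers defining the box around each
#'   centre value (default one tenth to ten times the centre).
#' @return Object of class `param_bounds`: list with named `lower` and
#'   `upper` vectors over the structure's active parameters.
#' @export
paramBounds <- function(structure, medians = cefepimeMedianParams(),
                        lower_mult = 0.1, upper_mult = 10) {
  m <- unclass(medians)[structure$active_params]
  if (anyNA(m) || any(m <= 0)) stop("positive centre value required for every active parameter")
  stopifnot(lower_mult > 0, upper_mult > lower_mult)
  structure(list(lower = m * lower_mult, upper = m * upper_mult),
            class = "param_bounds")
}

#' Bounds from explicit limits
#' @param lower,upper Named vectors, 0 < lower < upper elementwise.
#' @return A `param_bounds` object.
#' @export
makeBounds <- function(lower, upper) {
  stopifnot(identical(names(lower), names(upper)),
            all(lower > 0), all(upper > lower))
  structure(list(lower = lower, upper = upper), class = "param_bounds")
}

#' Initial support-point grid
#'
#' Fills the search box with a Latin hypercube sample drawn uniformly on the
#' log scale of each axis (the default boxes span two decades, so log-uniform
#' coverage is even in relative terms). All points receive equal weight
#' 1/n_points.
#'
#' @param bounds A [paramBounds()] box.
#' @param n_points Number of support points, >= 1.
#' @param seed Integer seed; the grid is reproducible given the seed.
#' @return List with `points` (matrix `n_points x p`, columns named after the
#'   parameters) and `weights` (all `1/n_points`).
#' @export
initializeGrid <- function(bounds, n_points, seed) {
  stopifnot(n_points >= 1)
  lo <- log(bounds$lower); hi <- log(bounds$upper)
  if (any(!is.finite(lo)) || any(hi <= lo)) stop("degenerate bounds")
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_points, length(lo))
  pts <- exp(sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  colnames(pts) <- names(bounds$lower)
  list(points = pts, weights = rep(1 / n_points, n_points))
}

# log-likelihood matrix pieces for a set of support points:
# SS[i, j] = weighted residual sum of squares of subject i at point j.
# -2LL_ij(gamma) = const_i + 2 n_i log(gamma) + SS_ij / gamma^2.
loglik_pieces <- function(contexts, points, structure) {
  n_sub <- length(contexts)
  SS <- matrix(NA_real_, n_sub, nrow(points))
  for (j in seq_len(nrow(points))) {
    p <- points[j, ]
    class(p) <- "pk_params"
    A <- buildRateMatrix(p, structure)
    for (i in seq_len(n_sub)) {
      SS[i, j] <- context_ss(contexts[[i]],
                             context_predict(contexts[[i]], A, p))
    }
  }
  SS
}

loglik_matrix <- function(SS, contexts, gamma) {
  n_i <- vapply(contexts, `[[`, 1, "n")
  const_i <- vapply(contexts, `[[`, 1, "const")
  -0.5 * (sweep(SS / gamma^2, 1, const_i + 2 * n_i * log(gamma), "+"))
}

# Population -2LL for weights w given logL (subjects x points), computed with
# per-subject scaling to avoid underflow.
population_neg2ll <- function(logL, w) {
  m <- apply(logL, 1, max)
  P <- exp(logL - m)
  lik <- as.vector(P %*% w)
  if (any(lik <= 0)) return(Inf)
  -2 * sum(log(lik) + m)
}

# Per-subject maximum-likelihood points: starting from each subject's best
# initial-grid point, maximize that subject's own log-likelihood by
# Nelder-Mead in log-parameter space (two rounds), clamped to the box. The
# resulting points seed the population support in the basin the data favour
# before any population-level refinement.
subject_mle_points <- function(contexts, grid_points, SSgrid, structure,
                               gamma, bounds, maxit = 1500) {
  loglo <- log(bounds$lower)
  loghi <- log(bounds$upper)
  pn <- colnames(grid_points)
  logLg <- loglik_matrix(SSgrid, contexts, gamma)
  out <- matrix(NA_real_, length(contexts), length(pn),
                dimnames = list(NULL, pn))
  for (i in seq_along(contexts)) {
    ctx <- contexts[[i]]
    obj <- function(lp) {
      lp <- pmin(pmax(lp, loglo), loghi)
      p <- exp(lp)
      names(p) <- pn
      class(p) <- "pk_params"
      A <- buildRateMatrix(p, structure)
      neg2ll_from_ss(context_ss(ctx, context_predict(ctx, A, p)),
                     ctx$const, ctx$n, gamma)
    }
    start <- log(grid_points[which.max(logLg[i, ]), ])
    o <- tryCatch({
      o1 <- stats::optim(start, obj, method = "Nelder-Mead",
                         control = list(maxit = maxit))
      stats::optim(o1$par, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit))
    }, error = function(e) NULL)
    out[i, ] <- if (is.null(o)) exp(start) else
      exp(pmin(pmax(o$par, loglo), loghi))
  }
  unique(out)
}

# Generalized-EM relocation: move each support point carrying weight toward
# the maximizer of its responsibility-weighted subject log-likelihood
# (a short Nelder-Mead in log-parameter space, clamped to the box). The
# relocated points are returned as candidates; appending them and re-solving
# the weights can only improve the mixture likelihood.
relocate_candidates <- function(points, SS, w, contexts, structure, gamma,
                                bounds, min_weight = 1e-4, maxit = 400) {
  logL <- loglik_matrix(SS, contexts, gamma)
  m <- apply(logL, 1, max)
  P <- exp(logL - m)
  denom <- as.vector(P %*% w)
  idx <- which(w > min_weight)
  if (length(idx) == 0) return(NULL)
  loglo <- log(bounds$lower)
  loghi <- log(bounds$upper)
  pn <- colnames(points)
  cands <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    j <- idx[k]
    r_ij <- w[j] * P[, j] / denom
    if (sum(r_ij) < 1e-10) next
    obj <- function(lp) {
      lp <- pmin(pmax(lp, loglo), loghi)
      p <- exp(lp)
      names(p) <- pn
      class(p) <- "pk_params"
      A <- buildRateMatrix(p, structure)
      ll <- vapply(seq_along(contexts), function(i) {
        ctx <- contexts[[i]]
        -0.5 * neg2ll_from_ss(context_ss(ctx, context_predict(ctx, A, p)),
                              ctx$const, ctx$n, gamma)
      }, 1)
      -sum(r_ij * ll)
    }
    o <- tryCatch(stats::optim(log(points[j, ]), obj,
                               method = "Nelder-Mead",
                               control = list(maxit = maxit,
                                              reltol = 1e-9)),
                  error = function(e) NULL)
    if (!is.null(o)) {
      cands[[k]] <- exp(pmin(pmax(o$par, loglo), loghi))
    }
  }
  cands <- cands[!vapply(cands, is.null, TRUE)]
  if (length(cands) == 0) return(NULL)
  out <- do.call(rbind, cands)
  colnames(out) <- pn
  out
}

# EM (multiplicative) update of mixing weights on the probability simplex.
# Each iteration cannot decrease the likelihood; stops when the KKT residual
# max_j |mean_i P_ij / (P w)_i - 1| over supported weights falls below tol.
optimize_weights <- function(logL, w0 = NULL, tol = 1e-8, max_iter = 5000) {
  n_sub <- nrow(logL); n_pt <- ncol(logL)
  m <- apply(logL, 1, max)
  P <- exp(logL - m)
  w <- if (is.null(w0)) rep(1 / n_pt, n_pt) else w0 / sum(w0)
  for (it in seq_len(max_iter)) {
    denom <- as.vector(P %*% w)
    if (any(denom <= 0)) stop("no finite-likelihood support point; widen the bounds")
    g <- as.vector(crossprod(P, 1 / denom)) / n_sub
    kkt <- max(abs(g[w > 0] - 1))
    w <- w * g
    w <- pmax(w, 0); w <- w / sum(w)
    if (kkt < tol) break
  }
  list(weights = w, neg2ll = population_neg2ll(logL, w))
}

#' Nonparametric population fit on an adaptive support-point grid
#'
#' Estimates the population distribution of the PK parameters as a discrete
#' set of support points with mixing weights, in the spirit of the
#' nonparametric adaptive grid (NPAG) algorithm. Each cycle (a) evaluates the
#' likelihood of every subject at every new support point, (b) maximises the
#' mixture likelihood over the weight simplex by monotone EM updates across
#' all points evaluated so far, and (c) proposes new points by perturbing the
#' points that carry weight along each axis of the (log-scale) box by a
#' fraction that halves every cycle. Because earlier points stay available to
#' the weight optimization, the -2LL trajectory is non-increasing. Cycling
#' stops when the improvement falls below `convergence_tol` (once the
#' expansion has shrunk to inactivity) or at `max_cycles`; points carrying
#' negligible weight are condensed away from the returned support.
#'
#' @param dataset List of [subjectRecord()]s (>= 1 subject, each with
#'   observations).
#' @param structure A [pk_structure()].
#' @param bounds A [paramBounds()] box over the active parameters.
#' @param n_init Number of initial grid points.
#' @param seed Integer seed governing all stochastic steps (required).
#' @param errmod An [errorModel()].
#' @param condense_tol Weight below which a support point is dropped.
#' @param convergence_tol Stop when the accepted -2LL improves by less.
#' @param max_cycles Maximum number of cycles.
#' @param expansion_frac Initial perturbation size as a fraction of the box;
#'   halves each cycle; `0` disables expansion (fixed-grid weight fit).
#' @param estimate_gamma If `TRUE`, the shared multiplicative error scale is
#'   re-estimated by 1-D maximum likelihood once per cycle; default keeps
#'   gamma fixed at its `errmod` value.
#' @param max_relocations Upper bound on the number of relocation sweeps
#'   (the generalized-EM refinement is the costly step; the cap keeps the
#'   fit's run time predictable).
#' @param init_points Optional matrix of starting support points (columns =
#'   active parameters), replacing the random grid.
#' @return Object of class `population_model`: support point matrix,
#'   `weights`, `gamma`, `neg2ll`, `aic`, per-cycle log, the inputs, and
#'   convergence information.
#' @export
fitPopulation <- function(dataset, structure, bounds = paramBounds(structure),
                          n_init = 40 * length(structure$active_params),
                          seed, errmod = errorModel(),
                          condense_tol = 1e-8, convergence_tol = 0.01,
                          max_cycles = 100, expansion_frac = 0.2,
                          estimate_gamma = FALSE, init_points = NULL,
                          max_relocations = 12) {
  if (missing(seed)) stop("fitPopulation requires an explicit seed")
  stopifnot(length(dataset) >= 1)
  contexts <- lapply(dataset, subject_context, structure = structure,
                     errmod = errmod)
  if (any(vapply(contexts, is.null, TRUE))) {
    stop("every subject must have at least one non-excluded observation")
  }
  pn <- names(bounds$lower)
  if (!setequal(pn, structure$active_params)) {
    stop("bounds must cover exactly the structure's active parameters")
  }

  if (is.null(init_points)) {
    grid <- initializeGrid(bounds, n_init, seed)
    points <- grid$points
  } else {
    points <- as.matrix(init_points)[, pn, drop = FALSE]
  }
  gamma <- errmod$gamma
  SS <- loglik_pieces(contexts, points, structure)
  if (expansion_frac > 0 && is.null(init_points)) {
    # seed the support with each subject's own maximum-likelihood point,
    # started from its best grid point (two-stage initialization)
    mle_pts <- subject_mle_points(contexts, points, SS, structure, gamma,
                                  bounds)
    points <- rbind(points, mle_pts)
    SS <- cbind(SS, loglik_pieces(contexts, mle_pts, structure))
  }
  opt <- optimize_weights(loglik_matrix(SS, contexts, gamma))
  w <- opt$weights
  best <- opt$neg2ll

  # condense: drop negligible-weight points, keeping the matrix small
  keep <- w > condense_tol
  points <- points[keep, , drop = FALSE]
  SS <- SS[, keep, drop = FALSE]
  w <- w[keep] / sum(w[keep])
  best <- population_neg2ll(loglik_matrix(SS, contexts, gamma), w)

  cycle_log <- data.frame(cycle = 0L, neg2ll = best,
                          n_support = nrow(points), gamma = gamma)
  frac <- expansion_frac
  frac_min <- expansion_frac / 2^9
  loglo <- log(bounds$lower)
  loghi <- log(bounds$upper)
  lbox <- loghi - loglo
  converged <- FALSE
  n_reloc <- 0L
  sig <- function(m) apply(m, 1, function(r) paste(signif(r, 12),
                                                   collapse = "|"))

  for (cyc in seq_len(max_cycles)) {
    improved <- 0
    shrink <- FALSE
    if (frac > 0) {
      # expansion: axis-wise +/- perturbations of every surviving point on
      # the log scale (where the box is defined multiplicatively), clamped
      # to the box; candidates join the grid and the weights are re-solved.
      # The perturbation fraction halves whenever a cycle fails to improve
      # (pattern-search schedule).
      cand <- list()
      for (ax in seq_along(pn)) {
        for (sgn in c(-1, 1)) {
          pts <- points
          pts[, ax] <- exp(pmin(pmax(log(pts[, ax]) + sgn * frac * lbox[ax],
                                     loglo[ax]), loghi[ax]))
          cand[[length(cand) + 1]] <- pts
        }
      }
      cand <- unique(do.call(rbind, cand))
      cand <- cand[!sig(cand) %in% sig(points), , drop = FALSE]
      if (nrow(cand) > 0) {
        SSc <- loglik_pieces(contexts, cand, structure)
        eps <- 1e-10
        w0 <- c(w * (1 - eps * nrow(cand)), rep(eps, nrow(cand)))
        opt <- optimize_weights(loglik_matrix(cbind(SS, SSc), contexts,
                                              gamma), w0)
        if (opt$neg2ll < best) {
          improved <- best - opt$neg2ll
          best <- opt$neg2ll
          points <- rbind(points, cand)
          SS <- cbind(SS, SSc)
          w <- opt$weights
        }
      }

      # when axis perturbations stall, relocate the weighted points toward
      # their responsibility-weighted subject likelihood optima (GEM step)
      # and shrink the perturbation, so each step level triggers at most one
      # relocation sweep
      if (improved < convergence_tol) {
        shrink <- TRUE
        reloc <- if (n_reloc < max_relocations) {
          n_reloc <- n_reloc + 1
          relocate_candidates(points, SS, w, contexts, structure,
                              gamma, bounds)
        } else NULL
        if (!is.null(reloc)) {
          reloc <- unique(reloc)
          reloc <- reloc[!sig(reloc) %in% sig(points), , drop = FALSE]
        }
        if (!is.null(reloc) && nrow(reloc) > 0) {
          SSr <- loglik_pieces(contexts, reloc, structure)
          eps <- 1e-10
          w0 <- c(w * (1 - eps * nrow(reloc)), rep(eps, nrow(reloc)))
          opt <- optimize_weights(loglik_matrix(cbind(SS, SSr), contexts,
                                                gamma), w0)
          if (opt$neg2ll < best) {
            improved <- improved + (best - opt$neg2ll)
            best <- opt$neg2ll
            points <- rbind(points, reloc)
            SS <- cbind(SS, SSr)
            w <- opt$weights
          }
        }
      }
    }

    if (estimate_gamma) {
      gfit <- stats::optimize(function(g) {
        population_neg2ll(loglik_matrix(SS, contexts, g), w)
      }, interval = c(gamma / 10, gamma * 10))
      if (gfit$objective < best - 1e-12) {
        improved <- improved + (best - gfit$objective)
        gamma <- gfit$minimum
        opt <- optimize_weights(loglik_matrix(SS, contexts, gamma), w)
        best <- min(gfit$objective, opt$neg2ll)
        w <- opt$weights
      }
    }

    # condense
    keep <- w > condense_tol
    if (any(!keep)) {
      points <- points[keep, , drop = FALSE]
      SS <- SS[, keep, drop = FALSE]
      w <- w[keep] / sum(w[keep])
      opt <- optimize_weights(loglik_matrix(SS, contexts, gamma), w)
      best <- opt$neg2ll
      w <- opt$weights
    }

    cycle_log <- rbind(cycle_log,
                       data.frame(cycle = cyc, neg2ll = best,
                                  n_support = nrow(points), gamma = gamma))
    if (frac == 0) {
      if (improved < convergence_tol) {
        converged <- TRUE
        break
      }
    } else if (shrink) {
      if (frac <= frac_min) {
        if (improved < convergence_tol) {
          converged <- TRUE
          break
        }
      } else {
        frac <- frac / 2
      }
    }
  }

  model <- list(
    structure = structure, support = points, weights = w, gamma = gamma,
    errmod = errorModel(unname(errmod$plasma["c0"]),
                        unname(errmod$plasma["c1"]),
                        unname(errmod$csf["c0"]), unname(errmod$csf["c1"]),
                        gamma),
    neg2ll = best, aic = modelAIC(best, nFittedParams(structure)),
    cycle_log = cycle_log, bounds = bounds, converged = converged,
    seed = seed,
    settings = list(n_init = n_init, condense_tol = condense_tol,
                    convergence_tol = convergence_tol,
                    max_cycles = max_cycles,
                    expansion_frac = expansion_frac,
                    estimate_gamma = estimate_gamma))
  class(model) <- "population_model"
  model
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model>", x$structure$name, "\n")
  cat(sprintf("  %d support point(s); -2LL = %.3f; AIC = %.3f; gamma = %.3g\n",
              nrow(x$support), x$neg2ll, x$aic, x$gamma))
  cat(sprintf("  %d cycle(s); converged: %s\n",
              max(x$cycle_log$cycle), x$converged))
  med <- populationMedians(x)
  cat("  weighted medians:\n")
  print(round(med, 4))
  invisible(x)
}

#' Weighted quantile of a discrete distribution
#'
#' Lower weighted quantile: the smallest value whose cumulative weight
#' reaches the probability `p`; when the cumulative weight hits `p` exactly,
#' the midpoint to the next value is returned.
#'
#' @param x Values. @param w Nonnegative weights. @param p Probability.
#' @return Scalar quantile.
#' @export
weightedQuantile <- function(x, w, p = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]; cw <- cumsum(w[ord]) / sum(w)
  k <- which(cw >= p - 1e-12)[1]
  if (abs(cw[k] - p) < 1e-12 && k < length(x)) (x[k] + x[k + 1]) / 2 else x[k]
}

#' Weighted medians of the fitted population distribution
#' @param model A [fitPopulation()] result.
#' @return Named vector of per-parameter weighted medians.
#' @export
populationMedians <- function(model) {
  vapply(colnames(model$support), function(pn) {
    weightedQuantile(model$support[, pn], model$weights, 0.5)
  }, 1)
}

#' Discrete Bayesian posterior over the population support points
#'
#' posterior_j is proportional to prior weight_j times the subject's
#' likelihood at point j. A subject with no usable observations returns the
#' prior unchanged, with a warning.
#'
#' @param subject A [subjectRecord()].
#' @param model A fitted [fitPopulation()] model.
#' @return Numeric vector of posterior weights (sums to 1).
#' @export
bayesianPosterior <- function(subject, model) {
  ctx <- subject_context(subject, model$structure, model$errmod)
  if (is.null(ctx)) {
    warning("subject '", subject$id,
            "' has no usable observations; returning the population prior")
    return(model$weights)
  }
  logL <- vapply(seq_len(nrow(model$support)), function(j) {
    p <- model$support[j, ]
    class(p) <- "pk_params"
    A <- buildRateMatrix(p, model$structure)
    -0.5 * neg2ll_from_ss(context_ss(ctx, context_predict(ctx, A, p)),
                          ctx$const, ctx$n, model$gamma)
  }, 1)
  lp <- log(model$weights) + logL
  keep <- model$weights > 0
  lp[!keep] <- -Inf
  post <- exp(lp - max(lp[keep]))
  post / sum(post)
}

#' Posterior-predicted concentration profile on a fixed time grid
#'
#' Predicts both output channels at `grid_step` intervals from 0 to
#' `horizon` for every support point using the subject's own dose events,
#' and aggregates across points by the posterior-weighted median (default;
#' the weighted mean and the single maximum-posterior point are available).
#' The default 0.2 h step is the study's 12-minute reporting grid, giving
#' 121 points over 24 h.
#'
#' @param subject A [subjectRecord()].
#' @param model A fitted [fitPopulation()] model.
#' @param grid_step Grid spacing in hours.
#' @param horizon End of the grid (h); must be a multiple of `grid_step`.
#' @param aggregate `"weighted_median"`, `"weighted_mean"` or `"map_point"`.
#' @param posterior Optional precomputed [bayesianPosterior()] weights.
#' @return Object of class `posterior_profile`: data frame with columns
#'   `time`, `plasma`, `csf`.
#' @export
posteriorProfile <- function(subject, model, grid_step = 0.2, horizon = 24,
                             aggregate = c("weighted_median",
                                           "weighted_mean", "map_point"),
                             posterior = NULL) {
  aggregate <- match.arg(aggregate)
  n_step <- horizon / grid_step
  if (abs(n_step - round(n_step)) > 1e-9) {
    stop("horizon must be a multiple of grid_step")
  }
  times <- grid_step * 0:round(n_step)
  if (is.null(posterior)) {
    posterior <- suppressWarnings(bayesianPosterior(subject, model))
  }
  if (length(posterior) != nrow(model$support) || sum(posterior) <= 0) {
    stop("empty or mismatched posterior")
  }
  doses <- subject$doses
  channels <- names(model$structure$outputs)
  use <- which(posterior > 1e-12)
  if (aggregate == "map_point") use <- which.max(posterior)
  pred <- array(dim = c(length(times), length(channels), length(use)))
  for (k in seq_along(use)) {
    p <- model$support[use[k], ]
    class(p) <- "pk_params"
    am <- solveAmounts(p, model$structure, doses, times)
    for (c_i in seq_along(channels)) {
      out <- model$structure$outputs[[channels[c_i]]]
      pred[, c_i, k] <- am[, out$state] / p[[out$volume]]
    }
  }
  w <- posterior[use]
  agg <- switch(aggregate,
    weighted_median = function(v) weightedQuantile(v, w, 0.5),
    weighted_mean = function(v) sum(v * w) / sum(w),
    map_point = function(v) v)
  prof <- data.frame(time = times)
  for (c_i in seq_along(channels)) {
    prof[[channels[c_i]]] <- apply(pred[, c_i, , drop = FALSE], 1, agg)
  }
  class(prof) <- c("posterior_profile", "data.frame")
  prof
}

#' Posterior-predicted concentrations at the observation times
#'
#' @inheritParams posteriorProfile
#' @return The subject's non-excluded observations with a `predicted` column.
#' @export
posteriorPredictions <- function(subject, model,
                                 aggregate = c("weighted_median",
                                               "weighted_mean", "map_point"),
                                 posterior = NULL) {
  aggregate <- match.arg(aggregate)
  ctx <- subject_context(subject, model$structure, model$errmod)
  if (is.null(ctx)) stop("subject has no usable observations")
  if (is.null(posterior)) posterior <- bayesianPosterior(subject, model)
  use <- which(posterior > 1e-12)
  if (aggregate == "map_point") use <- which.max(posterior)
  pred <- matrix(nrow = ctx$n, ncol = length(use))
  for (k in seq_along(use)) {
    p <- model$support[use[k], ]
    class(p) <- "pk_params"
    A <- buildRateMatrix(p, model$structure)
    pred[, k] <- context_predict(ctx, A, p)
  }
  w <- posterior[use]
  agg_pred <- switch(aggregate,
    weighted_median = apply(pred, 1, weightedQuantile, w = w, p = 0.5),
    weighted_mean = as.vector(pred %*% (w / sum(w))),
    map_point = pred[, 1])
  data.frame(id = ctx$id, time = ctx$times[ctx$row],
             output = ctx$output, observed = ctx$value,
             predicted = agg_pred, sd = ctx$sd0 * model$gamma)
}

#' Population-level predictive diagnostics per output channel
#'
#' Pools observed versus posterior-predicted concentrations across all
#' subjects and computes bias, imprecision and R-squared separately for the
#' plasma and CSF channels via [predictiveDiagnostics()].
#'
#' @param model A fitted [fitPopulation()] model.
#' @param dataset The list of [subjectRecord()]s that was fitted.
#' @param weighting Passed to [predictiveDiagnostics()].
#' @return Named list (one entry per channel) of diagnostics lists.
#' @export
populationDiagnostics <- function(model, dataset,
                                  weighting = c("inverse_variance", "unit")) {
  weighting <- match.arg(weighting)
  pooled <- do.call(rbind, lapply(dataset, function(s) {
    tryCatch(posteriorPredictions(s, model), error = function(e) NULL)
  }))
  out <- list()
  for (ch in names(model$structure$outputs)) {
    rows <- pooled[pooled$output == ch, , drop = FALSE]
    if (nrow(rows) < 2) {
      stop("fewer than 2 observations in channel '", ch, "'")
    }
    out[[ch]] <- predictiveDiagnostics(rows$observed, rows$predicted,
                                       rows$sd, weighting)
  }
  out
}
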