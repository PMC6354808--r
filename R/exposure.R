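#' Trapezoidal area under the curve over a time window
#'
#' @param times Sorted time grid (h) covering the window.
#' @param conc Concentrations (ug/ml) at `times`.
#' @param window Two-element window in hours, default `c(0, 24)`.
#' @return AUC in mg.h/liter.
#' @export
aucTrapezoid <- function(times, conc, window = c(0, 24)) {
  stopifnot(length(times) == length(conc), length(window) == 2,
            window[1] < window[2])
  if (window[1] < min(times) - 1e-9 || window[2] > max(times) + 1e-9) {
    stop("window [", window[1], ", ", window[2], "] outside the profile grid")
  }
  inside <- times > window[1] & times < window[2]
  t_sub <- c(window[1], times[inside], window[2])
  c_sub <- c(stats::approx(times, conc, xout = window[1])$y, conc[inside],
             stats::approx(times, conc, xout = window[2])$y)
  pracma::trapz(t_sub, c_sub)
}

#' Maximum concentration and its time within a window
#'
#' Cmax is the largest grid value inside the window; Tmax the earliest time
#' attaining it (ties resolved to the earlier time).
#'
#' @inheritParams aucTrapezoid
#' @return List with `cmax` (ug/ml) and `tmax` (h).
#' @export
cmaxTmax <- function(times, conc, window = c(0, 24)) {
  inside <- times >= window[1] - 1e-9 & times <= window[2] + 1e-9
  if (!any(inside)) stop("no grid points inside the window")
  t_sub <- times[inside]; c_sub <- conc[inside]
  k <- which.max(c_sub)
  list(cmax = c_sub[k], tmax = t_sub[k])
}

#' Terminal half-life from the log-linear tail of a predicted profile
#'
#' The elimination rate `k` is minus the least-squares slope of log
#' concentration on time over the last three grid points of the window
#' (default the first 8 h of the profile); the half-life is `ln(2)/k`.
#'
#' @inheritParams aucTrapezoid
#' @param window Window restricted to before the slope is taken, default
#'   `c(0, 8)` hours.
#' @return Half-life in hours.
#' @export
terminalHalfLife <- function(times, conc, window = c(0, 8)) {
  inside <- times >= window[1] - 1e-9 & times <= window[2] + 1e-9
  t_sub <- times[inside]; c_sub <- conc[inside]
  n <- length(t_sub)
  if (n < 3) stop("need at least 3 points in the window")
  t3 <- t_sub[(n - 2):n]; c3 <- c_sub[(n - 2):n]
  if (any(c3 <= 0)) stop("nonpositive concentration among the last 3 points")
  k <- -unname(stats::coef(stats::lm(log(c3) ~ t3))[2])
  if (!is.finite(k) || k <= 0) {
    stop("nonpositive elimination slope: half-life undefined")
  }
  log(2) / k
}

#' Round half away from zero (printed-table convention)
#' @param x Numeric. @param digits Decimal places.
#' @return Rounded values; exact halves round up in magnitude.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' CSF/plasma penetration percentages
#'
#' 100 times the CSF/plasma ratio of an exposure measure, rounded half-up to
#' an integer percent as printed per animal; the unrounded value is also
#' returned.
#'
#' @param csf,plasma Exposure values (AUC or Cmax); `plasma` must be > 0.
#' @return List with `pct` (integer percent) and `raw` (unrounded percent).
#' @export
penetrationPct <- function(csf, plasma) {
  if (any(plasma <= 0)) stop("zero or negative plasma exposure")
  raw <- 100 * csf / plasma
  list(pct = roundHalfUp(raw), raw = raw)
}

#' Exposure metrics of one subject from its posterior profile
#'
#' Computes, per output channel, AUC over 0-24 h, Cmax and Tmax on the
#' profile grid, the terminal half-life from the first 8 h, and the CSF/plasma
#' penetration percentages by AUC and Cmax.
#'
#' @param profile A [posteriorProfile()] (or any data frame with columns
#'   `time`, `plasma`, `csf` on a grid covering 0-24 h).
#' @param window Exposure window, default `c(0, 24)` h.
#' @param halflife_window Window for [terminalHalfLife()], default `c(0, 8)`.
#' @return Object of class `exposure_summary`: nested list with per-channel
#'   `auc`, `cmax`, `tmax`, `t_half` and the two penetration percentages.
#' @export
exposureSummary <- function(profile, window = c(0, 24),
                            halflife_window = c(0, 8)) {
  chans <- setdiff(names(profile), "time")
  per <- lapply(chans, function(ch) {
    ct <- cmaxTmax(profile$time, profile[[ch]], window)
    th <- tryCatch(terminalHalfLife(profile$time, profile[[ch]],
                                    halflife_window),
                   error = function(e) NA_real_)
    list(auc = aucTrapezoid(profile$time, profile[[ch]], window),
         cmax = ct$cmax, tmax = ct$tmax, t_half = th)
  })
  names(per) <- chans
  out <- per
  if (all(c("plasma", "csf") %in% chans)) {
    out$penetration_auc <- penetrationPct(per$csf$auc, per$plasma$auc)
    out$penetration_cmax <- penetrationPct(per$csf$cmax, per$plasma$cmax)
  }
  class(out) <- "exposure_summary"
  out
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat("<exposure_summary>\n")
  for (ch in intersect(names(x), c("plasma", "csf"))) {
    cat(sprintf("  %-6s AUC0-24 %8.1f mg.h/L  Cmax %7.1f ug/ml  Tmax %4.1f h  t1/2 %4.1f h\n",
                ch, x[[ch]]$auc, x[[ch]]$cmax, x[[ch]]$tmax, x[[ch]]$t_half))
  }
  if (!is.null(x$penetration_auc)) {
    cat(sprintf("  penetration: %d%% by AUC, %d%% by Cmax\n",
                x$penetration_auc$pct, x$penetration_cmax$pct))
  }
  invisible(x)
}

#' Median, interquartile range and CV% of a cohort metric
#'
#' Quantiles use the (n+1)-based convention (`quantile type = 6`), which
#' reproduces the study's printed interquartile ranges; the type is
#' configurable. CV% is 100 * SD / mean.
#'
#' @param values Numeric vector (at least one value).
#' @param quantile_type Passed to [stats::quantile()].
#' @return List with `median`, `q25`, `q75`, `cv_pct`, `n`.
#' @export
summarizeCohort <- function(values, quantile_type = 6) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3],
       cv_pct = 100 * stats::sd(values) / mean(values), n = length(values))
}

#' Per-animal exposure table from a fitted population model
#'
#' One row per subject with the columns of the study's exposure table:
#' plasma Cmax and AUC, CSF Cmax, Tmax and AUC, plasma terminal half-life,
#' and the two penetration percentages. Subjects without any usable CSF
#' observation still get CSF exposures (their posterior falls back to the
#' population prior) but are flagged `csf_sampled = 0` so penetration
#' summaries can exclude them.
#'
#' @param dataset List of [subjectRecord()]s.
#' @param model A fitted [fitPopulation()] model.
#' @param grid_step,horizon Passed to [posteriorProfile()].
#' @return Data frame with columns `animal`, `cmax_plasma`, `auc_plasma`,
#'   `cmax_csf`, `tmax_csf`, `auc_csf`, `t_half`, `pen_cmax_pct`,
#'   `pen_auc_pct`, `csf_sampled`.
#' @export
exposureTable <- function(dataset, model, grid_step = 0.2, horizon = 24) {
  rows <- lapply(dataset, function(s) {
    prof <- posteriorProfile(s, model, grid_step, horizon)
    ex <- exposureSummary(prof, window = c(0, horizon))
    obs <- s$observations
    has_csf <- any(obs$output == "csf" & obs$excluded == 0)
    data.frame(animal = s$id,
               cmax_plasma = ex$plasma$cmax, auc_plasma = ex$plasma$auc,
               cmax_csf = ex$csf$cmax, tmax_csf = ex$csf$tmax,
               auc_csf = ex$csf$auc, t_half = ex$plasma$t_half,
               pen_cmax_pct = ex$penetration_cmax$pct,
               pen_auc_pct = ex$penetration_auc$pct,
               csf_sampled = as.integer(has_csf))
  })
  do.call(rbind, rows)
}

#' Summary rows of an exposure table
#'
#' Computes the median and IQR of every exposure column twice: over all
#' animals and over the animals with sampled CSF only (the rule used for the
#' penetration estimates). Penetration medians are computed on the rounded
#' per-animal integers by default, matching the printed table; set
#' `rounded_penetration = FALSE` to summarize the raw ratios.
#'
#' @param tab An [exposureTable()]-shaped data frame (must include
#'   `csf_sampled`).
#' @param quantile_type Passed to [summarizeCohort()].
#' @param rounded_penetration Summarize integer percentages (default).
#' @return Data frame with columns `metric`, `group`, `median`, `q25`,
#'   `q75`, `cv_pct`, `n`.
#' @export
summarizeExposureTable <- function(tab, quantile_type = 6,
                                   rounded_penetration = TRUE) {
  metrics <- c("cmax_plasma", "auc_plasma", "cmax_csf", "tmax_csf",
               "auc_csf", "t_half", "pen_cmax_pct", "pen_auc_pct")
  metrics <- intersect(metrics, names(tab))
  groups <- list(all = rep(TRUE, nrow(tab)),
                 csf_sampled = tab$csf_sampled == 1)
  out <- list()
  for (g in names(groups)) {
    sel <- tab[groups[[g]], , drop = FALSE]
    if (nrow(sel) == 0) stop("no animals left after filtering: ", g)
    for (m in metrics) {
      v <- sel[[m]]
      if (!rounded_penetration && m %in% c("pen_cmax_pct", "pen_auc_pct")) {
        base <- sub("pen_", "", sub("_pct", "", m))
        num <- sel[[paste0(base, "_csf")]]
        den <- sel[[paste0(base, "_plasma")]]
        v <- 100 * num / den
      }
      s <- summarizeCohort(v, quantile_type)
      out[[length(out) + 1]] <- data.frame(metric = m, group = g,
                                           median = s$median, q25 = s$q25,
                                           q75 = s$q75, cv_pct = s$cv_pct,
                                           n = s$n)
    }
  }
  do.call(rbind, out)
}
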