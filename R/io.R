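dataset_columns <- c("subject_id", "weight_g", "event_type", "time_h",
                     "amount_mg", "infusion_h", "output", "conc_ug_ml",
                     "excluded")

#' Read a long-format concentration-time dataset
#'
#' One row per event. Required columns: `subject_id`, `weight_g`,
#' `event_type` (`dose` or `obs`), `time_h`, `amount_mg`, `infusion_h`,
#' `output` (`plasma`/`csf`), `conc_ug_ml`, `excluded` (0/1). Unknown
#' columns on observation rows (e.g. `bloq`) are carried through. Malformed
#' rows are reported with their line numbers.
#'
#' @param path CSV file path (header required, UTF-8, '.' decimal).
#' @return List of [subjectRecord()]s.
#' @export
readDataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(dataset_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- !df$event_type %in% c("dose", "obs")
  if (any(bad)) {
    stop("unknown event_type on line(s) ",
         paste(line[bad], collapse = ", "))
  }
  is_obs <- df$event_type == "obs"
  conc <- suppressWarnings(as.numeric(df$conc_ug_ml))
  bad <- is_obs & is.na(conc)
  if (any(bad)) {
    stop("non-numeric concentration on line(s) ",
         paste(line[bad], collapse = ", "))
  }
  amt <- suppressWarnings(as.numeric(df$amount_mg))
  bad <- !is_obs & (is.na(amt) | amt <= 0)
  if (any(bad)) {
    stop("dose row with missing or zero amount on line(s) ",
         paste(line[bad], collapse = ", "))
  }
  extra <- setdiff(names(df), dataset_columns)
  lapply(split(seq_len(nrow(df)), factor(df$subject_id,
                                         levels = unique(df$subject_id))),
         function(rows) {
    sub <- df[rows, , drop = FALSE]
    dose_rows <- sub[sub$event_type == "dose", , drop = FALSE]
    obs_rows <- sub[sub$event_type == "obs", , drop = FALSE]
    doses <- data.frame(start = dose_rows$time_h,
                        amount = as.numeric(dose_rows$amount_mg),
                        duration = as.numeric(dose_rows$infusion_h))
    obs <- data.frame(time = obs_rows$time_h,
                      value = as.numeric(obs_rows$conc_ug_ml),
                      output = obs_rows$output,
                      excluded = as.integer(obs_rows$excluded))
    for (col in extra) obs[[col]] <- obs_rows[[col]]
    subjectRecord(sub$subject_id[1], sub$weight_g[1], doses, obs)
  })
}

#' Write a dataset in the long CSV format read by [readDataset()]
#'
#' @param dataset List of [subjectRecord()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(dataset, path) {
  rows <- lapply(dataset, function(s) {
    dose <- data.frame(subject_id = s$id, weight_g = s$weight,
                       event_type = "dose", time_h = s$doses$start,
                       amount_mg = s$doses$amount,
                       infusion_h = s$doses$duration, output = "",
                       conc_ug_ml = NA_real_, excluded = NA_integer_)
    obs <- s$observations
    ob <- data.frame(subject_id = s$id, weight_g = s$weight,
                     event_type = "obs", time_h = obs$time,
                     amount_mg = NA_real_, infusion_h = NA_real_,
                     output = obs$output, conc_ug_ml = obs$value,
                     excluded = obs$excluded)
    extra <- setdiff(names(obs), c("time", "value", "output", "excluded"))
    for (col in extra) {
      dose[[col]] <- NA
      ob[[col]] <- obs[[col]]
    }
    rbind(dose, ob)
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA
    r[, all_cols, drop = FALSE]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Packaged per-animal exposure fixture
#'
#' The transcribed per-animal exposure table of the study: plasma and CSF
#' Cmax and AUC over 0-24 h, CSF Tmax, terminal half-life, the printed
#' penetration integers, and whether CSF was actually sampled in the animal
#' (four animals had intracisternal catheter failures; their CSF exposures
#' were model-estimated).
#'
#' @return Data frame of 11 animals.
#' @export
loadExposureFixture <- function() {
  utils::read.csv(system.file("extdata", "table3.csv", package = "csfpk"),
                  stringsAsFactors = FALSE)
}

#' Packaged summary-row fixture
#'
#' The printed median and IQR of every exposure column, for all animals and
#' for the subset with sampled CSF.
#'
#' @return Data frame with columns `metric`, `group`, `median`, `q25`, `q75`.
#' @export
loadSummaryFixture <- function() {
  utils::read.csv(system.file("extdata", "table3_summary.csv",
                              package = "csfpk"),
                  stringsAsFactors = FALSE)
}

#' Recompute every derived cell of the exposure table
#'
#' From the per-animal AUC and Cmax inputs of the packaged fixture this
#' recomputes both penetration integer columns and both summary rows
#' (median and IQR of every column, over all animals and over the
#' CSF-sampled subset) and compares each cell with the transcribed printed
#' value.
#'
#' @param fixture Per-animal table, default [loadExposureFixture()].
#' @param summary_fixture Printed summary rows, default
#'   [loadSummaryFixture()].
#' @return Data frame with columns `cell`, `computed`, `printed`, `pass`;
#'   attribute `all_pass`.
#' @export
reproduceExposureSummaries <- function(fixture = loadExposureFixture(),
                                       summary_fixture = loadSummaryFixture()) {
  if (nrow(fixture) == 0) stop("empty fixture")
  report <- list()
  add <- function(cell, computed, printed) {
    report[[length(report) + 1]] <<- data.frame(
      cell = cell, computed = computed, printed = printed,
      pass = isTRUE(all.equal(computed, printed, tolerance = 1e-9)))
  }
  # per-animal penetration integers from the AUC/Cmax inputs
  recomputed <- fixture
  recomputed$pen_auc_pct <- penetrationPct(fixture$auc_csf,
                                           fixture$auc_plasma)$pct
  recomputed$pen_cmax_pct <- penetrationPct(fixture$cmax_csf,
                                            fixture$cmax_plasma)$pct
  for (i in seq_len(nrow(fixture))) {
    add(paste0("animal", fixture$animal[i], "_pen_auc"),
        recomputed$pen_auc_pct[i], fixture$pen_auc_pct[i])
    add(paste0("animal", fixture$animal[i], "_pen_cmax"),
        recomputed$pen_cmax_pct[i], fixture$pen_cmax_pct[i])
  }
  # summary rows recomputed from the per-animal inputs
  smry <- summarizeExposureTable(recomputed)
  for (r in seq_len(nrow(summary_fixture))) {
    m <- summary_fixture$metric[r]; g <- summary_fixture$group[r]
    row <- smry[smry$metric == m & smry$group == g, ]
    for (stat in c("median", "q25", "q75")) {
      add(paste(g, m, stat, sep = "_"),
          roundHalfUp(row[[stat]], 1), summary_fixture[[stat]][r])
    }
  }
  out <- do.call(rbind, report)
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Transit-rate arithmetic from a parameter vector
#'
#' The combined plasma-to-CSF transit rate is `K13 + K34`; the time to
#' approach steady state is three half-times of that rate,
#' `3 * ln(2) / (K13 + K34)`; and the central elimination half-life is
#' `ln(2) / kel`. All three are rounded to 2 decimals for reporting.
#'
#' @param params A [pk_params()] vector with positive `kel`, `K13`, `K34`.
#' @return List with `combined_transit_rate` (1/h), `time_to_steady_state`
#'   (h), `kel_half_life` (h).
#' @export
transitArithmetic <- function(params = cefepimeMedianParams()) {
  p <- unclass(params)
  stopifnot(p[["kel"]] > 0, p[["K13"]] > 0, p[["K34"]] > 0)
  combined <- p[["K13"]] + p[["K34"]]
  list(combined_transit_rate = roundHalfUp(combined, 2),
       time_to_steady_state = roundHalfUp(3 * log(2) / combined, 2),
       kel_half_life = roundHalfUp(log(2) / p[["kel"]], 2))
}

#' Write a population fit report as JSON
#'
#' @param model A [fitPopulation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFitJSON <- function(model, path) {
  rep <- list(structure = model$structure$name,
              cycles = max(model$cycle_log$cycle),
              converged = model$converged,
              neg2ll = model$neg2ll, aic = model$aic, gamma = model$gamma,
              neg2ll_trajectory = model$cycle_log$neg2ll,
              support_points = cbind(as.data.frame(model$support),
                                     probability = model$weights),
              weighted_medians = as.list(populationMedians(model)),
              seed = model$seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Checksum of the packaged fixtures (guards against transcription drift)
#' @return Named character vector of MD5 sums.
#' @export
fixtureChecksums <- function() {
  files <- c(table3 = system.file("extdata", "table3.csv",
                                  package = "csfpk"),
             table3_summary = system.file("extdata", "table3_summary.csv",
                                          package = "csfpk"))
  sums <- tools::md5sum(files)
  names(sums) <- names(files)
  sums
}
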