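# Daily CFS scoring.  The Clinical Feature Scale assigns each of six
# categories (heart rate, systolic blood pressure, respiratory rate,
# temperature, sweating, posturing) a severity of 0-3 per day; the daily
# total ranges 0-18.  Vital categories are scored from the highest value
# observed in each 24-hour window after admission; sweating and posturing
# from daily note flags.  Day 0 (the initial resuscitation and
# stabilization period) is excluded from trajectories, which cover days
# 1-13.

parse_timestamps <- function(ts, what = "timestamp") {
  if (inherits(ts, "POSIXct")) return(ts)
  out <- as.POSIXct(ts, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  bad <- which(is.na(out) & !is.na(ts))
  if (length(bad)) {
    stop("unparseable ", what, " in record(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": '", ts[bad[1L]], "'")
  }
  out
}

#' Aggregate vital-sign samples into daily per-parameter maxima
#'
#' Buckets each sample into a 24-hour window anchored at the patient's
#' admission time (day `d` is the half-open interval
#' `[admission + d*24h, admission + (d+1)*24h)`) and keeps the highest
#' value per patient, day and parameter.  Samples before admission are
#' dropped with a warning giving their count; samples on or after day
#' `n_days` are silently ignored.  A parameter absent in a window is
#' absent from the result, never zero.
#'
#' @param vitals data.frame with columns `patient_id`, `timestamp`
#'   (POSIXct or ISO-8601 text), `parameter` (one of
#'   [CFS_VITAL_CATEGORIES]) and `value` (positive, in the parameter's
#'   units).
#' @param admissions data.frame with columns `patient_id` and
#'   `admission_time`, one row per patient.
#' @param n_days number of 24-hour windows starting at day 0.
#' @return data.frame with columns `patient_id`, `day_index`,
#'   `parameter`, `value` (the daily maximum).
#' @export
window_vitals <- function(vitals, admissions, n_days = 14L) {
  stopifnot(n_days >= 1L)
  need <- c("patient_id", "timestamp", "parameter", "value")
  if (!all(need %in% names(vitals))) {
    stop("vitals must have columns: ", paste(need, collapse = ", "))
  }
  empty <- data.frame(patient_id = character(), day_index = integer(),
                      parameter = character(), value = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(vitals) == 0L) return(empty)
  if (!all(vitals$parameter %in% CFS_VITAL_CATEGORIES)) {
    stop("unknown vital parameter(s): ",
         paste(setdiff(unique(vitals$parameter), CFS_VITAL_CATEGORIES),
               collapse = ", "))
  }
  ts <- parse_timestamps(vitals$timestamp)
  adm <- parse_timestamps(admissions$admission_time, "admission_time")
  idx <- match(vitals$patient_id, admissions$patient_id)
  if (anyNA(idx)) {
    stop("no admission time for patient(s): ",
         paste(unique(vitals$patient_id[is.na(idx)]), collapse = ", "))
  }
  secs <- as.numeric(ts) - as.numeric(adm[idx])
  pre <- secs < 0
  if (any(pre)) {
    warning(sum(pre), " sample(s) earlier than admission dropped")
  }
  day <- secs %/% 86400
  keep <- !pre & day < n_days
  if (!any(keep)) return(empty)
  df <- data.frame(patient_id = as.character(vitals$patient_id[keep]),
                   day_index = as.integer(day[keep]),
                   parameter = vitals$parameter[keep],
                   value = vitals$value[keep],
                   stringsAsFactors = FALSE)
  out <- stats::aggregate(value ~ patient_id + day_index + parameter,
                          data = df, FUN = max)
  out <- out[order(out$patient_id, out$day_index, out$parameter), ]
  rownames(out) <- NULL
  out
}

#' Score one patient-day
#'
#' Combines a day's per-parameter maxima with the day's note flags into
#' a six-category CFS record.  A vital category with no data that day is
#' scored per `missing_policy` (default: 0) and listed in
#' `missing_categories`; missingness is a flagged state, not an error.
#'
#' @param day_maxima named numeric vector of daily maxima, names among
#'   [CFS_VITAL_CATEGORIES]; omit (or set `NA`) categories with no data.
#' @param flags list with logical elements `sweating` and `posturing`.
#' @param rubrics named list of rubrics as from [default_rubrics()].
#' @param missing_policy how to score a vital category with no data;
#'   only `"zero"` (score 0, flag in `missing_categories`) is defined.
#' @return list of class `daily_cfs` with elements `sub_scores` (named
#'   integer, six categories), `total` (0-18) and `missing_categories`.
#' @examples
#' daily_cfs(c(HR = 125, SBP = 120, RR = 14, TEMP = 36.5),
#'           flags = list(sweating = TRUE, posturing = FALSE),
#'           rubrics = default_rubrics())
#' @export
daily_cfs <- function(day_maxima = numeric(),
                      flags = list(sweating = FALSE, posturing = FALSE),
                      rubrics = default_rubrics(),
                      missing_policy = c("zero")) {
  check_rubrics(rubrics)
  missing_policy <- match.arg(missing_policy)
  sub <- stats::setNames(integer(6L), CFS_CATEGORIES)
  missing <- character()
  for (cat in CFS_VITAL_CATEGORIES) {
    v <- if (cat %in% names(day_maxima)) day_maxima[[cat]] else NA_real_
    if (is.na(v)) {
      sub[[cat]] <- 0L
      missing <- c(missing, cat)
    } else {
      sub[[cat]] <- score_vital_category(v, rubrics[[cat]])
    }
  }
  sub[["SWEATING"]] <- score_symptom_category(isTRUE(flags$sweating))
  sub[["POSTURING"]] <- score_symptom_category(isTRUE(flags$posturing))
  structure(list(sub_scores = sub,
                 total = sum(sub),
                 missing_categories = missing),
            class = "daily_cfs")
}

#' Score a whole cohort day by day
#'
#' Runs [window_vitals()] and [daily_cfs()] over every patient and day,
#' producing one row per patient-day including wholly undocumented days
#' (flagged by `scored = FALSE`).  A day counts as scored if at least
#' one vital parameter was documented or a note-flag record exists.
#'
#' @inheritParams window_vitals
#' @param flags data.frame with columns `patient_id`, `day_index`,
#'   `sweating`, `posturing` (logical or 0/1), at most one row per
#'   patient-day.
#' @param rubrics named list of rubrics.
#' @return data.frame with columns `patient_id`, `day_index`, `hr`,
#'   `sbp`, `rr`, `temp`, `sweating`, `posturing`, `total`, `missing`
#'   (semicolon-separated missing vital categories) and `scored`.
#' @export
score_cohort <- function(vitals, flags, admissions,
                         rubrics = default_rubrics(), n_days = 14L) {
  check_rubrics(rubrics)
  if (anyDuplicated(flags[c("patient_id", "day_index")])) {
    stop("flags must have at most one record per patient-day")
  }
  wm <- window_vitals(vitals, admissions, n_days)
  patients <- as.character(admissions$patient_id)
  grid <- expand.grid(patient_id = patients,
                      day_index = seq_len(n_days) - 1L,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(p, d) paste(p, d, sep = "\r")
  # wide daily maxima
  vals <- matrix(NA_real_, nrow(grid), 4L,
                 dimnames = list(NULL, CFS_VITAL_CATEGORIES))
  if (nrow(wm)) {
    gk <- key(grid$patient_id, grid$day_index)
    ri <- match(key(wm$patient_id, wm$day_index), gk)
    ci <- match(wm$parameter, CFS_VITAL_CATEGORIES)
    vals[cbind(ri, ci)] <- wm$value
  }
  # flags
  has_flag <- rep(FALSE, nrow(grid))
  sw <- po <- rep(FALSE, nrow(grid))
  if (nrow(flags)) {
    fi <- match(key(flags$patient_id, flags$day_index),
                key(grid$patient_id, grid$day_index))
    ok <- !is.na(fi)
    has_flag[fi[ok]] <- TRUE
    sw[fi[ok]] <- as.logical(flags$sweating[ok])
    po[fi[ok]] <- as.logical(flags$posturing[ok])
  }
  score_col <- function(cat) {
    s <- integer(nrow(grid))
    ok <- !is.na(vals[, cat])
    if (any(ok)) s[ok] <- score_vital_category(vals[ok, cat], rubrics[[cat]])
    s
  }
  sc <- vapply(CFS_VITAL_CATEGORIES, score_col, integer(nrow(grid)))
  sw_s <- score_symptom_category(sw)
  po_s <- score_symptom_category(po)
  missing <- apply(vals, 1L, function(v) {
    paste(CFS_VITAL_CATEGORIES[is.na(v)], collapse = ";")
  })
  out <- data.frame(patient_id = grid$patient_id,
                    day_index = grid$day_index,
                    hr = sc[, "HR"], sbp = sc[, "SBP"],
                    rr = sc[, "RR"], temp = sc[, "TEMP"],
                    sweating = sw_s, posturing = po_s,
                    total = rowSums(sc) + sw_s + po_s,
                    missing = missing,
                    scored = rowSums(!is.na(vals)) > 0 | has_flag,
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$day_index), ]
  rownames(out) <- NULL
  out
}

#' Build one patient's 13-day CFS trajectory
#'
#' Drops day 0 and returns the CFS totals for days 1-13.  A wholly
#' unscored interior day is filled by linear interpolation between the
#' nearest scored neighbours; unscored boundary days carry the nearest
#' scored value.  Patients with fewer than two scored days among days
#' 1-13 are excluded (`NULL` is returned with a message).
#'
#' @param daily data.frame for one patient with columns `day_index`,
#'   `total` and `scored` (as produced by [score_cohort()]).
#' @return list with `values` (length 13, days 1-13) and `imputed_days`
#'   (integer day indices filled by the missing-day policy), or `NULL`
#'   if the patient is excluded.
#' @export
build_trajectory <- function(daily) {
  days <- 1:13
  d <- daily[daily$day_index %in% days & daily$scored, , drop = FALSE]
  if (nrow(d) < 2L) {
    message("patient excluded: fewer than 2 scored days among days 1-13")
    return(NULL)
  }
  v <- stats::approx(x = d$day_index, y = d$total, xout = days,
                     method = "linear", rule = 2)$y
  list(values = v, imputed_days = setdiff(days, d$day_index))
}

#' Assemble the cohort trajectory matrix
#'
#' Applies [build_trajectory()] per patient and stacks the included
#' trajectories into an N x 13 matrix ready for clustering.
#'
#' @param daily_table cohort daily table from [score_cohort()].
#' @return list with `matrix` (rownames = patient ids, columns
#'   `day1`..`day13`), `imputed` (named list of imputed day indices) and
#'   `excluded` (character vector of excluded patient ids).
#' @export
trajectory_matrix <- function(daily_table) {
  patients <- unique(daily_table$patient_id)
  rows <- list()
  imputed <- list()
  excluded <- character()
  for (p in patients) {
    tr <- suppressMessages(
      build_trajectory(daily_table[daily_table$patient_id == p, ])
    )
    if (is.null(tr)) {
      excluded <- c(excluded, p)
    } else {
      rows[[p]] <- tr$values
      if (length(tr$imputed_days)) imputed[[p]] <- tr$imputed_days
    }
  }
  if (length(excluded)) {
    message(length(excluded), " patient(s) excluded: ",
            paste(excluded, collapse = ", "))
  }
  m <- do.call(rbind, rows)
  if (!is.null(m)) colnames(m) <- paste0("day", 1:13)
  list(matrix = m, imputed = imputed, excluded = excluded)
}

#' Tally the Diagnosis Likelihood Tool indicators
#'
#' The DLT is a checklist of 11 binary diagnostic-likelihood indicators
#' (simultaneity and persistence of features, episode frequency,
#' medication requirement, exclusion of alternative causes, and so on);
#' its score is the number of indicators met.
#'
#' @param indicators logical vector of exactly 11 values.
#' @return integer in 0..11.
#' @export
dlt_tally <- function(indicators) {
  if (length(indicators) != 11L) {
    stop("the DLT has exactly 11 indicators, got ", length(indicators))
  }
  if (!is.logical(indicators) || anyNA(indicators)) {
    stop("DLT indicators must be TRUE/FALSE with no missing values")
  }
  sum(indicators)
}
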