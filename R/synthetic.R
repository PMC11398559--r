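#' Default trajectory archetypes
#'
#' The four latent CFS-trajectory shapes the generator emulates:
#' persistently low (flat near 2), decreasing (about 8 down to 3),
#' increasing (about 3 up to 9) and persistently high (flat near 10).
#' The exact curve values are free constants of the generator, chosen so
#' the mean curves are mutually well separated (pairwise DTW distance
#' greater than five times the default daily noise SD of 1.5).
#'
#' @param sd_noise daily noise standard deviation attached to each
#'   archetype (CFS points).
#' @return list of four archetypes, each a list with `name`,
#'   `mean_curve` (13 values, days 1-13) and `sd_noise`.
#' @export
make_default_archetypes <- function(sd_noise = 1.5) {
  curves <- list(
    persistently_low  = rep(2, 13),
    decreasing        = seq(8, 3, length.out = 13),
    increasing        = seq(3, 9, length.out = 13),
    persistently_high = rep(10, 13)
  )
  lapply(names(curves), function(nm) {
    list(name = nm, mean_curve = curves[[nm]], sd_noise = sd_noise)
  })
}

#' Synthetic-cohort configuration
#'
#' Collects every tunable of the generator with defaults mirroring the
#' group-level structure of an acute TBI cohort scored daily for
#' sympathetic hyperactivity: group prevalences 14/33/29/24%, group mean
#' ages 52/48/40/38 years (SD 18, truncated to 18-95), motor-GCS centers
#' 4/5/3/2 on the 1-6 scale, BMI Normal(26, 6) truncated above 12,
#' per-group PSH-diagnosis probabilities 0.26/0.38/0.57/0.65, DLT
#' Binomial(11, q) with q rising 0.18/0.36/0.60/0.68, and log-normal ICU
#' length-of-stay / ventilation-day distributions whose means rise with
#' group severity.  Discharge GCS components and mortality are drawn
#' independent of group.  All defaults are overridable.
#'
#' @param n_patients cohort size.
#' @param seed integer seed for [generate_cohort()].
#' @param ... overrides for any listed element.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 221L, seed = 42L, ...) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    group_proportions = c(0.14, 0.33, 0.29, 0.24),
    archetypes = make_default_archetypes(),
    sd_noise = 1.5,
    age_means = c(52, 48, 40, 38), age_sd = 18, age_range = c(18, 95),
    mgcs_centers = c(4, 5, 3, 2), mgcs_sd = 1.5,
    bmi_mean = 26, bmi_sd = 6, bmi_min = 12,
    male_prob = 0.79,
    psh_probs = c(0.26, 0.38, 0.57, 0.65),
    dlt_probs = c(0.18, 0.36, 0.60, 0.68),
    icu_los_means = c(17.8, 17.5, 21.1, 21.5),
    icu_los_sds = c(10.5, 8.9, 11.1, 11.1),
    vent_means = c(12.7, 11.3, 15.0, 15.3),
    vent_sds = c(9.9, 8.0, 9.9, 9.4),
    hosp_los_means = c(27.6, 27.0, 29.7, 31.3),
    hosp_los_sds = c(11.1, 11.5, 16.5, 15.5),
    survival_prob = 0.94,
    following_commands_prob = 0.75,
    admission_base = as.POSIXct("2017-03-01 08:00:00", tz = "UTC")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  check_cohort_config(structure(cfg, class = "cohort_config"))
}

check_cohort_config <- function(cfg) {
  G <- length(cfg$archetypes)
  stopifnot(cfg$n_patients >= 0L,
            length(cfg$group_proportions) == G,
            abs(sum(cfg$group_proportions) - 1) < 1e-8,
            all(cfg$group_proportions >= 0),
            all(cfg$psh_probs >= 0 & cfg$psh_probs <= 1),
            all(cfg$dlt_probs >= 0 & cfg$dlt_probs <= 1),
            all(vapply(cfg$archetypes,
                       function(a) length(a$mean_curve) == 13L &&
                         all(a$mean_curve >= 0 & a$mean_curve <= 18),
                       logical(1L))))
  cfg
}

# Deterministic allocation of a daily total to the six categories.
# Under the note rule symptoms score {0, 2}, so representable totals cap
# at 16 (= 4 vitals x 3 + 2 + 2); higher targets are clipped.  Symptom
# points are committed first for totals above 12 (sweating before
# posturing, in steps of 2), the remainder fills the vitals round-robin
# in the order HR, SBP, RR, TEMP.
allocate_total <- function(total) {
  t0 <- min(max(round(total), 0L), 16L)
  sym <- if (t0 <= 12L) 0L else as.integer(2L * ceiling((t0 - 12L) / 2))
  v <- t0 - sym
  base <- v %/% 4L
  extra <- v %% 4L
  vit <- rep(base, 4L) + as.integer(seq_len(4L) <= extra)
  stats::setNames(c(vit, if (sym >= 2L) 2L else 0L, if (sym == 4L) 2L else 0L),
                  CFS_CATEGORIES)
}

#' Simulate per-patient daily CFS targets and true group labels
#'
#' Assigns each patient an archetype according to the configured group
#' proportions, then draws each day's target total as
#' `round(clip(mean_curve[d] + Normal(0, sd_noise), 0, 18))` and splits
#' it into six category sub-scores with a deterministic greedy rule so
#' the allocation is reproducible.  Day 0 (the resuscitation window,
#' later dropped by scoring) uses the day-1 archetype value.
#'
#' @param config a [cohort_config()].
#' @return list with `labels` (integer archetype per patient),
#'   `totals` (n x 14 matrix, days 0-13) and `sub_scores` (n x 14 x 6
#'   array).  Assumes the RNG state is already set.
#' @export
simulate_trajectories <- function(config) {
  n <- config$n_patients
  G <- length(config$archetypes)
  labels <- sample.int(G, n, replace = TRUE, prob = config$group_proportions)
  totals <- matrix(0L, n, 14L)
  subs <- array(0L, c(n, 14L, 6L), dimnames = list(NULL, NULL, CFS_CATEGORIES))
  for (i in seq_len(n)) {
    curve <- config$archetypes[[labels[i]]]$mean_curve
    sdn <- config$archetypes[[labels[i]]]$sd_noise
    mu <- c(curve[1L], curve)                       # day 0 mirrors day 1
    tot <- round(pmin(pmax(mu + stats::rnorm(14L, 0, sdn), 0), 18))
    totals[i, ] <- as.integer(tot)
    for (d in seq_len(14L)) subs[i, d, ] <- allocate_total(tot[d])
  }
  list(labels = labels, totals = totals, sub_scores = subs)
}

# physiologic floors and caps per vital category, used when inverting a
# target sub-score into a band of raw values
VITAL_FLOORS <- c(HR = 45, SBP = 80, RR = 8, TEMP = 35)
VITAL_CAPS <- c(HR = 220, SBP = 260, RR = 60, TEMP = 43)

#' Simulate raw vitals and note flags reproducing target sub-scores
#'
#' Inverse of the daily scoring procedure: for each vital category the
#' day's maximum is drawn inside the value band of the target sub-score
#' (uniform within the band; the top band adds an exponential tail above
#' the last cutpoint, clipped to physiologic caps) and at least two
#' further samples are drawn at or below that maximum, all with
#' timestamps inside the day's 24-hour window.  Note flags are set iff
#' the corresponding target symptom score is 2.  Scoring the emitted
#' samples reproduces the targets exactly.
#'
#' @param targets named integer vector of six target sub-scores
#'   (vitals 0-3, symptoms 0 or 2).
#' @param rubrics named rubric list.
#' @param day_start POSIXct start of the 24-hour window.
#' @param patient_id id attached to the emitted rows.
#' @param n_samples samples per vital category (minimum 3).
#' @return list with `vitals` (data.frame rows for this patient-day)
#'   and `flags` (one-row data.frame).  Assumes the RNG state is set.
#' @export
simulate_vitals_for_target_cfs <- function(targets, rubrics = default_rubrics(),
                                           day_start = as.POSIXct("2017-03-01", tz = "UTC"),
                                           patient_id = "p1", n_samples = 3L) {
  check_rubrics(rubrics)
  n_samples <- max(3L, as.integer(n_samples))
  rows <- list()
  for (cat in CFS_VITAL_CATEGORIES) {
    s <- as.integer(targets[[cat]])
    if (is.na(s) || s < 0L || s > 3L) stop("invalid target sub-score for ", cat)
    cuts <- rubrics[[cat]]$cutpoints
    lo <- c(VITAL_FLOORS[[cat]], cuts)[s + 1L]
    hi <- c(cuts, VITAL_CAPS[[cat]])[s + 1L]
    if (lo >= hi) stop("target ", s, " for ", cat, " unreachable under this rubric")
    mx <- if (s == 3L) {
      min(lo + stats::rexp(1L, rate = 4 / (hi - lo)), hi)
    } else {
      lo + (hi - lo) * stats::runif(1L, 1e-6, 1 - 1e-6)
    }
    others <- VITAL_FLOORS[[cat]] +
      (mx - VITAL_FLOORS[[cat]]) * stats::runif(n_samples - 1L)
    secs <- sort(stats::runif(n_samples, 0, 86400 - 1))
    vals <- c(mx, others)[sample.int(n_samples)]
    rows[[cat]] <- data.frame(patient_id = patient_id,
                              timestamp = day_start + secs,
                              parameter = cat, value = vals,
                              stringsAsFactors = FALSE)
  }
  vit <- do.call(rbind, rows)
  rownames(vit) <- NULL
  flags <- data.frame(patient_id = patient_id,
                      day_index = NA_integer_,
                      sweating = as.integer(targets[["SWEATING"]]) == 2L,
                      posturing = as.integer(targets[["POSTURING"]]) == 2L,
                      stringsAsFactors = FALSE)
  list(vitals = vit, flags = flags)
}

truncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

rlnorm_ms <- function(n, m, s) {
  sdlog <- sqrt(log(1 + s^2 / m^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

#' Simulate admission covariates conditional on true group labels
#'
#' Age is truncated-normal with group-specific means; motor GCS is a
#' discretized group-shifted normal on 1-6; BMI and sex are drawn
#' independent of group.  Covariates are generated group-first (labels
#' drawn, covariates conditioned), so regression-recovery results should
#' be read as recovering the induced covariate-group association.
#'
#' @param labels integer archetype per patient.
#' @param config a [cohort_config()].
#' @return data.frame: `patient_id`, `age`, `bmi`, `mgcs`, `sex`.
#'   Assumes the RNG state is set.
#' @export
simulate_covariates <- function(labels, config) {
  n <- length(labels)
  data.frame(
    patient_id = cohort_ids(n),
    age = truncnorm(n, config$age_means[labels], config$age_sd,
                    config$age_range[1L], config$age_range[2L]),
    bmi = truncnorm(n, config$bmi_mean, config$bmi_sd, config$bmi_min, Inf),
    mgcs = pmin(pmax(round(stats::rnorm(n, config$mgcs_centers[labels],
                                        config$mgcs_sd)), 1L), 6L),
    sex = ifelse(stats::runif(n) < config$male_prob, "male", "female"),
    stringsAsFactors = FALSE
  )
}

#' Simulate in-hospital outcomes conditional on true group labels
#'
#' PSH diagnosis is Bernoulli with group-specific probability, the DLT
#' is Binomial(11, q) with q monotone in group severity, and ICU/hospital
#' stay and ventilation days are group-shifted log-normals.  Discharge
#' GCS components, command-following and survival are drawn independent
#' of group.
#'
#' @inheritParams simulate_covariates
#' @return data.frame in the outcomes-CSV layout.  Assumes the RNG
#'   state is set.
#' @export
simulate_outcomes <- function(labels, config) {
  n <- length(labels)
  eye <- sample(c(1L, 3L, 4L), n, replace = TRUE, prob = c(0.1, 0.1, 0.8))
  motor <- sample(4:6, n, replace = TRUE, prob = c(0.1, 0.2, 0.7))
  verbal <- sample(1:5, n, replace = TRUE, prob = c(0.3, 0.1, 0.2, 0.2, 0.2))
  data.frame(
    patient_id = cohort_ids(n),
    psh_case = stats::runif(n) < config$psh_probs[labels],
    dlt = stats::rbinom(n, 11L, config$dlt_probs[labels]),
    survived = stats::runif(n) < config$survival_prob,
    gcs_eye = eye, gcs_motor = motor, gcs_verbal = verbal,
    gcs_total = eye + motor + verbal,
    following_commands = stats::runif(n) < config$following_commands_prob,
    hospital_los = rlnorm_ms(n, config$hosp_los_means[labels],
                             config$hosp_los_sds[labels]),
    icu_los = rlnorm_ms(n, config$icu_los_means[labels],
                        config$icu_los_sds[labels]),
    vent_days = rlnorm_ms(n, config$vent_means[labels],
                          config$vent_sds[labels]),
    stringsAsFactors = FALSE
  )
}

cohort_ids <- function(n) sprintf("pt%04d", seq_len(n))

#' Generate a complete synthetic cohort
#'
#' Composes trajectory targets, raw vitals, note flags, covariates,
#' outcomes and ground-truth labels into one coherent cohort,
#' deterministic under `config$seed`.  Every patient appears in every
#' component; admission times are staggered hourly from
#' `config$admission_base`.
#'
#' @param config a [cohort_config()].
#' @param rubrics rubric list used to invert targets into raw vitals.
#' @return list of class `psh_cohort` with data.frames `vitals`,
#'   `flags`, `admissions`, `covariates`, `outcomes`, `truth`
#'   (patient_id, group), plus `targets` (the generated sub-score
#'   array) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            rubrics = default_rubrics()) {
  check_cohort_config(config)
  check_rubrics(rubrics)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- cohort_ids(n)
  traj <- simulate_trajectories(config)
  admissions <- data.frame(patient_id = ids,
                           admission_time = config$admission_base +
                             3600 * (seq_len(n) - 1L),
                           stringsAsFactors = FALSE)
  vit_list <- list()
  flag_list <- list()
  for (i in seq_len(n)) {
    for (d in 0:13) {
      sim <- simulate_vitals_for_target_cfs(
        traj$sub_scores[i, d + 1L, ], rubrics,
        day_start = admissions$admission_time[i] + d * 86400,
        patient_id = ids[i]
      )
      vit_list[[length(vit_list) + 1L]] <- sim$vitals
      f <- sim$flags
      f$day_index <- d
      flag_list[[length(flag_list) + 1L]] <- f
    }
  }
  empty_vitals <- data.frame(patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                             parameter = character(), value = numeric(),
                             stringsAsFactors = FALSE)
  empty_flags <- data.frame(patient_id = character(), day_index = integer(),
                            sweating = logical(), posturing = logical(),
                            stringsAsFactors = FALSE)
  vitals <- if (length(vit_list)) do.call(rbind, vit_list) else empty_vitals
  flags <- if (length(flag_list)) do.call(rbind, flag_list) else empty_flags
  rownames(vitals) <- rownames(flags) <- NULL
  covariates <- simulate_covariates(traj$labels, config)
  outcomes <- simulate_outcomes(traj$labels, config)
  structure(list(vitals = vitals, flags = flags, admissions = admissions,
                 covariates = covariates, outcomes = outcomes,
                 truth = data.frame(patient_id = ids, group = traj$labels,
                                    stringsAsFactors = FALSE),
                 targets = traj, config = config),
            class = "psh_cohort")
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `vitals.csv`, `flags.csv`, `admissions.csv`, `covariates.csv`,
#' `covariate_types.csv`, `outcomes.csv` and `true_labels.csv` under
#' `dir` in the pipeline's input formats (ISO-8601 timestamps, 0/1
#' flags).
#'
#' @param cohort a `psh_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  vit <- cohort$vitals
  vit$timestamp <- fmt_time(vit$timestamp)
  adm <- cohort$admissions
  adm$admission_time <- fmt_time(adm$admission_time)
  fl <- cohort$flags
  fl$sweating <- as.integer(fl$sweating)
  fl$posturing <- as.integer(fl$posturing)
  types <- data.frame(
    feature = c("age", "bmi", "mgcs", "sex"),
    type = c("continuous", "continuous", "continuous", "categorical"),
    stringsAsFactors = FALSE
  )
  files <- c(vitals = "vitals.csv", flags = "flags.csv",
             admissions = "admissions.csv", covariates = "covariates.csv",
             covariate_types = "covariate_types.csv",
             outcomes = "outcomes.csv", truth = "true_labels.csv")
  objs <- list(vit, fl[, c("patient_id", "day_index", "sweating", "posturing")],
               adm, cohort$covariates, types, cohort$outcomes, cohort$truth)
  paths <- file.path(dir, files)
  for (i in seq_along(objs)) {
    utils::write.csv(objs[[i]], paths[i], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read a vitals CSV in the pipeline input format
#'
#' Header `patient_id,timestamp,parameter,value`; ISO-8601 timestamps.
#' Values must be positive and parameters among [CFS_VITAL_CATEGORIES].
#'
#' @param path file path.
#' @return validated data.frame with parsed POSIXct timestamps.
#' @export
read_vitals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  need <- c("patient_id", "timestamp", "parameter", "value")
  if (!all(need %in% names(df))) {
    stop("vitals file must have columns: ", paste(need, collapse = ", "))
  }
  df$timestamp <- parse_timestamps(df$timestamp)
  if (any(!is.finite(df$value) | df$value <= 0)) {
    stop("vital-sign values must be positive")
  }
  df
}

#' Read a note-flags CSV (`patient_id,day_index,sweating,posturing`)
#' @param path file path.
#' @return data.frame with logical flag columns.
#' @export
read_flags_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  need <- c("patient_id", "day_index", "sweating", "posturing")
  if (!all(need %in% names(df))) {
    stop("flags file must have columns: ", paste(need, collapse = ", "))
  }
  df$sweating <- as.logical(df$sweating)
  df$posturing <- as.logical(df$posturing)
  df
}
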