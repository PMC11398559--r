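#' CFS vital-sign categories
#'
#' The four physiologic categories of the Clinical Feature Scale that are
#' scored from vital signs; sweating and posturing are scored from
#' clinical-note flags instead.
#' @export
CFS_VITAL_CATEGORIES <- c("HR", "SBP", "RR", "TEMP")

#' All six CFS categories
#' @export
CFS_CATEGORIES <- c(CFS_VITAL_CATEGORIES, "SWEATING", "POSTURING")

#' Construct a scoring rubric for one vital-sign category
#'
#' A rubric partitions the value axis of one vital sign into four bands
#' scoring 0-3.  Bands are left-closed on each cutpoint: a value equal to
#' a cutpoint falls into the higher band.
#'
#' @param category one of `"HR"`, `"SBP"`, `"RR"`, `"TEMP"`.
#' @param cutpoints numeric vector of exactly three strictly increasing
#'   thresholds, in the category's units (beats/min, mmHg, breaths/min,
#'   degrees Celsius).
#' @return an object of class `cfs_rubric`.
#' @examples
#' make_rubric("HR", c(100, 120, 140))
#' @export
make_rubric <- function(category, cutpoints) {
  category <- match.arg(category, CFS_VITAL_CATEGORIES)
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) != 3L) {
    stop("a rubric needs exactly 3 cutpoints, got ", length(cutpoints))
  }
  if (any(!is.finite(cutpoints)) || any(diff(cutpoints) <= 0)) {
    stop("rubric cutpoints must be finite and strictly increasing")
  }
  structure(list(category = category, cutpoints = cutpoints),
            class = "cfs_rubric")
}

#' Default CFS rubrics
#'
#' Severity thresholds for the four vital-sign categories, taken from the
#' published PSH Assessment Measure instrument: heart rate (100, 120,
#' 140) beats/min; systolic blood pressure (140, 160, 180) mmHg;
#' respiratory rate (18, 24, 30) breaths/min; temperature (37.0, 38.0,
#' 39.0) degrees Celsius.  All are overridable: any analysis function
#' taking a `rubrics` argument accepts a named list built from
#' [make_rubric()].
#'
#' @return named list of `cfs_rubric` objects, one per vital category.
#' @export
default_rubrics <- function() {
  list(
    HR   = make_rubric("HR",   c(100, 120, 140)),
    SBP  = make_rubric("SBP",  c(140, 160, 180)),
    RR   = make_rubric("RR",   c(18, 24, 30)),
    TEMP = make_rubric("TEMP", c(37.0, 38.0, 39.0))
  )
}

check_rubrics <- function(rubrics) {
  if (!all(CFS_VITAL_CATEGORIES %in% names(rubrics))) {
    stop("rubrics must be supplied for all of: ",
         paste(CFS_VITAL_CATEGORIES, collapse = ", "))
  }
  for (cat in CFS_VITAL_CATEGORIES) {
    r <- rubrics[[cat]]
    if (!inherits(r, "cfs_rubric")) stop("rubric for ", cat, " is not a cfs_rubric")
  }
  invisible(rubrics)
}

#' Score one vital-sign value against a category rubric
#'
#' Returns the 0-3 severity band of `value` under the rubric's three
#' cutpoints.  The mapping is monotone non-decreasing in `value` and
#' left-closed: `value == cutpoints[i]` scores `i`.
#'
#' @param value positive numeric vector of measurements.
#' @param rubric a `cfs_rubric` from [make_rubric()].
#' @return integer vector of scores in 0..3.
#' @examples
#' score_vital_category(125, make_rubric("HR", c(100, 120, 140)))  # 2
#' @export
score_vital_category <- function(value, rubric) {
  if (!inherits(rubric, "cfs_rubric")) stop("rubric must be a cfs_rubric")
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("vital-sign values must be positive and finite")
  }
  findInterval(value, rubric$cutpoints)
}

#' Score a note-derived symptom category
#'
#' Sweating and posturing are scored from daily clinical-note review:
#' any mention scores 2 (moderate), no mention scores 0 (absent).  The
#' note record does not carry enough granularity to use the full 0-3
#' range.
#'
#' @param mentioned logical vector; was the symptom mentioned that day?
#' @return integer vector with values in {0, 2}.
#' @export
score_symptom_category <- function(mentioned) {
  if (!is.logical(mentioned) || anyNA(mentioned)) {
    stop("`mentioned` must be TRUE/FALSE with no missing values")
  }
  ifelse(mentioned, 2L, 0L)
}

#' Read rubric cutpoints from a CSV config file
#'
#' Expects columns `category,cut1,cut2,cut3` with one row per vital
#' category.
#'
#' @param path file path.
#' @return named list of `cfs_rubric` objects.
#' @export
read_rubrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "cut1", "cut2", "cut3")
  if (!all(need %in% names(df))) {
    stop("rubric file must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    make_rubric(df$category[i], c(df$cut1[i], df$cut2[i], df$cut3[i]))
  })
  names(out) <- df$category
  check_rubrics(out)
}
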