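#' Cross-tabulate trajectory groups against a categorical outcome
#'
#' @param labels group membership per patient.
#' @param outcome categorical outcome per patient, aligned with `labels`.
#' @return integer contingency matrix (groups x outcome levels).
#' @export
crosstab <- function(labels, outcome) {
  if (length(labels) != length(outcome)) {
    stop("labels and outcome must have equal length")
  }
  if (anyNA(labels)) stop("missing group labels are not allowed")
  tab <- table(group = labels, outcome = outcome)
  unclass(tab)
}

#' Pearson chi-squared test on a contingency table
#'
#' The Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the row/column margins, `df = (r - 1)(c - 1)`, and no continuity
#' correction.  An expected count of zero is an error; expected counts
#' below 5 trigger a warning but the test is still computed.
#'
#' @param tab contingency matrix with at least 2 rows and 2 columns.
#' @return list of class `assoc_test`: `statistic`, `df`, `p_value`,
#'   `test_name`, `expected`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("chi-squared test needs at least a 2 x 2 table")
  }
  if (any(tab < 0) || sum(tab) == 0) stop("counts must be non-negative with positive total")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected count of 0; drop empty margins first")
  if (any(expected < 5)) {
    warning("expected count(s) below 5; chi-squared approximation may be poor")
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 test_name = "pearson_chi_squared", expected = expected),
            class = "assoc_test")
}

#' One-way analysis of variance across groups
#'
#' Standard fixed-effects ANOVA, `F` = between-group mean square over
#' within-group mean square with `df = (K - 1, N - K)`.  In the
#' degenerate case of zero variance everywhere and identical group
#' means, `F` is defined as 0 with `p = 1`.
#'
#' @param values numeric outcome per patient.
#' @param labels group per patient.
#' @return `assoc_test` list: `statistic` (F), `df` (length 2), `p_value`.
#' @export
one_way_anova <- function(values, labels) {
  if (length(values) != length(labels)) stop("values and labels must align")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  g <- factor(labels[keep])
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("ANOVA needs at least 2 groups with at least 2 observations each")
  }
  scale <- mean(values^2) + 1
  if (stats::var(values) < 1e-12 * scale) {
    # no variance anywhere: identical group means, F defined as 0
    return(structure(list(statistic = 0, df = c(nlevels(g) - 1L,
                                                length(values) - nlevels(g)),
                          p_value = 1, test_name = "one_way_anova"),
                     class = "assoc_test"))
  }
  a <- stats::anova(stats::lm(values ~ g))
  stat <- a[["F value"]][1L]
  p <- a[["Pr(>F)"]][1L]
  structure(list(statistic = stat, df = a[["Df"]],
                 p_value = p, test_name = "one_way_anova"),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic, digits = 5),
      ", df = ", paste(x$df, collapse = ", "),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Per-group odds of a binary outcome with Wald confidence intervals
#'
#' For each group row of a two-column table, odds = positives/negatives
#' and the interval is `exp(log(odds) +/- z * sqrt(1/pos + 1/neg))`.
#' No continuity correction is applied; a zero cell yields the point
#' estimate with an undefined (NA) interval and `ci_defined = FALSE`.
#'
#' @param tab two-column contingency matrix, positives in the column
#'   named by `positive` (default: first column).
#' @param positive column name or index of the positive outcome.
#' @param level confidence level.
#' @return data.frame with `group`, `positives`, `negatives`, `odds`,
#'   `lower`, `upper`, `ci_defined`.
#' @export
group_odds <- function(tab, positive = 1L, level = 0.95) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2L) stop("group_odds needs a binary (two-column) outcome")
  pi <- if (is.character(positive)) match(positive, colnames(tab)) else as.integer(positive)
  if (is.na(pi) || pi < 1L || pi > 2L) stop("unknown positive column")
  pos <- tab[, pi]
  neg <- tab[, 3L - pi]
  z <- stats::qnorm(1 - (1 - level) / 2)
  odds <- pos / neg
  se <- sqrt(1 / pos + 1 / neg)
  ok <- pos > 0 & neg > 0
  data.frame(group = rownames(tab) %||% as.character(seq_len(nrow(tab))),
             positives = as.integer(pos), negatives = as.integer(neg),
             odds = odds,
             lower = ifelse(ok, exp(log(odds) - z * se), NA_real_),
             upper = ifelse(ok, exp(log(odds) + z * se), NA_real_),
             ci_defined = ok,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-group means with t-based confidence intervals
#'
#' @param values numeric outcome per patient.
#' @param labels group per patient.
#' @param level confidence level.
#' @return data.frame with `group`, `n`, `mean`, `sd`, `lower`, `upper`,
#'   `ci_defined` (FALSE for singleton groups).
#' @export
group_mean_ci <- function(values, labels, level = 0.95) {
  if (length(values) != length(labels)) stop("values and labels must align")
  ks <- sort(unique(labels))
  rows <- lapply(ks, function(g) {
    v <- values[labels == g]
    n <- length(v)
    m <- mean(v)
    if (n < 2L) {
      data.frame(group = as.character(g), n = n, mean = m, sd = NA_real_,
                 lower = NA_real_, upper = NA_real_, ci_defined = FALSE)
    } else {
      s <- stats::sd(v)
      half <- stats::qt(1 - (1 - level) / 2, n - 1L) * s / sqrt(n)
      data.frame(group = as.character(g), n = n, mean = m, sd = s,
                 lower = m - half, upper = m + half, ci_defined = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Group-versus-outcome summary table
#'
#' Tests every declared outcome against trajectory group membership:
#' categorical outcomes by [crosstab()] + [chi_square_test()],
#' continuous outcomes by group means and [one_way_anova()].  Outcomes
#' that are entirely missing are skipped with a message.
#'
#' @param outcomes data.frame of per-patient outcomes (including
#'   `patient_id`, which is ignored by testing).
#' @param labels group per patient, aligned with `outcomes` rows.
#' @param types optional named character vector mapping outcome columns
#'   to `"continuous"` or `"categorical"`; by default numeric columns
#'   with more than 6 distinct values are continuous, the rest
#'   categorical.
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame with one row per tested outcome: `variable`,
#'   `type`, `test`, `statistic`, `p_value`, `significant`; per-group
#'   summaries are in attribute `group_summaries`.
#' @export
outcome_summary <- function(outcomes, labels, types = NULL, alpha = 0.05) {
  vars <- setdiff(names(outcomes), "patient_id")
  rows <- list()
  summaries <- list()
  for (v in vars) {
    x <- outcomes[[v]]
    if (all(is.na(x))) {
      message("outcome '", v, "' is entirely missing; skipped")
      next
    }
    type <- if (!is.null(types) && v %in% names(types)) {
      types[[v]]
    } else if (is.numeric(x) && length(unique(stats::na.omit(x))) > 6L) {
      "continuous"
    } else {
      "categorical"
    }
    if (type == "continuous") {
      tst <- one_way_anova(x, labels)
      summaries[[v]] <- group_mean_ci(x[!is.na(x)], labels[!is.na(x)])
    } else {
      tst <- chi_square_test(crosstab(labels[!is.na(x)], x[!is.na(x)]))
      summaries[[v]] <- crosstab(labels[!is.na(x)], x[!is.na(x)])
    }
    rows[[v]] <- data.frame(variable = v, type = type, test = tst$test_name,
                            statistic = tst$statistic, p_value = tst$p_value,
                            significant = tst$p_value < alpha)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "group_summaries") <- summaries
  out
}
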