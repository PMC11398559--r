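#' Univariate screening of admission covariates against trajectory groups
#'
#' Continuous covariates are tested by [one_way_anova()] across groups,
#' categorical ones by [chi_square_test()] of covariate x group.  A
#' constant covariate gets `p = 1` and is never selected.
#'
#' @param covariates data.frame of per-patient covariates (a
#'   `patient_id` column, if present, is ignored).
#' @param labels group per patient, aligned with rows.
#' @param types named character vector declaring each column
#'   `"continuous"` or `"categorical"`; columns without a declaration do
#'   not enter screening.  Defaults to numeric = continuous, everything
#'   else categorical.
#' @param alpha selection threshold.
#' @return data.frame with `feature`, `type`, `test`, `statistic`,
#'   `p_value`, `selected` (`p_value < alpha`).
#' @export
univariate_screen <- function(covariates, labels, types = NULL, alpha = 0.05) {
  vars <- setdiff(names(covariates), "patient_id")
  if (is.null(types)) {
    types <- vapply(covariates[vars], function(x) {
      if (is.numeric(x)) "continuous" else "categorical"
    }, character(1L))
  }
  vars <- intersect(vars, names(types))
  rows <- lapply(vars, function(v) {
    x <- covariates[[v]]
    keep <- !is.na(x)
    if (length(unique(x[keep])) < 2L) {
      return(data.frame(feature = v, type = types[[v]], test = "none",
                        statistic = NA_real_, p_value = 1, selected = FALSE))
    }
    tst <- if (types[[v]] == "continuous") {
      one_way_anova(x[keep], labels[keep])
    } else {
      chi_square_test(crosstab(labels[keep], x[keep]))
    }
    data.frame(feature = v, type = types[[v]], test = tst$test_name,
               statistic = tst$statistic, p_value = tst$p_value,
               selected = tst$p_value < alpha)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fit a multinomial logistic regression by Newton-Raphson
#'
#' Maximizes the multinomial log-likelihood under the softmax link with
#' the reference group's coefficients fixed at zero.  Because the link
#' is canonical the observed and expected information coincide, and the
#' returned coefficient covariance is the inverse information at the
#' optimum.  Convergence is declared when the largest absolute score
#' component falls below `1e-8` or the relative log-likelihood change
#' falls below `1e-10`; step halving guards the ascent.  Diverging
#' coefficients (`|beta| > 30`) are flagged as possible separation: the
#' fit is returned but marked non-converged.
#'
#' @param design numeric model matrix including an intercept column.
#' @param labels group membership (factor or coercible), `K >= 2` levels.
#' @param reference reference level; defaults to the first level.
#' @param max_iter,tol_score,tol_ll optimizer controls.
#' @param start optional starting coefficient matrix `(K-1) x p` (rows =
#'   non-reference groups in level order, columns = design columns).
#' @return object of class `mnlogit`: `coefficients` ((K-1) x p),
#'   `vcov`, `log_likelihood`, `converged`, `n_iter`, `reference`,
#'   `levels`, `n`, `fitted` (n x K class probabilities).
#' @export
fit_multinomial_logit <- function(design, labels, reference = NULL,
                                  max_iter = 100L, tol_score = 1e-8,
                                  tol_ll = 1e-10, start = NULL) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  g <- factor(labels)
  if (!is.null(reference)) g <- stats::relevel(g, ref = as.character(reference))
  K <- nlevels(g)
  if (K < 2L) stop("labels must have at least 2 levels")
  n <- nrow(X)
  p <- ncol(X)
  if (n <= (K - 1L) * p) stop("too few observations for ", (K - 1L) * p, " parameters")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  nonref <- levels(g)[-1L]
  Y <- 1 * outer(as.character(g), nonref, "==")       # n x (K-1) indicators
  B <- matrix(0, p, K - 1L)                           # columns = non-ref groups
  if (!is.null(start)) B <- t(as.matrix(start))
  probs_of <- function(B) {
    eta <- X %*% B
    eta <- pmin(pmax(eta, -700), 700)
    e <- exp(eta)
    e / (1 + rowSums(e))
  }
  ll_of <- function(B) {
    # clamp consistently so the plateau value never exceeds the true
    # log-likelihood bound of 0
    eta <- pmin(pmax(X %*% B, -700), 700)
    sum(Y * eta) - sum(log1p(rowSums(exp(eta))))
  }
  ll <- ll_of(B)
  converged <- FALSE
  it <- 0L
  H <- NULL
  while (it < max_iter) {
    it <- it + 1L
    P <- probs_of(B)
    G <- crossprod(X, Y - P)                          # p x (K-1) score blocks
    # information: block (a, b) = X' diag(P_a (delta_ab - P_b)) X
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (a in seq_len(K - 1L)) {
      for (b in seq_len(K - 1L)) {
        w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
        H[((a - 1L) * p + 1L):(a * p), ((b - 1L) * p + 1L):(b * p)] <-
          crossprod(X * w, X)
      }
    }
    if (max(abs(G)) < tol_score) { converged <- TRUE; break }
    delta <- tryCatch(solve(H, as.vector(G)), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), as.vector(G))
    })
    # trust-region style cap against wild steps from an ill-conditioned
    # information matrix far from the optimum
    cap <- 1e3 * (1 + max(abs(B)))
    if (max(abs(delta)) > cap) delta <- delta * (cap / max(abs(delta)))
    step <- 1
    improved <- FALSE
    repeat {
      Bnew <- B + matrix(step * delta, p, K - 1L)
      llnew <- ll_of(Bnew)
      if (is.finite(llnew) && llnew > ll) { improved <- TRUE; break }
      if (step < 1e-8) break
      step <- step / 2
    }
    if (!improved) { converged <- max(abs(G)) < 1e-4; break }  # ascent stalled
    done <- abs(llnew - ll) < tol_ll * max(abs(ll), 1)
    B <- Bnew
    ll <- llnew
    if (done) { converged <- TRUE; break }
  }
  if (any(abs(B) > 30)) {
    warning("coefficients diverging (|beta| > 30): possible separation; ",
            "fit flagged non-converged")
    converged <- FALSE
  }
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, nrow(H), ncol(H)))
  pn <- as.vector(outer(colnames(X), nonref, function(f, gr) paste(gr, f, sep = ":")))
  dimnames(vcov) <- list(pn, pn)
  coef <- t(B)
  dimnames(coef) <- list(nonref, colnames(X))
  P <- probs_of(B)
  fitted <- cbind(1 - rowSums(P), P)
  colnames(fitted) <- levels(g)
  structure(list(coefficients = coef, vcov = vcov, log_likelihood = ll,
                 converged = converged, n_iter = it,
                 reference = levels(g)[1L], levels = levels(g),
                 n = n, n_params = p * (K - 1L), fitted = fitted,
                 features = colnames(X)),
            class = "mnlogit")
}

#' @export
print.mnlogit <- function(x, ...) {
  cat("Multinomial logit (reference: ", x$reference, "), n = ", x$n,
      ", logLik = ", format(x$log_likelihood, digits = 6),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested multinomial models
#'
#' @param full,reduced `mnlogit` fits on the same data with the reduced
#'   model's features a subset of the full model's.
#' @return `assoc_test` list with `statistic` (2 * log-likelihood gap),
#'   `df` (difference in free parameters) and the chi-squared upper-tail
#'   `p_value`.
#' @export
lr_test <- function(full, reduced) {
  if (full$n != reduced$n) stop("models were fit to different data")
  if (!all(reduced$features %in% full$features)) {
    stop("reduced model's features must be a subset of the full model's")
  }
  stat <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (stat < -1e-6) stop("full model has lower likelihood than reduced: optimizer failure")
  stat <- max(stat, 0)
  df <- full$n_params - reduced$n_params
  if (df < 1L) {
    return(structure(list(statistic = 0, df = 0L, p_value = 1,
                          test_name = "likelihood_ratio"), class = "assoc_test"))
  }
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 test_name = "likelihood_ratio"),
            class = "assoc_test")
}

# expand one covariate into design columns; factors/characters are
# dummy-coded against their most frequent level, and enter/exit as a block
feature_block <- function(x, name) {
  if (is.numeric(x)) {
    m <- matrix(x, ncol = 1L, dimnames = list(NULL, name))
    return(m)
  }
  f <- factor(x)
  f <- stats::relevel(f, ref = names(which.max(table(f))))
  mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  colnames(mm) <- paste0(name, levels(f)[-1L])
  mm
}

stepwise_design <- function(covariates, features) {
  n <- nrow(covariates)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  for (f in features) X <- cbind(X, feature_block(covariates[[f]], f))
  X
}

#' Forward stepwise multinomial model over screened candidates
#'
#' Starts from the intercept-only model and, at each step, adds the
#' candidate whose likelihood-ratio test against the current model has
#' the smallest p-value, provided it is below `alpha` (ties: larger
#' statistic, then input order).  Multi-level categorical candidates
#' enter as a dummy block.  Stops when no candidate qualifies.
#'
#' @param covariates data.frame holding the candidate columns.
#' @param labels group membership per row.
#' @param candidates character vector of candidate column names
#'   (typically the screened features from [univariate_screen()]).
#' @param alpha entry threshold on the LRT p-value.
#' @param reference reference group level.
#' @return list with `model` (the final [fit_multinomial_logit()] fit)
#'   and `trace` (data.frame of the entry order: `step`, `feature`,
#'   `statistic`, `df`, `p_value`).
#' @export
forward_stepwise <- function(covariates, labels, candidates,
                             alpha = 0.05, reference = NULL) {
  if (!length(candidates)) stop("no candidate features supplied")
  keep <- stats::complete.cases(covariates[candidates])
  if (!all(keep)) {
    message(sum(!keep), " row(s) dropped for missing covariates")
    covariates <- covariates[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  selected <- character()
  current <- fit_multinomial_logit(stepwise_design(covariates, selected),
                                   labels, reference)
  trace <- data.frame(step = integer(), feature = character(),
                      statistic = numeric(), df = integer(),
                      p_value = numeric())
  remaining <- candidates
  step_i <- 0L
  while (length(remaining)) {
    fits <- lapply(remaining, function(f) {
      fit_multinomial_logit(stepwise_design(covariates, c(selected, f)),
                            labels, reference)
    })
    tests <- lapply(fits, lr_test, reduced = current)
    ps <- vapply(tests, `[[`, numeric(1L), "p_value")
    stats_ <- vapply(tests, `[[`, numeric(1L), "statistic")
    best <- order(ps, -stats_, seq_along(remaining))[1L]
    if (ps[best] >= alpha) break
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, feature = remaining[best],
                                     statistic = stats_[best],
                                     df = tests[[best]]$df,
                                     p_value = ps[best]))
    selected <- c(selected, remaining[best])
    current <- fits[[best]]
    remaining <- remaining[-best]
  }
  list(model = current, trace = trace, selected = selected)
}

#' Odds ratios with Wald confidence intervals from a multinomial fit
#'
#' `OR = exp(beta)` per non-reference group and feature, with interval
#' `exp(beta +/- z * se)` and a Wald z-test p-value.  Intercept rows are
#' omitted.  For a non-converged fit the ratios are returned but flagged
#' unreliable.
#'
#' @param model an `mnlogit` fit.
#' @param level confidence level.
#' @return data.frame with `group`, `feature`, `estimate` (log-odds),
#'   `or`, `lower`, `upper`, `p_value`, `reliable`.
#' @export
odds_ratios <- function(model, level = 0.95) {
  if (!model$converged) {
    warning("model did not converge; odds ratios flagged unreliable")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  co <- model$coefficients
  se <- matrix(sqrt(diag(model$vcov)), ncol(co), nrow(co))  # p x (K-1)
  se <- t(se)
  keep <- colnames(co) != "(Intercept)"
  rows <- expand.grid(group = rownames(co), feature = colnames(co)[keep],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b <- co[, keep, drop = FALSE]
  s <- se[, keep, drop = FALSE]
  data.frame(rows,
             estimate = as.vector(b),
             or = exp(as.vector(b)),
             lower = exp(as.vector(b) - z * as.vector(s)),
             upper = exp(as.vector(b) + z * as.vector(s)),
             p_value = 2 * stats::pnorm(-abs(as.vector(b) / as.vector(s))),
             reliable = model$converged)
}
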