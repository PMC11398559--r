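simulate_mnlogit_data <- function(n, B, seed) {
  # B: (K-1) x 2 matrix of (intercept, slope) for the non-reference groups
  set.seed(seed)
  x <- rnorm(n, 45, 15)
  eta <- cbind(1, x) %*% t(B)
  p <- cbind(1, exp(eta))
  p <- p / rowSums(p)
  y <- apply(p, 1, function(pr) sample.int(ncol(p), 1, prob = pr))
  list(design = cbind("(Intercept)" = 1, x = x), labels = y, x = x)
}

test_that("binary case reduces to ordinary logistic regression", {
  set.seed(55)
  n <- 400
  x <- rnorm(n)
  z <- rnorm(n)
  p <- plogis(-0.5 + 0.8 * x - 0.4 * z)
  y <- rbinom(n, 1, p)
  X <- cbind("(Intercept)" = 1, x = x, z = z)
  fit <- fit_multinomial_logit(X, y, reference = "0")
  ref <- glm(y ~ x + z, family = binomial())
  expect_lt(max(abs(fit$coefficients[1, ] - coef(ref))), 1e-6)
  # standard errors from the observed information agree too
  se_ref <- sqrt(diag(vcov(ref)))
  expect_lt(max(abs(sqrt(diag(fit$vcov)) - se_ref)), 1e-6)
})

test_that("multinomial fit agrees with an independent implementation", {
  skip_if_not_installed("nnet")
  dat <- simulate_mnlogit_data(800, rbind(c(0.3, -0.02), c(-0.5, 0.015), c(0.2, -0.04)),
                               seed = 91)
  fit <- fit_multinomial_logit(dat$design, dat$labels, reference = "1")
  nn <- nnet::multinom(factor(dat$labels) ~ dat$x, trace = FALSE,
                       reltol = 1e-14, maxit = 500)
  expect_lt(max(abs(fit$coefficients - unname(coef(nn)))), 1e-4)
  expect_equal(fit$log_likelihood, -nn$value, tolerance = 1e-8)
})

test_that("fitted class probabilities sum to one", {
  dat <- simulate_mnlogit_data(200, rbind(c(0, -0.02), c(0.5, 0.01)), seed = 12)
  fit <- fit_multinomial_logit(dat$design, dat$labels)
  expect_lt(max(abs(rowSums(fit$fitted) - 1)), 1e-12)
  expect_true(all(fit$fitted > 0))
})

test_that("known coefficients are recovered at large n", {
  B <- rbind(c(0, -0.04), c(0.5, -0.02), c(-0.3, 0.03))
  err <- vapply(c(301, 302, 303), function(s) {
    dat <- simulate_mnlogit_data(5000, B, seed = s)
    fit <- fit_multinomial_logit(dat$design, dat$labels, reference = "1")
    max(abs(fit$coefficients - B))
  }, numeric(1))
  expect_lt(mean(err), 0.35)   # intercept scale dominates; slopes are tighter
})

test_that("the optimizer reaches the same optimum from random starts", {
  dat <- simulate_mnlogit_data(300, rbind(c(0.2, -0.03), c(-0.2, 0.02)), seed = 8)
  set.seed(1)
  fits <- lapply(1:5, function(i) {
    st <- matrix(rnorm(2 * 2, 0, 0.5), 2, 2)
    fit_multinomial_logit(dat$design, dat$labels, reference = "1", start = st)
  })
  co <- sapply(fits, function(f) as.vector(f$coefficients))
  expect_lt(max(apply(co, 1, function(v) diff(range(v)))), 1e-5)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
})

test_that("degenerate designs are rejected with named columns", {
  X <- cbind("(Intercept)" = 1, a = rnorm(50), b = 0)
  expect_error(fit_multinomial_logit(X, rep(1:2, 25)), "collinear column")
  X2 <- cbind("(Intercept)" = 1, a = 1:50, a2 = 2 * (1:50))
  expect_error(fit_multinomial_logit(X2, rep(1:2, 25)), "a2")
})

test_that("perfect separation is flagged but estimates returned", {
  # narrow covariate scale forces the separating coefficients to diverge
  set.seed(40)
  x <- c(rnorm(30, -0.1, 0.001), rnorm(30, 0.1, 0.001))
  y <- rep(1:2, each = 30)
  X <- cbind("(Intercept)" = 1, x = x)
  expect_warning(fit <- fit_multinomial_logit(X, y), "separation")
  expect_false(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_warning(odds_ratios(fit), "unreliable")
})

test_that("likelihood-ratio test behaves at its boundaries", {
  dat <- simulate_mnlogit_data(300, rbind(c(0.2, -0.05), c(-0.4, 0.03)), seed = 3)
  full <- fit_multinomial_logit(dat$design, dat$labels)
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  reduced <- fit_multinomial_logit(dat$design[, 1, drop = FALSE], dat$labels)
  lr <- lr_test(full, reduced)
  expect_equal(lr$df, 2L)
  expect_lt(lr$p_value, 0.001)   # x truly drives the labels here
  expect_error(lr_test(reduced, full), "subset|failure")
})

test_that("univariate screening selects driven covariates and skips constants", {
  co <- generate_cohort(cohort_config(n_patients = 221, seed = 33))
  covs <- co$covariates
  covs$constant <- 1
  covs$noise <- rnorm(nrow(covs))
  scr <- univariate_screen(covs, co$truth$group,
                           types = c(age = "continuous", mgcs = "continuous",
                                     sex = "categorical", constant = "continuous",
                                     noise = "continuous"))
  expect_true(scr$selected[scr$feature == "age"])
  expect_true(scr$selected[scr$feature == "mgcs"])
  expect_false(scr$selected[scr$feature == "constant"])
  expect_equal(scr$p_value[scr$feature == "constant"], 1)
  expect_true(all((scr$p_value < 0.05) == scr$selected))
})

test_that("forward stepwise stops at the intercept when nothing qualifies", {
  set.seed(60)
  covs <- data.frame(a = rnorm(150), b = rnorm(150))
  labels <- sample(1:3, 150, replace = TRUE)
  # a stringent entry threshold that pure-noise candidates cannot meet
  st <- forward_stepwise(covs, labels, c("a", "b"), alpha = 1e-6)
  expect_length(st$selected, 0L)
  expect_equal(nrow(st$trace), 0L)
  expect_equal(st$model$features, "(Intercept)")
})

test_that("forward stepwise picks true drivers ahead of noise and is deterministic", {
  co <- generate_cohort(cohort_config(n_patients = 300, seed = 44))
  covs <- co$covariates
  set.seed(101)
  for (j in 1:3) covs[[paste0("noise", j)]] <- rnorm(nrow(covs))
  cand <- c("age", "mgcs", paste0("noise", 1:3))
  st1 <- forward_stepwise(covs, co$truth$group, cand)
  expect_true(all(c("age", "mgcs") %in% st1$selected))
  st2 <- forward_stepwise(covs, co$truth$group, cand)
  expect_identical(st1$selected, st2$selected)
  expect_equal(st1$trace$p_value, sort(st1$trace$p_value))
})

test_that("categorical candidates enter as dummy blocks against the modal level", {
  set.seed(70)
  n <- 300
  grp <- sample(1:3, n, replace = TRUE)
  race <- sample(c("white", "black", "other"), n, replace = TRUE,
                 prob = c(0.5, 0.35, 0.15))
  covs <- data.frame(race = race, age = rnorm(n, 45 - 3 * grp, 8))
  st <- forward_stepwise(covs, grp, c("race", "age"))
  expect_true("age" %in% st$selected)
  if ("race" %in% st$selected) {
    expect_true(any(grepl("^race", st$model$features)))
    expect_false("racewhite" %in% st$model$features)  # modal level is the baseline
  }
})

test_that("odds ratios exponentiate coefficients with Wald intervals", {
  dat <- simulate_mnlogit_data(2000, rbind(c(0, -0.0305), c(0, 0)), seed = 5)
  fit <- fit_multinomial_logit(dat$design, dat$labels, reference = "1")
  or <- odds_ratios(fit)
  expect_false("(Intercept)" %in% or$feature)
  # per-year odds ratio near exp(-0.0305) ~ 0.97 for the driven group
  expect_equal(or$or[or$group == "2"], exp(fit$coefficients["2", "x"]))
  se <- sqrt(fit$vcov["2:x", "2:x"])
  expect_equal(or$lower[or$group == "2"],
               exp(fit$coefficients["2", "x"] - qnorm(0.975) * se))
  # a null coefficient gives an interval spanning 1
  expect_gt(or$upper[or$group == "3"], 1)
  expect_lt(or$lower[or$group == "3"], 1)
})
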