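# Linear models for liana community structure: OLS fits with Wald CIs,
# Gaussian AIC stepwise selection, and the REML random-intercept
# pseudo-replication check for the nested sampling design.

#' Ordinary least squares fit with 95% confidence intervals
#'
#' @param y numeric response.
#' @param X data.frame or matrix of predictors (an intercept is added).
#' @param response name recorded in the result.
#' @return list of class `ls_model_fit`: `response`, `predictors`,
#'   `coefficients` (data.frame with estimate, lower, upper), `r_squared`,
#'   `f_statistic`, `aic`, `n`, and the underlying `lm` object.
#' @export
ols_fit <- function(y, X, response = "y") {
  X <- as.data.frame(X)
  if (length(y) <= ncol(X) + 1) stop("need n > p + 1 observations")
  # constant predictors are aliased with the intercept: drop, don't fail
  if (ncol(X)) {
    const <- vapply(X, function(v) length(unique(v)) == 1, TRUE)
    X <- X[, !const, drop = FALSE]
  }
  dat <- cbind(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(fit)))) stop("rank-deficient design: ",
                                  paste(names(coef(fit))[is.na(coef(fit))],
                                        collapse = ", "))
  ci <- confint(fit, level = 0.95)
  sm <- summary(fit)
  coefs <- data.frame(term = names(coef(fit)), estimate = unname(coef(fit)),
                      lower = ci[, 1], upper = ci[, 2], row.names = NULL)
  structure(list(
    response = response,
    predictors = colnames(X),
    coefficients = coefs,
    r_squared = sm$r.squared,
    f_statistic = if (ncol(X) > 0) unname(sm$fstatistic[1]) else NA_real_,
    aic = aic_gauss(fit),
    n = length(y),
    lm = fit
  ), class = "ls_model_fit")
}

#' @export
print.ls_model_fit <- function(x, ...) {
  cat(sprintf("Selected model for %s (n = %d): R2 = %.3f, F = %.2f, AIC = %.2f\n",
              x$response, x$n, x$r_squared, x$f_statistic, x$aic))
  for (i in seq_len(nrow(x$coefficients)))
    cat(sprintf("  %-12s %9.3f (%8.3f, %8.3f)\n",
                x$coefficients$term[i], x$coefficients$estimate[i],
                x$coefficients$lower[i], x$coefficients$upper[i]))
  invisible(x)
}

#' Gaussian AIC of a least-squares fit
#'
#' `AIC = n * log(RSS / n) + 2 * (k + 1)` with `k` the number of mean
#' parameters (the +1 counts the error variance). Constant terms are
#' dropped consistently, so only differences between models on the same
#' data are meaningful.
#'
#' @param fit an `lm` object or an [ols_fit] result.
#' @return the AIC value.
#' @export
aic_gauss <- function(fit) {
  if (inherits(fit, "ls_model_fit")) fit <- fit$lm
  rss <- sum(residuals(fit)^2)
  n <- length(residuals(fit))
  k <- length(coef(fit))
  n * log(rss / n) + 2 * (k + 1)
}

#' Stepwise AIC model selection (forward and backward)
#'
#' Greedy search over single-predictor additions and deletions starting
#' from the full model, accepting the move that lowers the Gaussian AIC
#' the most, until no move improves it. Exact AIC ties are broken toward
#' the model with fewer predictors.
#'
#' @param y numeric response.
#' @param X_full data.frame of candidate predictors.
#' @param response name recorded in the result.
#' @return an [ols_fit] of the selected predictor subset.
#' @export
stepwise_select <- function(y, X_full, response = "y") {
  X_full <- as.data.frame(X_full)
  all_vars <- colnames(X_full)
  fit_subset <- function(vars) {
    dat <- if (length(vars)) cbind(.y = y, X_full[, vars, drop = FALSE])
    else data.frame(.y = y)
    lm(.y ~ ., data = dat)
  }
  current <- all_vars
  current_aic <- aic_gauss(fit_subset(current))
  repeat {
    best_aic <- current_aic
    best_vars <- current
    for (v in current) { # drops first so AIC ties prefer fewer predictors
      cand <- setdiff(current, v)
      a <- aic_gauss(fit_subset(cand))
      if (a < best_aic - 1e-10 ||
          (a <= best_aic + 1e-10 && length(cand) < length(best_vars))) {
        best_aic <- a; best_vars <- cand
      }
    }
    for (v in setdiff(all_vars, current)) {
      cand <- c(current, v)
      a <- aic_gauss(fit_subset(cand))
      if (a < best_aic - 1e-10) { best_aic <- a; best_vars <- cand }
    }
    if (identical(sort(best_vars), sort(current))) break
    current <- best_vars
    current_aic <- best_aic
  }
  ols_fit(y, X_full[, current, drop = FALSE], response = response)
}

#' REML random-intercept model
#'
#' Profile-REML fit of `y ~ X + (1 | group)` (via lme4), used to test for
#' pseudo-replication in the nested quadrat design.
#'
#' @param y numeric response.
#' @param X data.frame of fixed predictors (may have zero columns).
#' @param groups grouping factor (>= 2 levels).
#' @return list with the `lmerMod` fit, the REML criterion, and the
#'   estimated variance components (`var_group`, `var_resid`).
#' @export
reml_random_intercept <- function(y, X, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  X <- as.data.frame(X)
  dat <- cbind(.y = y, X, .g = groups)
  rhs <- if (ncol(X)) paste(colnames(X), collapse = " + ") else "1"
  form <- as.formula(paste(".y ~", rhs, "+ (1 | .g)"))
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fit = fit,
       reml_criterion = lme4::REMLcrit(fit),
       var_group = vc$vcov[vc$grp == ".g"],
       var_resid = vc$vcov[vc$grp == "Residual"])
}

#' Likelihood-ratio test of the random intercept
#'
#' Compares the profile-REML criterion of the random-intercept model with
#' the same criterion evaluated at a zero variance ratio (no random term),
#' so both log-likelihoods share every constant. `LR = crit(theta = 0) -
#' crit(theta_hat) >= 0`; the p-value uses a plain chi-squared with 1 df,
#' which is conservative for detecting a variance component (no boundary
#' mixture correction).
#'
#' @inheritParams reml_random_intercept
#' @param level label for the grouping level tested (e.g. `"1-ha"`).
#' @return list of class `ls_ranef_test`: `level`, `ll_with`, `ll_without`
#'   (REML log-likelihoods), `lr`, `p_value`, `var_group`, `var_resid`.
#' @export
lr_test_random_effect <- function(y, X, groups, level = "group") {
  m <- reml_random_intercept(y, X, groups)
  devfun <- lme4::lmer(formula(m$fit), data = model.frame(m$fit),
                       REML = TRUE, devFunOnly = TRUE)
  crit0 <- devfun(0) # REML criterion with the random intercept shut off
  lr <- max(0, crit0 - m$reml_criterion)
  structure(list(
    level = level,
    ll_with = -m$reml_criterion / 2,
    ll_without = -crit0 / 2,
    lr = lr,
    p_value = pchisq(lr, df = 1, lower.tail = FALSE),
    var_group = m$var_group,
    var_resid = m$var_resid
  ), class = "ls_ranef_test")
}

#' @export
print.ls_ranef_test <- function(x, ...) {
  cat(sprintf("Random intercept (%s): LR = %.3f, p = %.4f (var %.3g vs resid %.3g)\n",
              x$level, x$lr, x$p_value, x$var_group, x$var_resid))
  invisible(x)
}
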