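#' Mann-Whitney U test
#'
#' Independent-samples rank test for a group difference. The reported
#' statistic is the U count for `x` (number of pairs in which an `x`
#' observation exceeds a `y` observation, ties counting one half);
#' p-values use the tie-corrected normal approximation, or the exact
#' distribution for small tie-free samples.
#'
#' @param x,y Numeric vectors (each non-empty); `NA`s are dropped.
#' @return A one-row tibble: `U`, `p`, `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  check_that(length(x) >= 1L && length(y) >= 1L,
             "Both groups need at least one observation.")
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble(U = unname(wt$statistic), p = wt$p.value,
         n_x = length(x), n_y = length(y))
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; incomplete pairs are
#' dropped pairwise. Constant input is flagged as undefined (`NA` with a
#' warning) rather than silently returning a value.
#'
#' @param x,y Paired numeric vectors.
#' @return A one-row tibble: `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  check_that(length(x) >= 3L, "Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input: Spearman correlation undefined.")
    return(tibble(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Residualize one symptom scale on another
#'
#' Returns the residuals of an intercept-plus-slope regression of
#' `outcome` on `control`, isolating the outcome-specific severity (for
#' example persecutory ideation with overall delusional ideation
#' regressed out). Residuals are mean zero by construction. A constant
#' control collapses to centering, with a warning. Incomplete pairs
#' yield `NA` residuals.
#'
#' @param outcome,control Numeric vectors of the same length.
#' @return Numeric vector of residuals (same length as the input).
#' @export
residualize <- function(outcome, control) {
  check_that(length(outcome) == length(control),
             "`outcome` and `control` must have equal length.")
  ok <- complete.cases(outcome, control)
  res <- rep(NA_real_, length(outcome))
  if (sd(control[ok]) == 0) {
    warn("Constant control scale: residuals are the centred outcome.")
    res[ok] <- outcome[ok] - mean(outcome[ok])
    return(res)
  }
  fit <- lm(outcome[ok] ~ control[ok])
  res[ok] <- unname(resid(fit))
  res
}

#' Skew-minimizing log transformation
#'
#' Evaluates a fixed candidate family -- the identity and
#' `log(x - min(x) + c)` for `c` on a fixed offset grid -- and returns
#' the candidate minimizing the absolute sample skewness. Every
#' candidate is monotone increasing, so ranks (and hence Spearman
#' correlations) are preserved. The chosen transform is recorded in a
#' descriptor so a report can be reproduced exactly.
#'
#' @param values Numeric vector (finite values; `NA` passed through).
#' @param offsets Offset grid for the log candidates.
#' @return A list with `values` (transformed), `transform`
#'   (`"identity"` or `"log"`), `offset`, and `skew_before`/`skew_after`.
#' @export
log_transform_minimizing_skew <- function(values,
                                          offsets = c(0.01, 0.1, 0.5, 1,
                                                      2, 5, 10)) {
  ok <- is.finite(values)
  check_that(any(ok), "Need at least one finite value.")
  base_skew <- sample_skewness(values[ok])
  if (is.na(base_skew)) {
    return(list(values = values, transform = "identity", offset = NA_real_,
                skew_before = base_skew, skew_after = base_skew))
  }
  lo <- min(values[ok])
  best <- list(values = values, transform = "identity", offset = NA_real_,
               skew = abs(base_skew))
  for (c0 in offsets) {
    tv <- values
    tv[ok] <- log(values[ok] - lo + c0)
    sk <- abs(sample_skewness(tv[ok]))
    if (!is.na(sk) && sk < best$skew) {
      best <- list(values = tv, transform = "log", offset = c0, skew = sk)
    }
  }
  list(values = best$values, transform = best$transform,
       offset = best$offset, skew_before = base_skew,
       skew_after = sample_skewness(best$values[ok]))
}

#' LASSO variable selection
#'
#' L1-penalized linear regression over the standardized candidate
#' predictors; the penalty `lambda` is chosen by seeded k-fold
#' cross-validation and predictors with non-zero coefficients at the
#' chosen `lambda` are retained. An empty retained set is a legal
#' outcome (full shrinkage). `lambda` may also be forced for diagnostic
#' use.
#'
#' @param design Numeric matrix or data frame of candidate predictors
#'   (complete cases only).
#' @param outcome Numeric response.
#' @param rule `"1se"` (default: largest `lambda` within one standard
#'   error of the CV minimum, favouring the sparser model) or `"min"`
#'   (CV-minimizing `lambda`).
#' @param nfolds Number of CV folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param lambda Optional forced penalty value, bypassing CV.
#' @return A list: `retained` (character vector of kept predictors),
#'   `lambda`, `rule`, and the non-zero `coefficients` at that lambda.
#' @export
lasso_select <- function(design, outcome, rule = c("1se", "min"),
                         nfolds = 10L, seed = 1L, lambda = NULL) {
  rule <- match.arg(rule)
  x <- as.matrix(design)
  check_that(nrow(x) == length(outcome), "Design/outcome size mismatch.")
  check_that(nrow(x) > 2L, "Need more than 2 observations.")
  check_that(!anyNA(x) && !anyNA(outcome),
             "LASSO stage requires complete cases.")
  if (is.null(lambda)) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(x, outcome, alpha = 1, nfolds = nfolds,
                            standardize = TRUE)
    lambda <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  }
  fit <- glmnet::glmnet(x, outcome, alpha = 1, standardize = TRUE)
  cf <- as.matrix(coef(fit, s = lambda, exact = TRUE,
                       x = x, y = outcome))[, 1]
  cf <- cf[setdiff(names(cf), "(Intercept)")]
  kept <- names(cf)[cf != 0]
  list(retained = kept, lambda = lambda, rule = rule,
       coefficients = cf[kept])
}

#' Ordinary least squares on the retained predictors
#'
#' Fits the post-selection linear model with an intercept and reports
#' coefficients, p-values and R-squared. An empty predictor set is a
#' legal outcome and produces an intercept-only record. A rank-deficient
#' design is rejected, naming the aliased columns.
#'
#' @param data Data frame holding outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns (possibly
#'   empty).
#' @return An `ols_fit` list: `coefficients` tibble (`term`, `estimate`,
#'   `std_error`, `p`), `r_squared`, `p_model`, `n`, `outcome`,
#'   `predictors`, and the underlying `lm` object.
#' @export
ols_fit <- function(data, outcome, predictors = character(0)) {
  check_that(outcome %in% names(data), "Outcome column not found.")
  check_that(all(predictors %in% names(data)),
             "All predictor columns must exist in `data`.")
  keep <- complete.cases(data[, c(outcome, predictors), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  fml <- if (length(predictors) == 0L) {
    stats::reformulate("1", response = outcome)
  } else {
    stats::reformulate(predictors, response = outcome)
  }
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Rank-deficient design; aliased column(s): ",
                 paste(bad, collapse = ", "), "."))
  }
  sm <- summary(fit)
  cf <- as.data.frame(sm$coefficients)
  out <- structure(
    list(coefficients = tibble(term = rownames(cf),
                               estimate = cf[, 1], std_error = cf[, 2],
                               p = cf[, 4]),
         r_squared = sm$r.squared,
         p_model = if (length(predictors) > 0L && !is.null(sm$fstatistic))
           stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE) else NA_real_,
         n = nrow(d), outcome = outcome, predictors = predictors,
         lm = fit),
    class = "ols_fit")
  out
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("<ols_fit>", x$outcome, "~",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "1",
      sprintf("  (n = %d, R^2 = %.3f)\n", x$n, x$r_squared))
  print(x$coefficients)
  invisible(x)
}
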