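# Regression of biobank impact on the fourteen biobank features:
# log(bIF + 1) ~ X1 + ... + X14, Gaussian errors, with Bonferroni
# correction over the fourteen feature coefficients and fit diagnostics.

#' Fit the biobank feature regression
#'
#' Gaussian generalized linear model of `log(bIF + 1)` on the fourteen
#' biobank features. P-values of the fourteen feature coefficients are
#' Bonferroni corrected (`min(1, 14 * p)`) and flagged significant at
#' alpha = 0.05 after correction. Rows with `bIF <= -1` (log undefined)
#' are dropped with a warning; perfect collinearity among features is an
#' error naming the collinear columns.
#'
#' @param features data.frame with the fourteen [BIOBANK_FEATURES]
#'   columns (and optionally `biobank_id`).
#' @param bif numeric bIF per row of `features`, or a `bif_scores` table
#'   from [rank_biobanks()] matched on `biobank_id`.
#' @param min_cases minimum complete cases required.
#' @return list of class `bif_feature_fit`: `coefficients` table
#'   (estimate, SE, 95% CI, raw and corrected p, significance flag),
#'   `r_squared`, `deviance`, `pearson_chisq` (both also given per
#'   residual degree of freedom), `n_biobanks`, and the underlying `fit`.
#' @export
fit_feature_model <- function(features, bif, min_cases = 30L) {
  if (inherits(bif, "bif_scores") || is.data.frame(bif)) {
    stopifnot(!is.null(features$biobank_id))
    bif <- bif$bIF[match(features$biobank_id, bif$biobank_id)]
  }
  X <- features[, intersect(BIOBANK_FEATURES, names(features)), drop = FALSE]
  missing_cols <- setdiff(BIOBANK_FEATURES, names(X))
  if (length(missing_cols) > 0L)
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  keep <- bif > -1 & !is.na(bif)
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with bIF <= -1 or missing dropped")
    X <- X[keep, , drop = FALSE]
    bif <- bif[keep]
  }
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  bif <- bif[cc]
  if (nrow(X) < min_cases)
    stop("need >= ", min_cases, " complete cases; have ", nrow(X))

  y <- log(bif + 1)
  dat <- cbind(y = y, X)
  mm <- stats::model.matrix(~ ., data = X)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("perfectly collinear feature(s): ", paste(dropped, collapse = ", "))
  }
  fit <- stats::glm(y ~ ., data = dat, family = stats::gaussian())
  sm <- summary(fit)
  co <- sm$coefficients
  est <- co[, 1]; se <- co[, 2]; p <- co[, 4]
  is_feature <- rownames(co) != "(Intercept)"
  m <- sum(is_feature)  # 14
  p_bonf <- ifelse(is_feature, pmin(1, m * p), p)
  ci_l <- est - stats::qnorm(0.975) * se
  ci_u <- est + stats::qnorm(0.975) * se
  # R^2 on the transformed response (Gaussian family: deviance = RSS)
  r2 <- 1 - fit$deviance / sum((y - mean(y))^2)
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  structure(list(
    coefficients = data.frame(
      term = rownames(co), estimate = est, std_error = se,
      ci_lower = ci_l, ci_upper = ci_u,
      p_value = p, p_bonferroni = p_bonf,
      significant = p_bonf < 0.05 & is_feature,
      row.names = NULL, stringsAsFactors = FALSE
    ),
    r_squared = r2,
    deviance = fit$deviance,
    deviance_per_df = fit$deviance / fit$df.residual,
    pearson_chisq = pearson,
    pearson_chisq_per_df = pearson / fit$df.residual,
    n_biobanks = nrow(X),
    fit = fit
  ), class = "bif_feature_fit")
}

#' @export
print.bif_feature_fit <- function(x, ...) {
  cat(sprintf("<bif_feature_fit> n = %d, R^2 = %.3f\n", x$n_biobanks,
              x$r_squared))
  cat(sprintf("  deviance/df = %.3f, Pearson chi-sq/df = %.3f\n",
              x$deviance_per_df, x$pearson_chisq_per_df))
  sig <- x$coefficients[x$coefficients$significant, "term"]
  cat("  significant after Bonferroni:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
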