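# ---- inferential layer ------------------------------------------------------

.as_psm_ttest <- function(ht, paired) {
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, alternative = ht$alternative,
         paired = paired, estimate = unname(ht$estimate),
         method = ht$method),
    class = "psm_ttest"
  )
}

#' @export
print.psm_ttest <- function(x, ...) {
  cat(sprintf("<psm_ttest> %s: t(%.1f) = %.3f, p = %.4g (%s)\n",
              if (x$paired) "paired" else "Welch",
              x$df, x$statistic, x$p_value, x$alternative))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' via [stats::t.test()]. Used to compare the per-image active-pixel
#' counts of the two training conditions.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (direction of
#'   `mean(x) - mean(y)`).
#' @return A list of class `psm_ttest` with `statistic`, `df`, `p_value`,
#'   `alternative` and `paired = FALSE`.
#' @export
welch_t <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both samples have zero variance; Welch statistic is undefined")
  }
  .as_psm_ttest(stats::t.test(x, y, alternative = alternative,
                              var.equal = FALSE, paired = FALSE),
                paired = FALSE)
}

#' Paired t-test
#'
#' One-sample t on the pairwise differences, with n - 1 degrees of
#' freedom (25 for the 26 per-letter accuracy pairs). This realizes the
#' paired comparison of the two training conditions' performance.
#'
#' @param x,y Equal-length numeric samples (pairs).
#' @inheritParams welch_t
#' @return A list of class `psm_ttest` with `paired = TRUE`.
#' @export
paired_t <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("paired samples must have equal length")
  stopifnot(length(x) >= 2L)
  if (stats::var(x - y) == 0) {
    stop("pairwise differences have zero variance; paired t is undefined")
  }
  .as_psm_ttest(stats::t.test(x, y, alternative = alternative, paired = TRUE),
                paired = TRUE)
}

#' Multiple regression with standardized predictors
#'
#' Transforms every predictor to standard scores (mean 0, SD 1 with the
#' n - 1 denominator) and fits ordinary least squares via [stats::lm()].
#' Slopes are therefore expressed per standard deviation of the raw
#' predictor, and — because standardized predictors are exactly mean-zero
#' — the intercept equals the sample mean of the dependent variable.
#'
#' @param table Data frame containing the dependent variable and
#'   predictors, with no missing cells.
#' @param dv Name of the dependent variable column.
#' @param predictors Character vector of predictor column names; each must
#'   have positive variance.
#' @return An object of class `std_regression`: `coefficients` data frame
#'   (term, estimate, se, p_value), `r2`, `adj_r2`, `n`, `predictors` and
#'   the underlying `lm` fit.
#' @export
standardized_regression <- function(table, dv, predictors) {
  stopifnot(is.data.frame(table), dv %in% names(table),
            all(predictors %in% names(table)))
  cols <- c(dv, predictors)
  if (anyNA(table[cols])) stop("table contains missing cells")
  zs <- lapply(predictors, function(p) {
    x <- table[[p]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("predictor '", p, "' has zero variance and cannot be standardized")
    }
    (x - mean(x)) / s
  })
  d <- data.frame(.dv = table[[dv]], zs)
  names(d) <- c(".dv", predictors)
  fit <- stats::lm(.dv ~ ., data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("predictors are collinear beyond tolerance: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(coefficients = data.frame(
           term = c("(Intercept)", predictors),
           estimate = unname(co[, 1]), se = unname(co[, 2]),
           p_value = unname(co[, 4]), stringsAsFactors = FALSE),
         r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
         n = nrow(d), predictors = predictors, fit = fit),
    class = "std_regression"
  )
}

#' @export
print.std_regression <- function(x, ...) {
  cat(sprintf("<std_regression> n = %d, adj R^2 = %.2f%%\n",
              x$n, 100 * x$adj_r2))
  co <- x$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %-12s %+ .4f +/- %.4f  (p = %.4g)\n",
                co$term[i], co$estimate[i], co$se[i], co$p_value[i]))
  }
  invisible(x)
}

#' @export
coef.std_regression <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
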