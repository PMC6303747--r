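# Supporting statistics for the behavioral (pre/post-copulatory) analyses:
# Yates-corrected chi-squared on 2x2 remating tables, paired t tests for
# within-treatment ejaculate comparisons, (mixed) linear models for mating
# behaviors, and mean imputation of sparsely missing covariates.

#' Yates-corrected chi-squared test on a 2x2 table
#'
#' Pearson's chi-squared with Yates' continuity correction,
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` with df = 1 (the correction is clamped
#' at zero, so near-identical rows give a statistic of exactly 0 and p = 1).
#' Delegates to [stats::chisq.test()], whose corrected statistic is
#' identical to the clamped formula.
#'
#' @param a,b successes and failures in row 1 (e.g. remated / did not).
#' @param c,d successes and failures in row 2.
#' @param correct apply the continuity correction (default TRUE).
#' @return list with `statistic`, `p_value`, `df`, `table`,
#'   `correction_applied`.
#' @export
yates_chi2 <- function(a, b, c, d, correct = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined: a table margin is zero", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), table = tab, correction_applied = correct)
}

#' Paired t test
#'
#' Standard two-sided paired t on the differences. Pairs with a missing
#' value in either vector are dropped. Zero-variance differences are handled
#' explicitly: all-zero differences give t = 0, p = 1; a constant nonzero
#' shift gives an infinite t reported with p = 0 and `degenerate = TRUE`.
#'
#' @param values_a,values_b paired measurements of equal length.
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- stats::complete.cases(values_a, values_b)
  d <- values_a[ok] - values_b[ok]
  if (length(d) < 2)
    stop("need at least 2 complete pairs", call. = FALSE)
  stderr_d <- stats::sd(d) / sqrt(length(d))
  if (stderr_d < 10 * .Machine$double.eps * max(abs(mean(d)), 1)) {
    if (abs(mean(d)) <= stderr_d)
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0,
                  n = length(d), degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                mean_diff = mean(d), n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(values_a[ok], values_b[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = length(d),
       degenerate = FALSE)
}

#' Linear model with an optional single random intercept
#'
#' Fits `response ~ predictors`, optionally with one random intercept (e.g.
#' generation or experimental group): ordinary least squares via [stats::lm()]
#' when `group` is NULL, otherwise a REML linear mixed model via
#' [lme4::lmer()]. The response may be log- or square-root-transformed first
#' to meet normality/homoscedasticity assumptions. p values use the t
#' distribution with residual df for OLS and the normal approximation for
#' the mixed fit.
#'
#' @param data data frame.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param group optional random-intercept column name.
#' @param transform `"none"`, `"log"` or `"sqrt"` applied to the response.
#' @return an `lm_fit` list: `coef`, `se`, `t_stat`, `p_value`,
#'   `sigma_resid`, `sigma_intercept` (0 for OLS), `transform`, `n_obs`,
#'   and the underlying fit object.
#' @export
fit_linear_model <- function(data, response, predictors, group = NULL,
                             transform = c("none", "log", "sqrt")) {
  transform <- match.arg(transform)
  pred_cols <- setdiff(predictors, "1")
  miss <- setdiff(c(response, pred_cols, group), names(data))
  if (length(miss))
    stop("column(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dat <- data[stats::complete.cases(data[c(response, pred_cols, group)]), ]
  yname <- ".resp"
  dat[[yname]] <- switch(transform,
                         none = dat[[response]],
                         log = log(dat[[response]]),
                         sqrt = sqrt(dat[[response]]))
  rhs <- if (length(pred_cols)) paste(pred_cols, collapse = " + ") else "1"
  Xchk <- stats::model.matrix(
    stats::as.formula(paste("~", rhs)), dat)
  qrX <- qr(Xchk)
  if (qrX$rank < ncol(Xchk)) {
    aliased <- colnames(Xchk)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (is.null(group)) {
    fm <- stats::lm(stats::as.formula(paste(yname, "~", rhs)), data = dat)
    sm <- summary(fm)$coefficients
    out <- list(coef = sm[, 1], se = sm[, 2], t_stat = sm[, 3],
                p_value = sm[, 4],
                sigma_resid = summary(fm)$sigma, sigma_intercept = 0,
                transform = transform, n_obs = nrow(dat), fit = fm)
  } else {
    fm <- lme4::lmer(
      stats::as.formula(paste(yname, "~", rhs, "+ (1 |", group, ")")),
      data = dat, REML = TRUE)
    sm <- stats::coef(summary(fm))
    vc <- as.data.frame(lme4::VarCorr(fm))
    out <- list(coef = sm[, "Estimate"], se = sm[, "Std. Error"],
                t_stat = sm[, "t value"],
                p_value = 2 * stats::pnorm(-abs(sm[, "t value"])),
                sigma_resid = vc$sdcor[vc$grp == "Residual"],
                sigma_intercept = vc$sdcor[vc$grp == group],
                transform = transform, n_obs = nrow(dat), fit = fm)
  }
  class(out) <- "lm_fit"
  out
}

#' Mean-impute missing values in a numeric vector
#'
#' Replaces missing entries by the mean of the observed entries (so sparse
#' gaps in behavioral covariates do not drop whole rows from a model). The
#' observed mean is unchanged by construction.
#'
#' @param column numeric vector, possibly with NAs.
#' @return list with `values` (no NAs) and `n_imputed`.
#' @export
mean_impute <- function(column) {
  obs <- !is.na(column)
  if (!any(obs)) stop("cannot impute an all-missing column", call. = FALSE)
  m <- mean(column[obs])
  column[!obs] <- m
  list(values = column, n_imputed = sum(!obs))
}
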