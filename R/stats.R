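# Analytical-validity statistics (ICC, Kendall W, CV, reliability bands)
# and clinical-validity statistics (KM/log-rank, Cox, Schoenfeld).

#' Log-transform a score matrix
#'
#' Natural log of (value + offset); the default offset of 1 keeps 0%
#' scores defined. Missing entries are preserved. Monotone, so orderings
#' within raters are unchanged.
#'
#' @param m numeric matrix (cases x raters), values >= 0.
#' @param offset added before the log (default 1).
#' @return transformed matrix of the same shape.
#' @export
log_transform <- function(m, offset = 1) {
  if (any(m < 0, na.rm = TRUE)) stop("scores must be >= 0")
  log(m + offset)
}

# Two-way ANOVA mean squares for a complete cases x raters matrix.
anova_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - g)^2)
  ssc <- n * sum((colm - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       msw = (ssc + sse) / (n * (k - 1)))
}

icc_all_forms <- function(ms, conf_level = 0.95) {
  n <- ms$n; k <- ms$k
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse; msw <- ms$msw
  a2 <- 1 - (1 - conf_level) / 2
  icc1 <- (msr - msw) / (msr + (k - 1) * msw)
  icc2 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc3 <- (msr - mse) / (msr + (k - 1) * mse)
  icc1k <- (msr - msw) / msr
  icc2k <- (msr - mse) / (msr + (msc - mse) / n)
  icc3k <- (msr - mse) / msr
  # F-based confidence limits (Shrout & Fleiss / McGraw & Wong)
  f1 <- msr / msw
  f1l <- f1 / stats::qf(a2, n - 1, n * (k - 1))
  f1u <- f1 * stats::qf(a2, n * (k - 1), n - 1)
  l1 <- (f1l - 1) / (f1l + k - 1); u1 <- (f1u - 1) / (f1u + k - 1)
  f3 <- msr / mse
  f3l <- f3 / stats::qf(a2, n - 1, (n - 1) * (k - 1))
  f3u <- f3 * stats::qf(a2, (n - 1) * (k - 1), n - 1)
  l3 <- (f3l - 1) / (f3l + k - 1); u3 <- (f3u - 1) / (f3u + k - 1)
  # ICC(2,1): Satterthwaite df for the rater term
  a <- k * icc2 / (n * (1 - icc2))
  b <- 1 + k * icc2 * (n - 1) / (n * (1 - icc2))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fu <- stats::qf(a2, n - 1, v)
  fl <- stats::qf(a2, v, n - 1)
  l2 <- n * (msr - fu * mse) /
    (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
  u2 <- n * (fl * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fl * msr)
  kform <- function(l) l * k / (1 + l * (k - 1))  # Spearman-Brown on limits
  data.frame(
    form = c("ICC1", "ICC2", "ICC3", "ICC1k", "ICC2k", "ICC3k"),
    value = c(icc1, icc2, icc3, icc1k, icc2k, icc3k),
    lower = c(l1, l2, l3, kform(l1), kform(l2), kform(l3)),
    upper = c(u1, u2, u3, kform(u1), kform(u2), kform(u3)),
    stringsAsFactors = FALSE)
}

concordance_result <- function(statistic, value, ci, n_cases, n_raters,
                               extra = list()) {
  structure(c(list(statistic = statistic, value = value,
                   ci = ci, n_cases = n_cases, n_raters = n_raters,
                   band = classify_reliability(value)), extra),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$statistic, x$value))
  if (!any(is.na(x$ci)))
    cat(sprintf(" (95%% CI, %.4f-%.4f)", x$ci[1], x$ci[2]))
  cat(sprintf("  [%s]  n_cases = %d, n_raters = %d\n",
              x$band, x$n_cases, x$n_raters))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' Two-way ANOVA mean squares on the complete-case matrix, with all six
#' Shrout-Fleiss forms. The default, ICC(2,1) -- two-way random effects,
#' absolute agreement, single rater -- is
#' \code{(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}.
#' 95% confidence limits use the F-distribution method (Satterthwaite
#' degrees of freedom for the rater term in ICC(2,1)).
#'
#' Rows containing any missing value are dropped (case-wise deletion); the
#' number dropped is recorded in \code{n_dropped}.
#'
#' @param m numeric matrix, cases in rows, raters in columns.
#' @param form one of \code{"ICC1", "ICC2", "ICC3", "ICC1k", "ICC2k",
#'   "ICC3k"}; default \code{"ICC2"} = ICC(2,1).
#' @param conf_level confidence level (default 0.95).
#' @return a \code{concordance_result}; the \code{forms} field holds the
#'   full six-form table.
#' @export
icc <- function(m, form = "ICC2", conf_level = 0.95) {
  m <- as.matrix(m)
  complete <- stats::complete.cases(m)
  dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 complete cases and 2 raters")
  ms <- anova_mean_squares(m)
  forms <- icc_all_forms(ms, conf_level)
  row <- forms[forms$form == form, ]
  if (!nrow(row)) stop("unknown ICC form: ", form)
  concordance_result(row$form, row$value, c(row$lower, row$upper),
                     ms$n, ms$k,
                     extra = list(forms = forms, n_dropped = dropped,
                                  mean_squares = ms))
}

#' Kendall's coefficient of concordance (tie-corrected)
#'
#' Ranks each rater's scores across cases with mid-rank ties, then
#' \code{W = 12 S / (m^2 (n^3 - n) - m sum(T_j))} where S is the sum of
#' squared deviations of case rank-sums from their mean and
#' \code{T_j = sum(t^3 - t)} over the tie groups of rater j. A chi-squared
#' approximation \code{m (n - 1) W} on n - 1 degrees of freedom provides a
#' p-value.
#'
#' @param m matrix of ordinal (or continuous) scores, cases x raters;
#'   rows with missing values are dropped.
#' @return a \code{concordance_result} (CI undefined for W; fields
#'   \code{chisq}, \code{df}, \code{p}).
#' @export
kendall_w <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 cases and 2 raters")
  ranks <- apply(m, 2L, rank)
  ties <- vapply(seq_len(k), function(j) {
    t <- table(m[, j])
    sum(t^3 - t)
  }, numeric(1))
  denom <- k^2 * (n^3 - n) - k * sum(ties)
  if (denom <= 0)
    stop("W undefined: every rater gave a constant rating")
  rs <- rowSums(ranks)
  s <- sum((rs - mean(rs))^2)
  w <- 12 * s / denom
  chisq <- k * (n - 1) * w
  concordance_result("Kendall W", w, c(NA_real_, NA_real_), n, k,
                     extra = list(chisq = chisq, df = n - 1,
                                  p = stats::pchisq(chisq, n - 1,
                                                    lower.tail = FALSE)))
}

#' Reliability band of a concordance value
#'
#' Bands follow the printed intervals: moderate 0.40-0.60, good
#' 0.61-0.80 (implemented as the half-open interval (0.60, 0.80]),
#' excellent above 0.80; values below 0.40 fall under the lowest band and
#' are labeled poor.
#'
#' @param value ICC or W value (<= 1).
#' @return one of \code{"poor", "moderate", "good", "excellent"}.
#' @export
classify_reliability <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value > 1) stop("reliability value must be <= 1")
  if (value < 0.40) "poor"
  else if (value <= 0.60) "moderate"
  else if (value <= 0.80) "good"
  else "excellent"
}

#' Per-case coefficient of variation across raters
#'
#' Sample standard deviation divided by mean for each case's rater values;
#' cases with zero mean get a missing CV. The summary is the median CV
#' across cases.
#'
#' @param m matrix, cases x raters; missing entries ignored per case.
#' @return list with \code{cv} (per-case vector) and \code{median_cv}.
#' @export
coefficient_of_variation <- function(m) {
  m <- as.matrix(m)
  cv <- apply(m, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x)
  })
  list(cv = cv, median_cv = stats::median(cv, na.rm = TRUE))
}

# Build a survival formula from a records data frame.
surv_formula <- function(covariates) {
  stats::as.formula(paste("survival::Surv(time_months, event) ~",
                          paste(covariates, collapse = " + ")))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param records data frame with \code{time_months}, \code{event} and the
#'   grouping column.
#' @param group name of the grouping column (default \code{"group"}).
#' @return list with \code{fit} (a \code{survfit} object), \code{chisq}
#'   and two-sided \code{p} from the log-rank test.
#' @export
km_logrank <- function(records, group = "group") {
  g <- factor(records[[group]])
  g <- droplevels(g)
  if (nlevels(g) != 2L) stop("need exactly 2 non-empty groups")
  if (sum(records$event) < 1L) stop("need at least 1 event")
  records$.group <- g
  fit <- survival::survfit(surv_formula(".group"), data = records)
  sd <- survival::survdiff(surv_formula(".group"), data = records)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd$chisq), p = p,
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling. The
#' multivariable adjustment set is the TIL group plus sex, age and tumor
#' stage (I-IV, stage I reference, three dummy contrasts). Non-convergence
#' or a monotone likelihood (perfect separation, detected as an unstable
#' or unbounded coefficient) raises an error.
#'
#' @param records data frame with \code{time_months}, \code{event} and the
#'   covariate columns.
#' @param covariates character vector of covariate names (default
#'   \code{"group"}; use \code{c("group", "sex", "age", "stage")} for the
#'   adjusted model).
#' @param ties tie-handling method (default \code{"efron"}).
#' @return object of class \code{cox_result}: data frame with one row per
#'   model term (coef, se, hr, lower, upper, p); the fitted
#'   \code{coxph} object is in the \code{fit} attribute.
#' @export
cox_fit <- function(records, covariates = "group", ties = "efron") {
  if (sum(records$event) < 1L) stop("need at least 1 event")
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("constant covariate: ", cv)
  }
  if ("stage" %in% covariates)
    records$stage <- factor(records$stage, levels = c("I", "II", "III", "IV"))
  fml <- surv_formula(covariates)
  environment(fml) <- environment()  # so residuals()/cox.zph() can refit
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = ties,
                    x = TRUE, y = TRUE, model = TRUE,
                    control = survival::coxph.control(eps = 1e-12,
                                                      iter.max = 50L)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stop("Cox fit failed: monotone likelihood (perfect separation?)")
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  out <- data.frame(term = names(beta), coef = unname(beta),
                    se = unname(se), hr = exp(unname(beta)),
                    lower = exp(unname(beta) - z * unname(se)),
                    upper = exp(unname(beta) + z * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Schoenfeld-residual proportional-hazards check
#'
#' Scaled Schoenfeld residuals regressed on Kaplan-Meier-transformed time;
#' score test of zero slope per covariate plus the global test
#' (\code{survival::cox.zph}).
#'
#' @param fit a \code{cox_result} or \code{coxph} object.
#' @param transform time transform (default \code{"km"}).
#' @return data frame with \code{term}, \code{chisq}, \code{df}, \code{p};
#'   the last row is \code{GLOBAL}.
#' @export
schoenfeld_test <- function(fit, transform = "km") {
  if (inherits(fit, "cox_result")) fit <- attr(fit, "fit")
  stopifnot(inherits(fit, "coxph"))
  if (fit$nevent < 3L) stop("need at least 3 events")
  z <- survival::cox.zph(fit, transform = transform)
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL, stringsAsFactors = FALSE)
}
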