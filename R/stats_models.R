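#' Intraclass correlation, two-way mixed model, absolute agreement
#'
#' Single-measures ICC of the "absolute agreement" type for two paired
#' measurement channels (e.g. examiner vs recognizer), computed from the
#' two-way mean squares: with n targets and k = 2 raters,
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' Absolute agreement penalizes systematic offsets between the
#' channels, so ICC = 1 only when the two series are identical.
#'
#' @param x,y paired numeric series of equal length (>= 3).
#' @return list of class `icc_result` with `icc`, the mean squares, and
#'   the model description.
#' @export
icc_absolute_agreement <- function(x, y) {
  if (length(x) != length(y)) stop_vrt("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop_vrt("ICC input must not contain NA")
  n <- length(x)
  if (n < 3L) stop_vrt("ICC needs at least 3 paired observations")
  m <- cbind(x, y)
  gm <- mean(m)
  if (all(m == m[1L])) stop_vrt("zero total variance; ICC undefined")
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  k <- 2L
  msr <- k * sum((row_m - gm)^2) / (n - 1L)
  msc <- n * sum((col_m - gm)^2) / (k - 1L)
  mse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2) / ((n - 1L) * (k - 1L))
  icc <- (msr - mse) / (msr + (k - 1L) * mse + (k / n) * (msc - mse))
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse, n = n,
                 model = "two-way mixed", type = "absolute agreement",
                 unit = "single measures"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f  (%s, %s, %s; n = %d)\n",
              x$icc, x$model, x$type, x$unit, x$n))
  invisible(x)
}

#' Durbin-Watson statistic
#'
#' `d = sum((e_t - e_{t-1})^2) / sum(e_t^2)` over residuals in row
#' order; d is in (0, 4), near 2 for serially uncorrelated residuals.
#'
#' @param residuals numeric vector, length >= 2.
#' @return the statistic d.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2L) stop_vrt("need at least 2 residuals")
  if (all(residuals == 0)) stop_vrt("all residuals are zero")
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Pairwise collinearity check
#'
#' Pearson correlations between candidate predictors with a flag for
#' pairs whose |r| exceeds the threshold; flagged pairs should not enter
#' the same regression model (the pipeline never co-enters SNR and the
#' rank-normalized effort rating for this reason).
#'
#' @param predictors data.frame of numeric candidate predictors.
#' @param threshold |r| above which a pair is flagged (default 0.7).
#' @return list with the correlation matrix `r` and a data.frame
#'   `flagged` of offending pairs.
#' @export
collinearity_check <- function(predictors, threshold = 0.7) {
  predictors <- as.data.frame(predictors)
  if (ncol(predictors) < 2L) stop_vrt("need at least 2 predictors")
  sds <- vapply(predictors, sd, 0)
  if (any(sds == 0))
    stop_vrt("constant predictor '%s'", names(predictors)[sds == 0][1L])
  r <- cor(predictors)
  pairs <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(r)[pairs[, 1L]],
                        var2 = colnames(r)[pairs[, 2L]],
                        r = r[pairs], stringsAsFactors = FALSE)
  list(r = r, threshold = threshold, flagged = flagged)
}

#' Stepwise linear regression with diagnostics
#'
#' Forward-stepwise ordinary least squares: at each step the candidate
#' whose addition has the smallest p-value enters if p <= `entry_p`
#' (default .05); after each entry, any selected predictor whose p-value
#' has risen to >= `removal_p` (default .10) is removed.  The result
#' reports every candidate — selected predictors with their
#' final-model coefficients, and non-selected predictors with the
#' coefficient each would have if added to the final model (flagged by
#' `entered = FALSE`) — together with standardized betas, 95% CIs,
#' adjusted R-squared, the model F test, and the Durbin-Watson statistic
#' of the final residuals in row order.
#'
#' @param data data.frame holding response and candidates, no missing
#'   values.
#' @param response name of the response column.
#' @param candidates character vector of candidate predictor columns, in
#'   reporting order.
#' @param entry_p,removal_p stepwise entry/removal thresholds.
#' @return object of class `stepwise_fit`.
#' @export
fit_stepwise <- function(data, response, candidates,
                         entry_p = 0.05, removal_p = 0.10) {
  data <- as.data.frame(data)
  used <- data[, c(response, candidates)]
  if (anyNA(used)) stop_vrt("stepwise input must not contain missing values")
  coef_table <- function(vars) {
    f <- stats::reformulate(vars, response)
    fit <- lm(f, data = data)
    cf <- coef(fit)
    if (anyNA(cf))
      stop_vrt("perfect collinearity among predictors: %s",
               paste(vars, collapse = ", "))
    list(fit = fit, summary = summary(fit)$coefficients)
  }
  selected <- character()
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > 2L * length(candidates) + 2L) break  # entry/removal cycle
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      # a perfect (zero-residual) fit yields NaN p; treat as significant
      ps <- vapply(remaining, function(cn) {
        p <- coef_table(c(selected, cn))$summary[cn, 4L]
        if (is.nan(p)) 0 else p
      }, 0)
      best <- which.min(ps)
      if (ps[best] <= entry_p) {
        selected <- c(selected, remaining[best])
        changed <- TRUE
      }
    }
    if (length(selected) > 1L) {
      sm <- coef_table(selected)$summary
      ps <- sm[selected, 4L]
      ps[is.nan(ps)] <- 0
      worst <- which.max(ps)
      if (ps[worst] >= removal_p) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  final <- if (length(selected)) coef_table(selected)$fit
  else lm(stats::reformulate("1", response), data = data)
  sy <- sd(data[[response]])
  row_for <- function(cn) {
    if (cn %in% selected) {
      fit <- final
    } else {
      fit <- coef_table(c(selected, cn))$fit
    }
    sm <- summary(fit)$coefficients
    b <- sm[cn, 1L]; se <- sm[cn, 2L]; p <- sm[cn, 4L]
    dfres <- fit$df.residual
    ci <- b + c(-1, 1) * qt(0.975, dfres) * se
    data.frame(predictor = cn, entered = cn %in% selected,
               beta = b, se = se,
               std_beta = b * sd(data[[cn]]) / sy,
               ci_lower = ci[1L], ci_upper = ci[2L], p = p,
               stringsAsFactors = FALSE)
  }
  coefs <- do.call(rbind, lapply(candidates, row_for))
  rownames(coefs) <- NULL
  sm <- summary(final)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = coefs,
    entry_order = selected,
    response = response,
    model = list(
      r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
      f = if (is.null(fstat)) NA_real_ else unname(fstat[1L]),
      df1 = if (is.null(fstat)) NA_real_ else unname(fstat[2L]),
      df2 = if (is.null(fstat)) NA_real_ else unname(fstat[3L]),
      p = if (is.null(fstat)) NA_real_ else
        pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
      durbin_watson = tryCatch(durbin_watson(stats::residuals(final)),
                               error = function(e) NA_real_),
      n = nrow(data)),
    fit = final),
    class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Stepwise OLS for %s (entered: %s)\n", x$response,
              if (length(x$entry_order)) paste(x$entry_order, collapse = ", ")
              else "none"))
  tab <- x$coefficients
  tab$beta <- round(tab$beta, digits)
  tab$se <- round(tab$se, digits)
  tab$std_beta <- round(tab$std_beta, digits)
  tab$ci_lower <- round(tab$ci_lower, digits)
  tab$ci_upper <- round(tab$ci_upper, digits)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("adj. R2 = %.3f, F(%g, %g) = %.3f, Durbin-Watson d = %.3f\n",
              x$model$adj_r2, x$model$df1, x$model$df2, x$model$f,
              x$model$durbin_watson))
  invisible(x)
}

#' Per-participant Pearson correlations
#'
#' Pearson r and two-sided p between two measures within each
#' participant, with a min/mean/max summary.  Participants with zero
#' variance in either measure are flagged and excluded from the
#' summary.
#'
#' @param x,y numeric vectors.
#' @param participant_keys participant id per pair.
#' @return list with `per_participant` (data.frame: participant, n, r,
#'   p, flagged) and `summary` (min, mean, max of r).
#' @export
per_participant_pearson <- function(x, y, participant_keys) {
  rows <- lapply(unique(participant_keys), function(p) {
    idx <- which(participant_keys == p)
    ok <- !is.na(x[idx]) & !is.na(y[idx])
    xi <- x[idx][ok]; yi <- y[idx][ok]
    if (length(xi) < 3L)
      stop_vrt("participant '%s' has fewer than 3 pairs", p)
    if (sd(xi) == 0 || sd(yi) == 0) {
      return(data.frame(participant = p, n = length(xi), r = NA_real_,
                        p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(xi, yi)
    data.frame(participant = p, n = length(xi), r = unname(ct$estimate),
               p = ct$p.value, flagged = FALSE, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  ok <- !per$flagged
  list(per_participant = per,
       summary = list(min = min(per$r[ok]), mean = mean(per$r[ok]),
                      max = max(per$r[ok]), n_flagged = sum(per$flagged)))
}

#' Thin wrappers over standard significance tests
#'
#' Convenience contracts over the routine tests the pipeline reports:
#' pooled-variance independent-samples t-test, repeated-measures ANOVA
#' (participant error stratum), Shapiro-Wilk normality check, and
#' Bonferroni correction.  These delegate to the standard `stats`
#' routines.
#'
#' @param values numeric vector.
#' @param groups two-level factor (independent samples).
#' @param within within-participant factor.
#' @param subject participant id.
#' @param p raw p-values.
#' @return the underlying test objects / adjusted p-values.
#' @name basic_tests
NULL

#' @rdname basic_tests
#' @export
group_ttest <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop_vrt("group_ttest needs exactly 2 groups")
  if (min(table(g)) < 2L) stop_vrt("each group needs at least 2 values")
  t.test(values ~ g, var.equal = TRUE)
}

#' @rdname basic_tests
#' @export
rm_anova <- function(values, within, subject) {
  df <- data.frame(values = values, within = factor(within),
                   subject = factor(subject))
  if (nlevels(df$subject) < 2L) stop_vrt("need at least 2 subjects")
  fit <- aov(values ~ within + Error(subject / within), data = df)
  tab <- summary(fit)[["Error: subject:within"]][[1L]]
  list(f = tab["within", "F value"], df1 = tab["within", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["within", "Pr(>F)"],
       aov = fit)
}

#' @rdname basic_tests
#' @export
shapiro_wilk <- function(values) shapiro.test(values)

#' @rdname basic_tests
#' @export
bonferroni <- function(p) p.adjust(p, method = "bonferroni")
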