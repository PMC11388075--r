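#' Testicular volume by the Lambert formula
#'
#' `volume = length x height x width x 0.71` (all dimensions in cm, volume in
#' mL). Vectorized.
#'
#' @param length_cm,height_cm,width_cm testis dimensions in cm (> 0).
#' @return volume in mL.
#' @examples
#' lambert_volume(4, 3, 2.5)  # 21.3 mL
#' @export
lambert_volume <- function(length_cm, height_cm, width_cm) {
  if (any(c(length_cm, height_cm, width_cm) <= 0, na.rm = TRUE))
    abort("all testis dimensions must be > 0")
  length_cm * height_cm * width_cm * 0.71
}

#' Two-group comparison of one parameter (NOA vs OA)
#'
#' Student's two-sample t-test, pooled variance by default (Welch behind the
#' `var_equal` flag), with group means and SDs formatted as in a cohort
#' comparison table.
#'
#' @param records tibble with a `group` column (`"NOA"`/`"OA"`) and the
#'   parameter column.
#' @param parameter name of the column to compare.
#' @param var_equal pooled-variance t-test when `TRUE` (default); Welch
#'   otherwise.
#' @return one-row tibble: `parameter`, `mean_noa`, `sd_noa`, `mean_oa`,
#'   `sd_oa`, `t`, `df`, `p_value`.
#' @export
group_compare <- function(records, parameter, var_equal = TRUE) {
  g <- records$group
  x <- records[[parameter]]
  if (is.null(x)) abort(sprintf("no column '%s' in records", parameter))
  xn <- x[g == "NOA"]; xo <- x[g == "OA"]
  if (length(xn) < 2L || length(xo) < 2L)
    abort("need at least 2 patients per group")
  if (sd(xn) == 0 && sd(xo) == 0 && mean(xn) == mean(xo))
    return(tibble(parameter = parameter, mean_noa = mean(xn),
                  sd_noa = 0, mean_oa = mean(xo), sd_oa = 0,
                  t = 0, df = length(xn) + length(xo) - 2, p_value = 1))
  tt <- stats::t.test(xn, xo, var.equal = var_equal)
  tibble(parameter = parameter,
         mean_noa = mean(xn), sd_noa = sd(xn),
         mean_oa = mean(xo), sd_oa = sd(xo),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Pearson correlation matrix with assumption checks
#'
#' Pairwise-complete Pearson correlations with two-sided p-values, plus the
#' per-variable Shapiro-Wilk normality check and (when a `group` column is
#' present) Levene's test of variance homogeneity across groups.
#'
#' @param records tibble of patients.
#' @param variables character vector of numeric column names.
#' @return list of class `pearson_matrix`: `r` and `p` matrices (unit
#'   diagonal; `NA` for zero-variance pairs), `assumptions` tibble
#'   (`variable`, `shapiro_w`, `shapiro_p`, `levene_p`), `n` matrix of
#'   pairwise complete counts.
#' @export
pearson_matrix <- function(records, variables) {
  stopifnot(all(variables %in% names(records)))
  k <- length(variables)
  r <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- r; n <- r
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    x <- records[[variables[i]]]; y <- records[[variables[j]]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  assumptions <- purrr::map_dfr(variables, function(v) {
    x <- records[[v]]
    x <- x[is.finite(x)]
    sw <- if (length(x) >= 3L && sd(x) > 0)
      stats::shapiro.test(x) else list(statistic = NA, p.value = NA)
    lev <- NA_real_
    if (!is.null(records$group) && length(unique(records$group)) > 1L) {
      lv <- car::leveneTest(records[[v]], factor(records$group))
      lev <- lv[["Pr(>F)"]][1]
    }
    tibble(variable = v, shapiro_w = unname(sw$statistic),
           shapiro_p = sw$p.value, levene_p = lev)
  })
  structure(list(r = r, p = p, n = n, assumptions = assumptions),
            class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, ...) {
  cat("<pearson_matrix>\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Tidy a correlation matrix into pair rows
#' @param x a `pearson_matrix`.
#' @param ... unused.
#' @return tibble `var1`, `var2`, `r`, `p_value`, `n`.
#' @method tidy pearson_matrix
#' @export
tidy.pearson_matrix <- function(x, ...) {
  vars <- rownames(x$r)
  out <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i >= j) next
    out[[length(out) + 1L]] <- tibble(
      var1 = vars[i], var2 = vars[j],
      r = x$r[i, j], p_value = x$p[i, j], n = x$n[i, j])
  }
  dplyr::bind_rows(out)
}

#' ROC analysis with DeLong CI and the Youden-optimal cutoff
#'
#' Empirical ROC by threshold sweep over the observed scores (predict
#' positive when `score >= threshold`, or `<=` for `direction = "lower"`).
#' AUC by the trapezoidal rule — identical to the Mann-Whitney U statistic
#' divided by `n1 * n0` — with a DeLong 95% CI. The optimal cutoff maximizes
#' the Youden index J = sensitivity + specificity - 1; ties in J are broken
#' toward the higher specificity.
#'
#' @param scores numeric predictor.
#' @param labels class labels.
#' @param positive_class label of the positive class (default `"OA"`).
#' @param direction `"higher"` if larger scores indicate the positive class,
#'   `"lower"` for the reverse, `"auto"` to pick the direction with AUC >=
#'   0.5.
#' @return list of class `roc_result`: `curve` tibble (`threshold`,
#'   `sensitivity`, `specificity`), `auc`, `auc_ci` (DeLong 95%),
#'   `youden_cutoff`, `sensitivity`, `specificity` (at the cutoff),
#'   `direction`.
#' @export
roc_analysis <- function(scores, labels, positive_class = "OA",
                         direction = c("higher", "lower", "auto")) {
  direction <- match.arg(direction)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    abort("both classes must be present in labels")
  if (direction == "auto") {
    direction <- if (mean(rank(scores)[pos]) >= mean(rank(scores)[!pos]))
      "higher" else "lower"
  }
  s <- if (direction == "higher") scores else -scores
  thr <- sort(unique(s))
  thr <- c(thr, Inf)
  sens <- vapply(thr, function(t) sum(pos & s >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(!pos & s < t) / n0, numeric(1))
  # trapezoid over (1 - spec, sens); equals rank U / (n1 n0)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  ci <- delong_ci(s, pos)
  J <- sens + spec - 1
  best <- which(J == max(J))
  best <- best[which.max(spec[best])]
  cutoff <- thr[best]
  if (direction == "lower") cutoff <- -cutoff
  structure(list(
    curve = tibble(threshold = if (direction == "lower") -thr else thr,
                   sensitivity = sens, specificity = spec),
    auc = auc, auc_ci = ci,
    youden_cutoff = cutoff,
    sensitivity = sens[best], specificity = spec[best],
    direction = direction, n_positive = n1, n_negative = n0),
    class = "roc_result")
}

# DeLong 95% CI for a single AUC
delong_ci <- function(s, pos, level = 0.95) {
  x <- s[pos]; y <- s[!pos]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  mat <- outer(x, y, psi)
  auc <- mean(mat)
  v10 <- rowMeans(mat)   # per positive
  v01 <- colMeans(mat)   # per negative
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (95%% CI %.3f-%.3f), Youden cutoff %.4g: sens %.1f%%, spec %.1f%%\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$youden_cutoff,
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Glance at a ROC result
#' @param x a `roc_result`.
#' @param ... unused.
#' @return one-row tibble.
#' @importFrom generics glance
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, auc_ci_lower = x$auc_ci[1], auc_ci_upper = x$auc_ci[2],
         youden_cutoff = x$youden_cutoff, sensitivity = x$sensitivity,
         specificity = x$specificity,
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' Fit the diagnostic logistic model (e.g. FSH + mean diameter)
#'
#' Maximum-likelihood logistic regression of the NOA/OA outcome (OA coded 1)
#' on the chosen covariates, with Wald standard errors, 95% CIs, odds ratios
#' `exp(beta)`, McFadden pseudo-R2 and variance inflation factors from
#' auxiliary linear regressions of each covariate on the others. Perfect
#' separation is detected and reported as an error naming the covariate.
#'
#' @param records tibble with a `group` column and the covariates.
#' @param covariates character vector of covariate column names (default
#'   `c("fsh", "mean_diameter")`).
#' @param outcome name of the outcome column (default `"group"`).
#' @param positive_class level coded 1 (default `"OA"`).
#' @return object of class `diagnostic_model` wrapping the `glm` fit, with
#'   `coefficients` tibble (`term`, `beta`, `se`, `ci_lower`, `ci_upper`,
#'   `odds_ratio`, `or_ci_lower`, `or_ci_upper`, `p_value`), `pseudo_r2`,
#'   `vif`.
#' @export
fit_logistic <- function(records, covariates = c("fsh", "mean_diameter"),
                         outcome = "group", positive_class = "OA") {
  stopifnot(all(c(covariates, outcome) %in% names(records)))
  y <- as.integer(records[[outcome]] == positive_class)
  if (length(unique(y)) < 2L) abort("outcome is not binary in these records")
  X <- records[covariates]
  zero_var <- vapply(X, function(v) sd(v) == 0, logical(1))
  if (any(zero_var))
    abort(sprintf("covariate '%s' is constant and inestimable",
                  covariates[zero_var][1]))
  dat <- cbind(tibble(.y = y), X)
  fml <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = dat))
  # separation: fitted probabilities numerically 0/1 everywhere
  pr <- stats::fitted(fit)
  if (all(pr < 1e-8 | pr > 1 - 1e-8)) {
    worst <- covariates[which.max(abs(stats::coef(fit)[-1]))]
    abort(sprintf(
      "perfect separation detected (covariate '%s'); model inestimable",
      worst))
  }
  sm <- summary(fit)$coefficients
  beta <- sm[, 1]; se <- sm[, 2]; pv <- sm[, 4]
  ci_l <- beta - 1.96 * se; ci_u <- beta + 1.96 * se
  coefs <- tibble(term = rownames(sm), beta = beta, se = se,
                  ci_lower = ci_l, ci_upper = ci_u,
                  odds_ratio = exp(beta),
                  or_ci_lower = exp(ci_l), or_ci_upper = exp(ci_u),
                  p_value = pv)
  null_dev <- fit$null.deviance; dev <- fit$deviance
  vif <- if (length(covariates) > 1L) {
    vapply(covariates, function(v) {
      aux <- stats::lm(stats::as.formula(
        paste(v, "~", paste(setdiff(covariates, v), collapse = " + "))),
        data = X)
      r2 <- summary(aux)$r.squared
      1 / (1 - r2)
    }, numeric(1))
  } else setNames(1, covariates)
  structure(list(fit = fit, coefficients = coefs,
                 pseudo_r2 = 1 - dev / null_dev, vif = vif,
                 covariates = covariates, positive_class = positive_class,
                 outcome = outcome),
            class = "diagnostic_model")
}

#' @export
print.diagnostic_model <- function(x, ...) {
  cat(sprintf("<diagnostic_model> %s ~ %s (positive class %s)\n",
              x$outcome, paste(x$covariates, collapse = " + "),
              x$positive_class))
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("McFadden pseudo-R2 %.3f; VIF %s\n", x$pseudo_r2,
              paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy the diagnostic model coefficients
#' @param x a `diagnostic_model`.
#' @param ... unused.
#' @return the coefficients tibble (one row per term).
#' @method tidy diagnostic_model
#' @export
tidy.diagnostic_model <- function(x, ...) x$coefficients

#' Glance at the diagnostic model
#' @param x a `diagnostic_model`.
#' @param ... unused.
#' @return one-row tibble with pseudo-R2, AIC, n and max VIF.
#' @method glance diagnostic_model
#' @export
glance.diagnostic_model <- function(x, ...) {
  tibble(pseudo_r2 = x$pseudo_r2, aic = stats::AIC(x$fit),
         n = length(stats::fitted(x$fit)), max_vif = max(x$vif))
}

#' Classification report at a probability cutoff
#'
#' Classify as the positive class (OA) when the fitted probability is at
#' least `cutoff` (default 0.5), then report the confusion counts and the
#' five derived metrics: sensitivity (OA correctly classified / all OA),
#' specificity (NOA correct / all NOA), PPV, NPV and accuracy, as
#' percentages.
#'
#' `classification_report()` is a generic: give it a fitted
#' `diagnostic_model` plus records, or a 2x2 confusion matrix of observed x
#' predicted counts (rows = observed `c(negative, positive)`, columns =
#' predicted) to reproduce a published table's arithmetic.
#'
#' @param x a `diagnostic_model` or a 2x2 counts matrix.
#' @param ... method arguments.
#' @return tibble: `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy` (percentages).
#' @export
classification_report <- function(x, ...) UseMethod("classification_report")

#' @rdname classification_report
#' @param records tibble of patients to classify.
#' @param cutoff probability cutoff (default 0.5).
#' @export
classification_report.diagnostic_model <- function(x, records, cutoff = 0.5,
                                                   ...) {
  if (missing(records) || !nrow(records)) abort("records must be non-empty")
  pr <- stats::predict(x$fit, newdata = records[x$covariates],
                       type = "response")
  obs <- records[[x$outcome]] == x$positive_class
  pred <- pr >= cutoff
  cm <- matrix(c(sum(!obs & !pred), sum(!obs & pred),
                 sum(obs & !pred), sum(obs & pred)),
               2, 2, byrow = TRUE)
  classification_report(cm)
}

#' @rdname classification_report
#' @export
classification_report.matrix <- function(x, ...) {
  stopifnot(all(dim(x) == c(2L, 2L)), all(x >= 0))
  tn <- x[1, 1]; fp <- x[1, 2]; fn <- x[2, 1]; tp <- x[2, 2]
  tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = 100 * tp / (tp + fp),
    npv = 100 * tn / (tn + fn),
    accuracy = 100 * (tp + tn) / sum(x))
}
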