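# Cohort-level statistics: normality-gated group comparisons with Tukey
# post-hoc tests, chi-square for categorical data, per-group Pearson
# correlation grids, and univariate / covariate-adjusted linear regressions
# reporting standardized coefficients.

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD. Constant input is flagged non-testable.
#'
#' @param values numeric vector, n >= 3 after dropping `NA`.
#' @param alpha significance level for the `is_normal` verdict.
#' @return list with `statistic`, `p_value`, `is_normal`, `degenerate`.
#' @export
test_normality <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 3L) stop("need at least 3 non-missing values", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                is_normal = NA, degenerate = TRUE))
  }
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       is_normal = kt$p.value >= alpha, degenerate = FALSE)
}

#' Compare a continuous variable across cohort groups
#'
#' The test is gated on normality of the variable pooled across groups (KS at
#' `alpha`): a normal variable gets Student's t-test (two groups) or one-way
#' ANOVA with Tukey-adjusted pairwise post-hoc p-values (three or more); a
#' non-normal variable gets the Kruskal-Wallis test.
#'
#' @param table cohort data frame.
#' @param variable name of the continuous variable.
#' @param group name of the group column (default `"group"`).
#' @param alpha normality-gate level.
#' @return object of class `group_comparison`: `variable`, `test_used`,
#'   `statistic`, `p_value`, `posthoc` (named Tukey-adjusted p-values or
#'   `NULL`), `group_summary`.
#' @export
compare_groups <- function(table, variable, group = "group", alpha = 0.05) {
  if (!variable %in% names(table)) stop(sprintf("missing variable '%s'", variable), call. = FALSE)
  if (!group %in% names(table)) stop(sprintf("missing group column '%s'", group), call. = FALSE)
  keep <- !is.na(table[[variable]]) & !is.na(table[[group]])
  x <- table[[variable]][keep]
  g <- factor(table[[group]][keep])
  counts <- table(g)
  if (length(counts) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 3L)) {
    stop(sprintf("groups with n < 3: %s",
                 paste(names(counts)[counts < 3L], collapse = ", ")), call. = FALSE)
  }
  summ <- data.frame(
    group = names(counts), n = as.integer(counts),
    mean = as.numeric(tapply(x, g, mean)),
    sd = as.numeric(tapply(x, g, stats::sd))
  )
  norm <- test_normality(x, alpha = alpha)
  posthoc <- NULL
  if (!isTRUE(norm$degenerate) && isTRUE(norm$is_normal)) {
    if (nlevels(g) == 2L) {
      tt <- stats::t.test(x ~ g, var.equal = TRUE)
      test_used <- "t-test"
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      fit <- stats::aov(x ~ g)
      an <- summary(fit)[[1L]]
      test_used <- "anova"
      statistic <- an[["F value"]][1L]
      p <- an[["Pr(>F)"]][1L]
      tk <- stats::TukeyHSD(fit)$g
      posthoc <- stats::setNames(tk[, "p adj"], rownames(tk))
    }
  } else {
    kw <- stats::kruskal.test(x ~ g)
    test_used <- "kruskal-wallis"
    statistic <- unname(kw$statistic)
    p <- kw$p.value
  }
  structure(list(variable = variable, test_used = test_used,
                 statistic = statistic, p_value = p, posthoc = posthoc,
                 group_summary = summ, normality = norm),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4f, p = %.4g\n",
              x$variable, x$test_used, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("  Tukey-adjusted pairwise p-values:\n")
    for (nm in names(x$posthoc)) cat(sprintf("    %s: %.4g\n", nm, x$posthoc[[nm]]))
  }
  invisible(x)
}

#' Pearson chi-square test on a contingency table of counts
#'
#' No continuity correction. Zero marginal rows/columns are rejected;
#' expected counts below 1 are rejected as unreliable.
#'
#' @param contingency matrix of group-by-category counts.
#' @return list with `statistic`, `p_value`, `df`, `expected`.
#' @export
chi_square_counts <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0) || anyNA(m)) stop("counts must be non-negative and complete", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("contingency table has a zero marginal row or column", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1)) stop("expected counts below 1; chi-square unreliable", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), expected = expected)
}

#' Per-group Pearson correlation grid between two layers
#'
#' For each group and each sector, correlates `<layer_a>_<sector>` with
#' `<layer_b>_<sector>` (two-sided test). Constant columns are flagged and
#' give `NA`.
#'
#' @param table cohort data frame.
#' @param layer_a,layer_b variable prefixes (e.g. `"gcl"`, `"mrnfl"`).
#' @param sectors sector suffixes (e.g. `c("central", "inner_inferior")`).
#' @param group group column name.
#' @return data frame with `group`, `sector`, `n`, `r`, `p_value`, `flagged`.
#' @export
pearson_grid <- function(table, layer_a, layer_b, sectors, group = "group") {
  if (!group %in% names(table)) stop(sprintf("missing group column '%s'", group), call. = FALSE)
  gl <- unique(as.character(table[[group]]))
  out <- expand.grid(group = gl, sector = sectors,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$n <- NA_integer_; out$r <- NA_real_; out$p_value <- NA_real_
  out$flagged <- FALSE
  for (i in seq_len(nrow(out))) {
    va <- paste(layer_a, out$sector[i], sep = "_")
    vb <- paste(layer_b, out$sector[i], sep = "_")
    miss <- setdiff(c(va, vb), names(table))
    if (length(miss)) stop(sprintf("missing variables: %s", paste(miss, collapse = ", ")), call. = FALSE)
    rows <- table[[group]] == out$group[i]
    a <- table[[va]][rows]; b <- table[[vb]][rows]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    out$n[i] <- length(a)
    if (length(a) < 3L) stop(sprintf("group '%s' has n < 3", out$group[i]), call. = FALSE)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      out$flagged[i] <- TRUE
    } else {
      ct <- stats::cor.test(a, b, method = "pearson")
      out$r[i] <- unname(ct$estimate)
      out$p_value[i] <- ct$p.value
    }
  }
  out
}

regression_result <- function(dependent, predictor, model, fit, x, y, covariates) {
  sm <- summary(fit)$coefficients
  b <- sm[predictor, "Estimate"]
  ci <- stats::confint(fit)[predictor, ]
  structure(list(
    dependent = dependent, predictor = predictor, model = model,
    coefficient = unname(b),
    standardized_coefficient = unname(b * stats::sd(x) / stats::sd(y)),
    ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
    p_value = unname(sm[predictor, "Pr(>|t|)"]),
    n = length(y), covariates = covariates
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s ~ %s (%s model%s)\n", x$dependent, x$predictor, x$model,
              if (length(x$covariates)) paste0("; adjusted for ",
                                               paste(x$covariates, collapse = ", ")) else ""))
  cat(sprintf("  standardized coefficient %.4f, slope %.4f (95%% CI %.4f to %.4f), p = %.4g, n = %d\n",
              x$standardized_coefficient, x$coefficient, x$ci_low, x$ci_high,
              x$p_value, x$n))
  invisible(x)
}

#' Univariate linear regression with a standardized coefficient
#'
#' Ordinary least squares of the dependent on a single predictor (complete
#' cases). The standardized coefficient is `slope * SD(predictor) /
#' SD(dependent)`, which for a univariate model equals the Pearson
#' correlation; the confidence interval refers to the unstandardized slope.
#'
#' @param table cohort data frame.
#' @param dependent,predictor variable names.
#' @return object of class `regression_result`.
#' @export
univariate_regression <- function(table, dependent, predictor) {
  miss <- setdiff(c(dependent, predictor), names(table))
  if (length(miss)) stop(sprintf("missing variables: %s", paste(miss, collapse = ", ")), call. = FALSE)
  d <- table[stats::complete.cases(table[c(dependent, predictor)]),
             c(dependent, predictor)]
  if (nrow(d) < 10L) stop("need n >= 10 complete cases", call. = FALSE)
  if (stats::sd(d[[predictor]]) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(stats::reformulate(predictor, dependent), data = d)
  regression_result(dependent, predictor, "univariate", fit,
                    d[[predictor]], d[[dependent]], character(0))
}

#' Covariate-adjusted linear regression with a standardized coefficient
#'
#' Multiple OLS of the dependent on the predictor plus covariates (complete
#' cases); reports the predictor's standardized partial coefficient
#' (`slope * SD(predictor) / SD(dependent)`) and two-sided p-value. A
#' rank-deficient design is rejected with the collinear columns named.
#'
#' @param table cohort data frame.
#' @param dependent,predictor variable names.
#' @param covariates covariate names (default age, gender_male,
#'   diabetes_duration, hba1c).
#' @return object of class `regression_result`.
#' @export
adjusted_regression <- function(table, dependent, predictor,
                                covariates = c("age", "gender_male",
                                               "diabetes_duration", "hba1c")) {
  vars <- c(dependent, predictor, covariates)
  miss <- setdiff(vars, names(table))
  if (length(miss)) stop(sprintf("missing variables: %s", paste(miss, collapse = ", ")), call. = FALSE)
  d <- table[stats::complete.cases(table[vars]), vars]
  if (nrow(d) < length(covariates) + 10L) {
    stop(sprintf("need n >= %d complete cases", length(covariates) + 10L), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(d[c(predictor, covariates)]))
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    dropped <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(c(predictor, covariates), dependent), data = d)
  regression_result(dependent, predictor, "adjusted", fit,
                    d[[predictor]], d[[dependent]], covariates)
}
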