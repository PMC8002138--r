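# Intra-rater reliability battery: two-way absolute-agreement intraclass
# correlation with F-based confidence intervals, Bland-Altman agreement
# analysis with a difference-vs-mean trend line, and the root-mean-square
# within-subject coefficient of variation.

# Two-way ANOVA mean squares of an n x k repeated-measures matrix.
anova_mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), sst = sst, n = n, k = k)
}

check_repeats <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x) || anyNA(x)) stop("repeated measures must be a complete numeric matrix", call. = FALSE)
  if (nrow(x) < 3L || ncol(x) < 2L) {
    stop("need at least 3 subjects and 2 sessions", call. = FALSE)
  }
  x
}

#' Absolute-agreement intraclass correlation (two-way random effects)
#'
#' Computes the two-way absolute-agreement ICC of McGraw and Wong — ICC(A,1)
#' for single measures,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' and ICC(A,k) for average measures,
#' `(MSR - MSE) / (MSR + (MSC - MSE)/n)` —
#' from the two-way ANOVA mean squares of the subject-by-session matrix, with
#' the standard F-based 95% confidence interval (average-measure bounds by
#' Spearman-Brown transformation of the single-measure bounds).
#'
#' @param data numeric matrix or data frame, subjects in rows, sessions in
#'   columns; no missing cells, at least 3 subjects and 2 sessions.
#' @param form `"single"` or `"average"` measures.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `anova_mean_squares` (rows, columns, error), `n`, `k`, `form`,
#'   `degenerate` flag. A matrix with zero total variance is reported as an
#'   explicit degenerate result with `icc = NA`.
#' @export
icc_absolute_agreement <- function(data, form = c("single", "average"),
                                   conf_level = 0.95) {
  form <- match.arg(form)
  x <- check_repeats(data)
  ms <- anova_mean_squares(x)
  n <- ms$n; k <- ms$k
  out <- structure(list(
    form = form, icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    anova_mean_squares = c(rows = ms$msr, columns = ms$msc, error = ms$mse),
    n = n, k = k, conf_level = conf_level, degenerate = FALSE
  ), class = "icc_result")
  if (ms$sst <= 0) {
    out$degenerate <- TRUE
    return(out)
  }
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  a1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # Single-measure CI (McGraw & Wong 1996), then Spearman-Brown for average.
  if (mse == 0 && msc == 0) {
    ci1 <- c(1, 1)
  } else {
    alpha <- 1 - conf_level
    a <- (k * a1) / (n * (1 - a1))
    b <- 1 + (k * a1 * (n - 1)) / (n * (1 - a1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    high <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci1 <- c(low, high)
  }
  if (form == "single") {
    out$icc <- a1
    out$ci_low <- ci1[1L]; out$ci_high <- ci1[2L]
  } else {
    sb <- function(r) k * r / (1 + (k - 1) * r)
    out$icc <- (msr - mse) / (msr + (msc - mse) / n)
    out$ci_low <- sb(ci1[1L]); out$ci_high <- sb(ci1[2L])
  }
  out$ci_low <- min(out$ci_low, out$icc)
  out$ci_high <- max(out$ci_high, out$icc)
  out
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (two-way random, absolute agreement, %s measures)\n", x$form))
  if (x$degenerate) {
    cat("  degenerate: zero total variance, ICC undefined\n")
  } else {
    cat(sprintf("  ICC = %.4f, %d%% CI [%.4f, %.4f] (n = %d subjects, k = %d sessions)\n",
                x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n, x$k))
  }
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `first - second`; the bias is their mean and the limits of
#' agreement are `bias +/- 1.96 * SD(differences)`. A least-squares regression
#' of difference on pairwise mean gives the trend line.
#'
#' @param first,second paired measurement vectors, equal length >= 3.
#' @return object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `trend_slope`, `trend_intercept`, `differences`, `means`.
#' @export
bland_altman <- function(first, second) {
  if (length(first) != length(second)) stop("`first` and `second` must have equal length", call. = FALSE)
  if (length(first) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(first) || anyNA(second)) stop("missing values not allowed", call. = FALSE)
  d <- first - second
  m <- (first + second) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  if (stats::var(m) > 0) {
    fit <- stats::lm.fit(cbind(1, m), d)$coefficients
  } else {
    fit <- c(bias, 0)
  }
  structure(list(
    bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    trend_intercept = unname(fit[1L]), trend_slope = unname(fit[2L]),
    differences = d, means = m
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (first - second)\n")
  cat(sprintf("  bias %.4f, limits of agreement [%.4f, %.4f]\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  trend: difference = %.4f %+.4f * mean\n",
              x$trend_intercept, x$trend_slope))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' Difference-vs-mean scatter with bias, limits of agreement, and the
#' regression line of difference on mean.
#'
#' @param x a [bland_altman()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of measurements",
                 ylab = "difference (first - second)", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2), col = c("grey40", "black", "grey40"))
  graphics::abline(x$trend_intercept, x$trend_slope, col = "deeppink")
  invisible(x)
}

#' Within-subject coefficient of variation of paired measurements
#'
#' Root-mean-square form: with per-subject difference `d_i` and pairwise mean
#' `m_i`, `CV = 100 * sqrt(mean((d_i^2 / 2) / m_i^2))` percent. The
#' per-subject SD/mean variant (`method = "sd-mean"`) averages
#' `100 * |d_i| / (sqrt(2) * m_i)`. The confidence interval applies chi-square
#' bounds with n degrees of freedom to the within-subject variance.
#'
#' @param first,second paired measurement vectors, equal length >= 3, all
#'   pairwise means positive.
#' @param method `"rms"` (default) or `"sd-mean"`.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `cv_result`: `cv_percent`, `ci_low`, `ci_high`,
#'   `method`, `n`.
#' @export
coefficient_of_variation <- function(first, second, method = c("rms", "sd-mean"),
                                     conf_level = 0.95) {
  method <- match.arg(method)
  if (length(first) != length(second)) stop("`first` and `second` must have equal length", call. = FALSE)
  n <- length(first)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(first) || anyNA(second)) stop("missing values not allowed", call. = FALSE)
  d <- first - second
  m <- (first + second) / 2
  if (any(m <= 0)) stop("all subject means must be positive", call. = FALSE)
  cv <- if (method == "rms") {
    100 * sqrt(mean((d^2 / 2) / m^2))
  } else {
    mean(100 * abs(d) / (sqrt(2) * m))
  }
  alpha <- 1 - conf_level
  ci <- cv * sqrt(n / stats::qchisq(c(1 - alpha / 2, alpha / 2), df = n))
  structure(list(cv_percent = cv, ci_low = ci[1L], ci_high = ci[2L],
                 method = method, n = n, conf_level = conf_level),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Within-subject CV (%s): %.4f%%, %d%% CI [%.4f, %.4f] (n = %d)\n",
              x$method, x$cv_percent, round(100 * x$conf_level),
              x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Pivot a long repeated-measures table to a subjects-by-sessions matrix
#'
#' @param data long data frame.
#' @param value name of the value column.
#' @param subject,session names of the subject and session columns.
#' @return numeric matrix, subjects in rows (named), sessions in columns.
#' @export
as_repeats_matrix <- function(data, value, subject = "vessel_id", session = "session") {
  need <- c(value, subject, session)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")), call. = FALSE)
  wide <- stats::reshape(
    data[need], direction = "wide",
    idvar = subject, timevar = session, v.names = value
  )
  m <- as.matrix(wide[, setdiff(names(wide), subject), drop = FALSE])
  rownames(m) <- as.character(wide[[subject]])
  colnames(m) <- sub(paste0("^", value, "\\."), "session_", colnames(m))
  m
}
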