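# Synthetic eye-level cohorts: a latent-Gaussian model draws continuous
# variables per group with requested means, SDs and pairwise Pearson
# correlations; binary covariates are drawn independently at requested rates.

#' Specify a synthetic cohort
#'
#' @param groups named integer vector of eyes per group (each >= 3), e.g.
#'   `c(control = 32, NDR = 32, NPDR = 21)`.
#' @param means,sds named lists: one element per group, each a named numeric
#'   vector over the same set of continuous variables. `NA` means produce an
#'   `NA` column for that group (a variable not recorded there); SDs must be
#'   >= 0 where the mean is not `NA`.
#' @param correlations optional data frame with columns `var_a`, `var_b`,
#'   `group` (a group label or `"all"`), `r` (each in (-1, 1)): target Pearson
#'   correlations imposed on the latent Gaussian.
#' @param binary_rates optional named list per group of named rates in
#'   `[0, 1]` (`NA` allowed) for binary covariates.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, means, sds, correlations = NULL,
                        binary_rates = NULL, seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named vector", call. = FALSE)
  }
  if (any(groups < 3L)) stop("each group needs n >= 3", call. = FALSE)
  gl <- names(groups)
  if (!setequal(names(means), gl) || !setequal(names(sds), gl)) {
    stop("`means` and `sds` must have one element per group", call. = FALSE)
  }
  vars <- names(means[[1L]])
  for (g in gl) {
    if (!setequal(names(means[[g]]), vars) || !setequal(names(sds[[g]]), vars)) {
      stop("all groups must share the same continuous variable set", call. = FALSE)
    }
    bad <- !is.na(means[[g]]) & (is.na(sds[[g]]) | sds[[g]] < 0)
    if (any(bad)) {
      stop(sprintf("group '%s': SDs must be >= 0 where the mean is given", g), call. = FALSE)
    }
  }
  if (!is.null(correlations)) {
    need <- c("var_a", "var_b", "group", "r")
    if (!is.data.frame(correlations) || !all(need %in% names(correlations))) {
      stop("`correlations` must have columns var_a, var_b, group, r", call. = FALSE)
    }
    if (any(abs(correlations$r) >= 1)) {
      stop("correlation targets must lie in (-1, 1)", call. = FALSE)
    }
    unknown <- setdiff(unique(c(correlations$var_a, correlations$var_b)), vars)
    if (length(unknown)) {
      stop(sprintf("correlation targets name unknown variables: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(groups = groups, means = means, sds = sds,
                 correlations = correlations, binary_rates = binary_rates,
                 seed = as.integer(seed), variables = vars),
            class = "cohort_spec")
}

# Assemble the per-group latent correlation matrix and fail (naming the
# targeted pairs) if the assembly is not positive semi-definite.
group_correlation_matrix <- function(spec, group) {
  vars <- spec$variables
  p <- length(vars)
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  tgt <- spec$correlations
  pairs <- character(0)
  if (!is.null(tgt)) {
    use <- tgt$group == group | tgt$group == "all"
    for (i in which(use)) {
      a <- tgt$var_a[i]; b <- tgt$var_b[i]
      R[a, b] <- R[b, a] <- tgt$r[i]
      pairs <- c(pairs, sprintf("%s~%s (r = %g)", a, b, tgt$r[i]))
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "correlation targets for group '%s' do not form a positive semi-definite matrix; targeted pairs: %s",
      group, paste(pairs, collapse = ", ")), call. = FALSE)
  }
  R
}

#' Generate a synthetic cohort table
#'
#' Per group, continuous variables are a linear transform of correlated
#' standard-normal latents (symmetric matrix square root of the target
#' correlation matrix), so sample means/SDs and targeted Pearson correlations
#' converge to the spec values as n grows. Binary covariates are independent
#' Bernoulli draws at the requested rates.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with `eye_id`, `group`, the continuous variables, and
#'   the binary covariates.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  vars <- spec$variables
  with_seed(spec$seed, {
    parts <- lapply(names(spec$groups), function(g) {
      n <- spec$groups[[g]]
      R <- group_correlation_matrix(spec, g)
      e <- eigen(R, symmetric = TRUE)
      S <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(vars)) %*% t(e$vectors)
      Z <- matrix(stats::rnorm(n * length(vars)), n) %*% S
      X <- sapply(seq_along(vars), function(j) {
        mu <- spec$means[[g]][[vars[j]]]
        sd <- spec$sds[[g]][[vars[j]]]
        if (is.na(mu)) rep(NA_real_, n) else mu + sd * Z[, j]
      })
      df <- as.data.frame(X)
      names(df) <- vars
      if (!is.null(spec$binary_rates)) {
        rates <- spec$binary_rates[[g]]
        for (v in names(rates)) {
          df[[v]] <- if (is.na(rates[[v]])) NA_integer_ else
            stats::rbinom(n, 1L, rates[[v]])
        }
      }
      cbind(data.frame(eye_id = sprintf("%s_%02d", g, seq_len(n)),
                       group = g, stringsAsFactors = FALSE), df)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Default study-like cohort specification
#'
#' Emulates a three-group OCT study — healthy controls and two diabetic
#' groups without and with mild retinopathy — with group sizes 32/32/21 and
#' the demographic, morphometric and ETDRS-sector thickness structure typical
#' of such cohorts: arterial morphometry (RAOD, RALD, AWT, WLR, WCSA),
#' ganglion cell layer (GCL) and macular RNFL sector thicknesses, average
#' peripapillary RNFL and total retinal thickness. GCL and macular RNFL are
#' strongly correlated in the central sector (r 0.81/0.68/0.78 in
#' control/NDR/NPDR) and moderately in the inner-inferior and outer-superior
#' sectors; WCSA and central GCL are correlated at 0.353; outer and lumen
#' diameters are correlated at 0.85 for physical plausibility. Diabetes-only
#' covariates (duration, HbA1c, creatinine, eGFR, insulin) are `NA` in
#' controls.
#'
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L) {
  g <- c(control = 32L, NDR = 32L, NPDR = 21L)
  # per-variable (mean, sd) triplets: control, NDR, NPDR
  tab <- list(
    age = c(55.34, 12.37, 60.50, 9.95, 60.48, 9.53),
    bmi = c(27.16, 5.03, 32.12, 7.23, 29.44, 4.84),
    diabetes_duration = c(NA, NA, 9.24, 8.10, 14.67, 6.03),
    hba1c = c(NA, NA, 9.25, 2.30, 9.28, 1.79),
    creatinine = c(NA, NA, 0.83, 0.21, 1.05, 0.53),
    egfr = c(NA, NA, 88.19, 20.71, 74.25, 28.61),
    bcva_logmar = c(0.02, 0.04, 0.04, 0.06, 0.04, 0.06),
    raod = c(130.71, 10.08, 133.73, 8.44, 135.76, 10.04),
    rald = c(97.21, 8.10, 98.78, 6.87, 100.38, 8.12),
    awt = c(16.75, 2.19, 17.47, 1.90, 17.69, 2.13),
    wlr = c(0.35, 0.05, 0.36, 0.04, 0.35, 0.05),
    wcsa = c(6065.36, 1162.26, 6391.15, 977.05, 6646.89, 1085.16),
    gcl_central = c(16.16, 4.68, 15.06, 4.11, 17.81, 7.70),
    gcl_inner_inferior = c(52.97, 4.73, 48.47, 6.07, 48.81, 8.98),
    gcl_outer_superior = c(34.81, 3.49, 33.72, 3.25, 33.48, 4.32),
    gcl_average = c(40.65, 3.29, 38.05, 3.95, 38.80, 4.19),
    mrnfl_central = c(12.50, 1.97, 12.44, 2.18, 13.57, 2.98),
    mrnfl_inner_inferior = c(25.75, 2.76, 24.56, 3.30, 23.29, 3.70),
    mrnfl_outer_superior = c(37.25, 5.36, 35.34, 5.31, 38.19, 8.12),
    mrnfl_average = c(27.22, 1.97, 26.48, 2.58, 27.98, 5.19),
    prnfl_average = c(103.19, 17.47, 99.19, 10.28, 98.48, 11.61),
    total_central = c(280.19, 21.38, 264.44, 22.20, 286.19, 24.07),
    total_average = c(315.88, 12.48, 302.66, 14.07, 315.32, 16.79)
  )
  means <- lapply(c(1, 3, 5), function(i) vapply(tab, `[`, numeric(1), i))
  sds <- lapply(c(2, 4, 6), function(i) vapply(tab, `[`, numeric(1), i))
  names(means) <- names(sds) <- names(g)
  corr <- rbind(
    data.frame(var_a = "gcl_central", var_b = "mrnfl_central",
               group = c("control", "NDR", "NPDR"), r = c(0.81, 0.68, 0.78)),
    data.frame(var_a = "gcl_inner_inferior", var_b = "mrnfl_inner_inferior",
               group = c("control", "NDR", "NPDR"), r = c(0.61, 0.68, 0.46)),
    data.frame(var_a = "gcl_outer_superior", var_b = "mrnfl_outer_superior",
               group = c("control", "NDR", "NPDR"), r = c(0.35, 0.54, 0.48)),
    data.frame(var_a = "wcsa", var_b = "gcl_central", group = "all", r = 0.353),
    data.frame(var_a = "raod", var_b = "rald", group = "all", r = 0.85)
  )
  rates <- list(
    control = c(gender_male = 17 / 32, smoking = 8 / 32, insulin = NA,
                hbp = 17 / 32, cardiovascular = 3 / 32, dyslipidemia = 6 / 32),
    NDR = c(gender_male = 18 / 32, smoking = 10 / 32, insulin = 21 / 32,
            hbp = 24 / 32, cardiovascular = 14 / 32, dyslipidemia = 18 / 32),
    NPDR = c(gender_male = 15 / 21, smoking = 8 / 21, insulin = 17 / 21,
             hbp = 13 / 21, cardiovascular = 12 / 21, dyslipidemia = 16 / 21)
  )
  cohort_spec(g, means, sds, correlations = corr, binary_rates = rates, seed = seed)
}
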