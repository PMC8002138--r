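# Pipeline plumbing: cohort CSV round-trip, report writing, and a driver
# that chains simulate -> measure -> morphometry -> reliability -> cohort
# into a deterministic end-to-end synthetic analysis with a hashed manifest.

#' Read a cohort CSV
#'
#' Requires the documented `eye_id` and `group` columns; every other column is
#' preserved untouched. Missing required columns are rejected by name.
#'
#' @param path CSV path.
#' @param required column names that must be present.
#' @return data frame.
#' @export
read_cohort_csv <- function(path, required = c("eye_id", "group")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("cohort CSV missing required columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Write a cohort CSV at full precision
#'
#' @param table data frame.
#' @param path CSV path.
#' @return invisible path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a report table with rounded numeric columns
#'
#' Report tables round to 2 decimals; use [write_cohort_csv()] where full
#' precision must survive a round trip.
#'
#' @param table data frame.
#' @param path CSV path.
#' @param digits decimal places for numeric columns.
#' @return invisible path.
#' @export
write_report <- function(table, path, digits = 2) {
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], round, digits = digits)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param out_dir directory for artifacts (created if needed).
#' @param seed master integer seed; every stage derives its own stream from
#'   it.
#' @param stages subset of `simulate`, `measure`, `morphometry`,
#'   `reliability`, `cohort`, run in that order. Stages not run read their
#'   inputs from `out_dir` and abort naming any missing artifact.
#' @param n_eyes,vessels_per_eye,sessions size of the synthetic vessel study.
#' @param psf_sigma_um,noise_sd,um_per_px phantom blur, noise and sampling.
#' @param cohort_spec a [cohort_spec()]; defaults to
#'   [default_cohort_spec()] seeded from `seed`.
#' @param densitometry a [densitometry_config()].
#' @param alpha significance level for the cohort reports.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "measure", "morphometry",
                                  "reliability", "cohort"),
                       n_eyes = 6L, vessels_per_eye = 4L, sessions = 2L,
                       psf_sigma_um = 4, noise_sd = 3, um_per_px = 1,
                       cohort_spec = NULL, densitometry = densitometry_config(),
                       alpha = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.numeric(seed) || seed != round(seed)) stop("`seed` must be an integer", call. = FALSE)
  if (is.null(cohort_spec)) cohort_spec <- default_cohort_spec(seed = seed + 101L)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 n_eyes = as.integer(n_eyes),
                 vessels_per_eye = as.integer(vessels_per_eye),
                 sessions = as.integer(sessions),
                 psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
                 um_per_px = um_per_px, cohort_spec = cohort_spec,
                 densitometry = densitometry, alpha = alpha),
            class = "run_config")
}

artifact_path <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(config, name, stage) {
  p <- artifact_path(config, name)
  if (!file.exists(p)) {
    stop(sprintf("stage '%s' requires missing artifact '%s'", stage, name), call. = FALSE)
  }
  p
}

stage_simulate <- function(config) {
  # True per-vessel diameters: outer diameter and wall thickness drawn around
  # control-like means, lumen implied; four arteries per eye, two sessions of
  # independent noise per vessel.
  n_vessels <- config$n_eyes * config$vessels_per_eye
  truth <- with_seed(config$seed, {
    raod <- stats::rnorm(n_vessels, 130.71, 10.08)
    awt <- pmax(stats::rnorm(n_vessels, 16.75, 2.19), 5)
    data.frame(
      eye_id = rep(sprintf("eye_%02d", seq_len(config$n_eyes)),
                   each = config$vessels_per_eye),
      vessel_id = sprintf("vessel_%03d", seq_len(n_vessels)),
      raod_um = raod, rald_um = raod - 2 * awt,
      stringsAsFactors = FALSE
    )
  })
  profiles <- do.call(rbind, lapply(seq_len(n_vessels), function(i) {
    do.call(rbind, lapply(seq_len(config$sessions), function(s) {
      spec <- vessel_phantom_spec(
        truth$raod_um[i], truth$rald_um[i],
        psf_sigma_um = config$psf_sigma_um, noise_sd = config$noise_sd,
        um_per_px = config$um_per_px
      )
      pr <- generate_vessel_profile(spec, seed = config$seed + 1000L + i * 10L + s)
      data.frame(eye_id = truth$eye_id[i], vessel_id = truth$vessel_id[i],
                 session = s, position_px = pr$profile$positions,
                 intensity = pr$profile$intensities, stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(truth, artifact_path(config, "truth.csv"), row.names = FALSE)
  utils::write.csv(profiles, artifact_path(config, "profiles.csv"), row.names = FALSE)
  write_cohort_csv(generate_cohort(config$cohort_spec),
                   artifact_path(config, "cohort.csv"))
  c("truth.csv", "profiles.csv", "cohort.csv")
}

stage_measure <- function(config) {
  path <- require_artifact(config, "profiles.csv", "measure")
  profiles <- utils::read.csv(path, stringsAsFactors = FALSE)
  calib <- calibrate_scale(200 / config$um_per_px)
  keys <- unique(profiles[c("eye_id", "vessel_id", "session")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    rows <- profiles$vessel_id == keys$vessel_id[i] & profiles$session == keys$session[i]
    prof <- intensity_profile(profiles$position_px[rows], profiles$intensity[rows])
    m <- measure_vessel(prof, calib, config$densitometry)
    cbind(keys[i, , drop = FALSE],
          data.frame(raod_um = m$raod_um, rald_um = m$rald_um))
  }))
  rownames(out) <- NULL
  utils::write.csv(out, artifact_path(config, "measurements.csv"), row.names = FALSE)
  "measurements.csv"
}

stage_morphometry <- function(config) {
  path <- require_artifact(config, "measurements.csv", "morphometry")
  meas <- utils::read.csv(path, stringsAsFactors = FALSE)
  eyes <- morphometry_by_eye(meas, n_largest = config$vessels_per_eye)
  write_cohort_csv(eyes, artifact_path(config, "eye_morphometry.csv"))
  "eye_morphometry.csv"
}

stage_reliability <- function(config) {
  path <- require_artifact(config, "measurements.csv", "reliability")
  meas <- utils::read.csv(path, stringsAsFactors = FALSE)
  report <- lapply(c(raod = "raod_um", rald = "rald_um"), function(v) {
    m <- as_repeats_matrix(meas, v)
    icc1 <- icc_absolute_agreement(m, "single")
    icck <- icc_absolute_agreement(m, "average")
    ba <- bland_altman(m[, 1L], m[, 2L])
    cv <- coefficient_of_variation(m[, 1L], m[, 2L])
    list(
      icc_single = icc1$icc, icc_single_ci = c(icc1$ci_low, icc1$ci_high),
      icc_average = icck$icc, icc_average_ci = c(icck$ci_low, icck$ci_high),
      bias = ba$bias, loa = c(ba$loa_low, ba$loa_high),
      trend_slope = ba$trend_slope,
      cv_percent = cv$cv_percent, cv_ci = c(cv$ci_low, cv$ci_high),
      n_vessels = nrow(m)
    )
  })
  jsonlite::write_json(report, artifact_path(config, "reliability.json"),
                       auto_unbox = TRUE, digits = NA)
  "reliability.json"
}

stage_cohort <- function(config) {
  path <- require_artifact(config, "cohort.csv", "cohort")
  cohort <- read_cohort_csv(path)
  vars <- c("age", "bmi", "raod", "rald", "awt", "wlr", "wcsa",
            "gcl_central", "gcl_average", "mrnfl_average", "prnfl_average",
            "total_central")
  comps <- do.call(rbind, lapply(vars, function(v) {
    gc <- compare_groups(cohort, v, alpha = config$alpha)
    data.frame(variable = v, test_used = gc$test_used,
               statistic = gc$statistic, p_value = gc$p_value)
  }))
  grid <- pearson_grid(cohort, "gcl", "mrnfl",
                       c("central", "inner_inferior", "outer_superior"))
  regs <- do.call(rbind, lapply(c("raod", "rald", "awt", "wlr", "wcsa"), function(dep) {
    uni <- univariate_regression(cohort, dep, "gcl_central")
    adj <- adjusted_regression(cohort, dep, "gcl_central")
    data.frame(dependent = dep, predictor = "gcl_central",
               model = c("univariate", "adjusted"),
               standardized_coefficient = c(uni$standardized_coefficient,
                                            adj$standardized_coefficient),
               p_value = c(uni$p_value, adj$p_value),
               n = c(uni$n, adj$n))
  }))
  write_report(comps, artifact_path(config, "cohort_comparisons.csv"), digits = 4)
  write_report(grid, artifact_path(config, "cohort_correlations.csv"), digits = 4)
  write_report(regs, artifact_path(config, "cohort_regressions.csv"), digits = 4)
  c("cohort_comparisons.csv", "cohort_correlations.csv", "cohort_regressions.csv")
}

#' Run the synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order — simulate (phantom
#' profiles, ground truth, synthetic cohort), measure (FWHM densitometry of
#' every profile), morphometry (per-eye aggregation), reliability (ICC,
#' Bland-Altman, CV across the two sessions), cohort (group comparisons,
#' correlation grid, regressions) — writing each stage's artifacts to
#' `config$out_dir` and finally a JSON manifest with an MD5 hash per file.
#' Identical configuration and seed reproduce identical manifests.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(simulate = stage_simulate, measure = stage_measure,
                  morphometry = stage_morphometry, reliability = stage_reliability,
                  cohort = stage_cohort)
  produced <- character(0)
  for (stage in names(runners)) {
    if (stage %in% config$stages) {
      message(sprintf("[retidens] stage '%s' ...", stage))
      t0 <- Sys.time()
      produced <- c(produced, runners[[stage]](config))
      message(sprintf("[retidens] stage '%s' done in %.2f s", stage,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  manifest <- data.frame(
    file = produced,
    md5 = unname(tools::md5sum(vapply(produced, function(f)
      artifact_path(config, f), character(1)))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, artifact_path(config, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}
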