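# Synthetic vessel cross-section phantoms with exact analytic blur.
#
# The artery cross-section is modelled as a piecewise-constant profile —
# background | wall annulus | lumen | wall annulus | background — convolved
# with a Gaussian point-spread function. Because the ideal profile is a sum of
# boxcars, the convolution has a closed form in terms of the normal CDF, so
# the sampled phantom carries its blur exactly and the pre-blur edge positions
# are known to machine precision.

#' Specify a vessel cross-section phantom
#'
#' Defines the geometry, contrast, blur and noise of a synthetic retinal
#' artery intensity profile. The true outer diameter (`raod_um`) and lumen
#' diameter (`rald_um`) imply a wall thickness `(raod_um - rald_um) / 2`;
#' the profile extends `profile_halfwidth_um` beyond each outer wall edge.
#'
#' Default intensities put the lumen at the local background level with
#' brighter walls. Half-maximum boundary localization is unbiased only when
#' the two sides of an edge share a reference level; a lumen darker (or
#' brighter) than the surrounding tissue biases the inner crossings, which is
#' a property of the FWHM method itself, not of the phantom.
#'
#' @param raod_um true outer diameter, um (> 0).
#' @param rald_um true lumen diameter, um (0 < rald_um < raod_um).
#' @param wall_intensity,lumen_intensity,background_intensity intensities in
#'   arbitrary units; the wall must differ from both other levels.
#' @param psf_sigma_um Gaussian blur scale, um (>= 0).
#' @param noise_sd additive i.i.d. Gaussian noise SD, intensity units (>= 0).
#' @param um_per_px sampling step, um per pixel (> 0).
#' @param profile_halfwidth_um extent of the profile beyond each outer wall
#'   edge, um; must cover at least 3 blur sigmas.
#' @param polarity `"walls-bright"` or `"walls-dark"`; with the default
#'   intensities this flips the wall contrast, with explicit intensities it
#'   must agree with them.
#' @return an object of class `vessel_phantom_spec`.
#' @examples
#' spec <- vessel_phantom_spec(130, 97)
#' generate_vessel_profile(spec, seed = 1)$truth
#' @export
vessel_phantom_spec <- function(raod_um, rald_um,
                                wall_intensity = NULL,
                                lumen_intensity = 60,
                                background_intensity = 60,
                                psf_sigma_um = 0,
                                noise_sd = 0,
                                um_per_px = 1,
                                profile_halfwidth_um = 50,
                                polarity = c("walls-bright", "walls-dark")) {
  polarity <- match.arg(polarity)
  if (is.null(wall_intensity)) {
    if (polarity == "walls-bright") {
      wall_intensity <- 160
    } else {
      # dark walls over a brighter field; keep lumen == background by default
      wall_intensity <- 20
      if (missing(lumen_intensity)) lumen_intensity <- 120
      if (missing(background_intensity)) background_intensity <- 120
    }
  }
  check_scalar(raod_um, "raod_um", positive = TRUE)
  check_scalar(rald_um, "rald_um", positive = TRUE)
  if (rald_um >= raod_um) stop("`rald_um` must be smaller than `raod_um`", call. = FALSE)
  check_scalar(wall_intensity, "wall_intensity")
  check_scalar(lumen_intensity, "lumen_intensity")
  check_scalar(background_intensity, "background_intensity")
  check_scalar(psf_sigma_um, "psf_sigma_um", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(um_per_px, "um_per_px", positive = TRUE)
  check_scalar(profile_halfwidth_um, "profile_halfwidth_um", positive = TRUE)
  if (wall_intensity == lumen_intensity || wall_intensity == background_intensity) {
    stop("wall intensity must differ from both lumen and background", call. = FALSE)
  }
  bright <- wall_intensity > background_intensity
  if (bright != (polarity == "walls-bright")) {
    stop("`polarity` disagrees with the supplied intensities", call. = FALSE)
  }
  if (profile_halfwidth_um < 3 * psf_sigma_um) {
    stop(sprintf(
      paste0("profile window too small: profile_halfwidth_um = %g does not cover ",
             "3 * psf_sigma_um = %g beyond the outer boundaries"),
      profile_halfwidth_um, 3 * psf_sigma_um), call. = FALSE)
  }
  structure(list(
    raod_um = raod_um, rald_um = rald_um,
    wall_intensity = wall_intensity,
    lumen_intensity = lumen_intensity,
    background_intensity = background_intensity,
    psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
    um_per_px = um_per_px,
    profile_halfwidth_um = profile_halfwidth_um,
    polarity = polarity
  ), class = "vessel_phantom_spec")
}

#' Ground-truth morphometry implied by a phantom spec
#'
#' @param spec a [vessel_phantom_spec()].
#' @return named list with `raod_um`, `rald_um`, `awt_um`, `wlr`, `wcsa_um2`.
#' @export
phantom_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "vessel_phantom_spec"))
  awt <- (spec$raod_um - spec$rald_um) / 2
  list(
    raod_um = spec$raod_um,
    rald_um = spec$rald_um,
    awt_um = awt,
    wlr = (spec$raod_um - spec$rald_um) / spec$rald_um,
    wcsa_um2 = (pi / 4) * (spec$raod_um^2 - spec$rald_um^2)
  )
}

# Gaussian-blurred indicator of [a, b]: closed-form boxcar * Gaussian.
# The sigma = 0 branch is the sigma -> 0 limit, so a sample landing exactly
# on an edge takes the midway value 1/2 and the phantom stays symmetric.
blurred_box <- function(x, a, b, sigma) {
  if (sigma == 0) {
    as.numeric(x > a & x < b) + 0.5 * (x == a | x == b)
  } else {
    stats::pnorm((x - a) / sigma) - stats::pnorm((x - b) / sigma)
  }
}

#' Generate a sampled vessel cross-section intensity profile
#'
#' Renders the phantom as background + wall annuli + lumen, blurred
#' analytically by the spec's Gaussian PSF, sampled at `um_per_px`, with
#' additive i.i.d. Gaussian noise. Identical `(spec, seed)` pairs reproduce
#' identical output; the ground truth does not depend on the seed.
#'
#' @param spec a [vessel_phantom_spec()].
#' @param seed integer seed for the noise.
#' @return list with `profile` (an [intensity_profile()]; positions are
#'   0-based pixel indices, the vessel centre sits mid-profile) and `truth`
#'   (see [phantom_ground_truth()]).
#' @export
generate_vessel_profile <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "vessel_phantom_spec"))
  ro <- spec$raod_um / 2
  ri <- spec$rald_um / 2
  half_extent <- ro + spec$profile_halfwidth_um
  n <- 2L * floor(half_extent / spec$um_per_px) + 1L
  if (n < 7L) stop("profile window too small: fewer than 7 samples", call. = FALSE)
  centre <- (n - 1) / 2
  x <- (seq_len(n) - 1 - centre) * spec$um_per_px  # um, 0 at vessel centre
  s <- spec$psf_sigma_um
  walls <- blurred_box(x, -ro, -ri, s) + blurred_box(x, ri, ro, s)
  lumen <- blurred_box(x, -ri, ri, s)
  intens <- spec$background_intensity +
    (spec$wall_intensity - spec$background_intensity) * walls +
    (spec$lumen_intensity - spec$background_intensity) * lumen
  if (spec$noise_sd > 0) {
    intens <- intens + with_seed(seed, stats::rnorm(n, sd = spec$noise_sd))
  }
  list(
    profile = intensity_profile(intensities = intens),
    truth = phantom_ground_truth(spec)
  )
}

#' Simulate repeated diameter readings of known vessels
#'
#' Emulates a grader re-measuring every vessel in separate sessions: each true
#' diameter receives independent additive Gaussian measurement error per
#' session. With `error_sd = 0` the sessions are identical.
#'
#' @param truth_table data frame with columns `raod_um` and `rald_um` (one row
#'   per vessel); an optional `vessel_id` column is carried through.
#' @param error_sd measurement error SD, um (>= 0).
#' @param n_repeats number of sessions (>= 2).
#' @param seed integer seed.
#' @return long data frame with columns `vessel_id`, `session`, `raod_um`,
#'   `rald_um`.
#' @export
generate_repeat_measurements <- function(truth_table, error_sd, n_repeats = 2L, seed = 1L) {
  if (!is.data.frame(truth_table) || nrow(truth_table) == 0L) {
    stop("`truth_table` must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("raod_um", "rald_um") %in% names(truth_table))) {
    stop("`truth_table` needs `raod_um` and `rald_um` columns", call. = FALSE)
  }
  check_scalar(error_sd, "error_sd", nonneg = TRUE)
  if (!is.numeric(n_repeats) || n_repeats < 2L) {
    stop("`n_repeats` must be >= 2", call. = FALSE)
  }
  n <- nrow(truth_table)
  ids <- if ("vessel_id" %in% names(truth_table)) truth_table$vessel_id else seq_len(n)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_repeats), function(s) {
      data.frame(
        vessel_id = ids,
        session = s,
        raod_um = truth_table$raod_um + stats::rnorm(n, sd = error_sd),
        rald_um = truth_table$rald_um + stats::rnorm(n, sd = error_sd),
        stringsAsFactors = FALSE
      )
    }))
    rownames(out) <- NULL
    out
  })
}
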