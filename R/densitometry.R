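# FWHM micro-densitometry of a vessel cross-section intensity profile.
#
# A line crossing an artery in an OCT B-scan produces an intensity profile
# with two wall lobes separated by the lumen. Each wall boundary is localized
# at half of the lobe's peak height above its local background, with sub-pixel
# precision by linear interpolation between the two samples that straddle the
# half level. The outer-to-outer crossing distance gives the outer diameter,
# the inner-to-inner distance the lumen diameter; a scale calibration converts
# pixels to micrometres.

#' Construct an intensity profile
#'
#' @param positions pixel coordinates, strictly increasing and uniformly
#'   spaced; defaults to `0:(length(intensities) - 1)` (sample `i` sits at
#'   position `i`, 0-based).
#' @param intensities intensity values, length >= 7, finite.
#' @return object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions = NULL, intensities) {
  if (is.null(positions)) positions <- seq_along(intensities) - 1
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  if (length(intensities) < 7L) stop("profile needs at least 7 samples", call. = FALSE)
  if (length(positions) != length(intensities)) {
    stop("`positions` and `intensities` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(positions)) || !all(is.finite(intensities))) {
    stop("profile values must be finite", call. = FALSE)
  }
  d <- diff(positions)
  if (any(d <= 0)) stop("`positions` must be strictly increasing", call. = FALSE)
  step <- mean(d)
  if (any(abs(d - step) > 1e-9 * max(abs(step), 1))) {
    stop("`positions` must be uniformly spaced", call. = FALSE)
  }
  structure(list(positions = positions, intensities = intensities, step = step),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Intensity profile: %d samples, step %g px, range [%g, %g]\n",
              length(x$positions), x$step, min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Calibrate the pixel scale from the 200 um scale bar
#'
#' @param pixels_per_200um measured pixel length of the 200 um scale bar (> 0).
#' @return object of class `scale_calibration` with `um_per_px = 200 /
#'   pixels_per_200um`.
#' @examples
#' calibrate_scale(100)$um_per_px  # 2 um per pixel
#' @export
calibrate_scale <- function(pixels_per_200um) {
  check_scalar(pixels_per_200um, "pixels_per_200um", positive = TRUE)
  structure(list(pixels_per_200um = pixels_per_200um,
                 um_per_px = 200 / pixels_per_200um),
            class = "scale_calibration")
}

#' Read a grayscale OCT image (PNG or TIFF)
#'
#' Multi-channel images are collapsed to grayscale by averaging the first
#' three channels.
#'
#' @param path image file; extension selects the reader.
#' @return numeric matrix of intensities in `[0, 1]`.
#' @export
read_oct_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required", call. = FALSE)
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    stop(sprintf("unsupported image extension '%s' (use png/tiff)", ext), call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    k <- min(dim(img)[3L], 3L)
    img <- apply(img[, , seq_len(k), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Extract an intensity profile along a line in an image
#'
#' Samples the image by bilinear interpolation at uniform spacing along the
#' segment from `line_start` to `line_end`. Positions are pixel distances
#' along the line.
#'
#' @param image numeric matrix (rows x cols).
#' @param line_start,line_end `(row, col)` endpoints, 1-based, inside the
#'   image.
#' @param samples_per_px sampling density along the line (> 0).
#' @return an [intensity_profile()].
#' @export
extract_profile <- function(image, line_start, line_end, samples_per_px = 1) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (length(line_start) != 2L || length(line_end) != 2L) {
    stop("line endpoints must be (row, col) pairs", call. = FALSE)
  }
  check_scalar(samples_per_px, "samples_per_px", positive = TRUE)
  nr <- nrow(image); nc <- ncol(image)
  inside <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc
  if (!inside(line_start) || !inside(line_end)) {
    stop("line endpoints must lie inside the image", call. = FALSE)
  }
  dr <- line_end[1] - line_start[1]
  dc <- line_end[2] - line_start[2]
  len <- sqrt(dr^2 + dc^2)
  if (len == 0) stop("zero-length line", call. = FALSE)
  pos <- seq(0, len, by = 1 / samples_per_px)
  rr <- line_start[1] + pos / len * dr
  cc <- line_start[2] + pos / len * dc
  # bilinear interpolation with clamping at the image border
  r0 <- pmin(pmax(floor(rr), 1L), nr - 1L); r1 <- r0 + 1L
  c0 <- pmin(pmax(floor(cc), 1L), nc - 1L); c1 <- c0 + 1L
  fr <- rr - r0; fc <- cc - c0
  val <- image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    image[cbind(r1, c0)] * fr * (1 - fc) +
    image[cbind(r0, c1)] * (1 - fr) * fc +
    image[cbind(r1, c1)] * fr * fc
  intensity_profile(pos, val)
}

#' Densitometry configuration
#'
#' @param polarity `"auto"`, `"walls-bright"` or `"walls-dark"`. Auto runs the
#'   lobe detector under both orientations and keeps the one whose best lobe
#'   pair is more prominent.
#' @param smoothing_window_px odd moving-average window applied before lobe
#'   detection; 1 disables smoothing (the default). Crossings are computed on
#'   the smoothed signal.
#' @param baseline_fraction fraction of the profile ends used as each lobe's
#'   local background (0 < f <= 0.25).
#' @param min_lumen_px minimum separation between the two wall lobe peaks.
#' @return object of class `densitometry_config`.
#' @export
densitometry_config <- function(polarity = c("auto", "walls-bright", "walls-dark"),
                                smoothing_window_px = 1L,
                                baseline_fraction = 0.10,
                                min_lumen_px = 10) {
  polarity <- match.arg(polarity)
  if (smoothing_window_px < 1L || smoothing_window_px %% 2L == 0L) {
    stop("`smoothing_window_px` must be an odd integer >= 1", call. = FALSE)
  }
  check_scalar(baseline_fraction, "baseline_fraction", positive = TRUE)
  if (baseline_fraction > 0.25) stop("`baseline_fraction` must be <= 0.25", call. = FALSE)
  check_scalar(min_lumen_px, "min_lumen_px", positive = TRUE)
  structure(list(polarity = polarity,
                 smoothing_window_px = as.integer(smoothing_window_px),
                 baseline_fraction = baseline_fraction,
                 min_lumen_px = min_lumen_px),
            class = "densitometry_config")
}

# Interior local maxima of y; a flat plateau contributes its last sample.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  i[y[i] >= y[i - 1L] & y[i] > y[i + 1L]]
}

# Topographic prominence of each peak index in y.
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(i) {
    h <- y[i]
    left_min <- {
      j <- i
      m <- h
      while (j > 1L && y[j - 1L] <= h) { j <- j - 1L; m <- min(m, y[j]) }
      if (j == 1L) min(y[1L:i]) else m
    }
    right_min <- {
      j <- i
      m <- h
      n <- length(y)
      while (j < n && y[j + 1L] <= h) { j <- j + 1L; m <- min(m, y[j]) }
      if (j == length(y)) min(y[i:length(y)]) else m
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

# Detection on a single polarity-normalized signal; returns the best
# qualifying pair and its prominence score, or NULL.
best_lobe_pair <- function(s, positions, min_lumen_px) {
  peaks <- local_maxima(s)
  if (length(peaks) < 2L) return(NULL)
  prom <- peak_prominence(s, peaks)
  centre <- (positions[1L] + positions[length(positions)]) / 2
  best <- NULL
  for (a in seq_along(peaks)) {
    for (b in seq_along(peaks)) {
      if (b <= a) next
      if (abs(positions[peaks[b]] - positions[peaks[a]]) < min_lumen_px) next
      score <- prom[a] + prom[b]
      mid_off <- abs((positions[peaks[a]] + positions[peaks[b]]) / 2 - centre)
      if (is.null(best) || score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 && mid_off < best$mid_off)) {
        best <- list(idx = c(peaks[a], peaks[b]), score = score, mid_off = mid_off)
      }
    }
  }
  best
}

#' Detect the two vessel-wall lobes in a profile
#'
#' After polarity normalization (walls as local maxima) and optional
#' smoothing, the two most prominent local maxima separated by at least
#' `min_lumen_px` are taken as the wall lobes; among equally prominent pairs
#' the one whose midpoint is closest to the profile centre wins. Each lobe's
#' baseline is the median of the `baseline_fraction` of samples on its outer
#' side, and its half level sits midway between baseline and peak.
#'
#' @param profile an [intensity_profile()].
#' @param config a [densitometry_config()].
#' @return list of two `wall_lobe` objects (left first), each with
#'   `extremum_position`, `extremum_value`, `baseline_value`, `half_level`,
#'   plus the normalization needed to recompute crossings.
#' @export
detect_wall_lobes <- function(profile, config = densitometry_config()) {
  stopifnot(inherits(profile, "intensity_profile"))
  stopifnot(inherits(config, "densitometry_config"))
  y <- moving_average(profile$intensities, config$smoothing_window_px)
  if (diff(range(y)) <= 0) stop("no contrast: profile is flat", call. = FALSE)
  pos <- profile$positions

  candidates <- switch(config$polarity,
    "walls-bright" = list(`1` = best_lobe_pair(y, pos, config$min_lumen_px)),
    "walls-dark" = list(`-1` = best_lobe_pair(-y, pos, config$min_lumen_px)),
    "auto" = list(`1` = best_lobe_pair(y, pos, config$min_lumen_px),
                  `-1` = best_lobe_pair(-y, pos, config$min_lumen_px))
  )
  candidates <- Filter(Negate(is.null), candidates)
  if (length(candidates) == 0L) stop("no vessel found: fewer than two qualifying wall lobes", call. = FALSE)
  scores <- vapply(candidates, function(p) p$score, numeric(1))
  pick <- which.max(scores)
  sign <- as.numeric(names(candidates)[pick])
  pair <- candidates[[pick]]

  s <- sign * y
  n <- length(s)
  ntail <- max(1L, ceiling(config$baseline_fraction * n))
  make_lobe <- function(idx, side) {
    baseline <- if (side == "left") stats::median(s[seq_len(ntail)]) else
      stats::median(s[(n - ntail + 1L):n])
    extremum <- s[idx]
    if (extremum <= baseline) {
      stop("no vessel found: lobe peak does not rise above its baseline", call. = FALSE)
    }
    structure(list(
      extremum_position = pos[idx],
      extremum_index = idx,
      extremum_value = extremum,
      baseline_value = baseline,
      half_level = baseline + (extremum - baseline) / 2,
      sign = sign,
      smoothing_window_px = config$smoothing_window_px
    ), class = "wall_lobe")
  }
  idx <- sort(pair$idx)
  list(make_lobe(idx[1L], "left"), make_lobe(idx[2L], "right"))
}

#' Half-maximum crossings of a wall lobe
#'
#' Walks outward from the lobe's peak on each side until a sample interval
#' straddles the half level, then locates the crossing by linear
#' interpolation between the two straddling samples.
#'
#' @param profile the [intensity_profile()] the lobe was detected in.
#' @param lobe a `wall_lobe` from [detect_wall_lobes()].
#' @return numeric `c(left_crossing, right_crossing)` in sub-pixel positions.
#' @export
half_max_crossings <- function(profile, lobe) {
  stopifnot(inherits(profile, "intensity_profile"), inherits(lobe, "wall_lobe"))
  s <- lobe$sign * moving_average(profile$intensities, lobe$smoothing_window_px)
  pos <- profile$positions
  i0 <- lobe$extremum_index
  half <- lobe$half_level

  cross_at <- function(j) {
    # crossing inside [j, j + 1]
    t <- (half - s[j]) / (s[j + 1L] - s[j])
    pos[j] + t * (pos[j + 1L] - pos[j])
  }
  left <- NA_real_
  j <- i0
  while (j > 1L) {
    if (s[j - 1L] <= half && s[j] >= half) { left <- cross_at(j - 1L); break }
    j <- j - 1L
  }
  if (is.na(left)) stop("open lobe: half level never crossed on the left", call. = FALSE)
  right <- NA_real_
  j <- i0
  n <- length(s)
  while (j < n) {
    if (s[j] >= half && s[j + 1L] <= half) { right <- cross_at(j); break }
    j <- j + 1L
  }
  if (is.na(right)) stop("open lobe: half level never crossed on the right", call. = FALSE)
  c(left, right)
}

#' Measure a vessel's outer and lumen diameters by FWHM densitometry
#'
#' Runs lobe detection and half-maximum localization, orders the four
#' boundary crossings, and converts pixel distances to micrometres with the
#' scale calibration: outer diameter from the outer crossings of the two wall
#' lobes, lumen diameter from the inner crossings.
#'
#' @param profile an [intensity_profile()].
#' @param calib a [scale_calibration()].
#' @param config a [densitometry_config()].
#' @return object of class `vessel_measurement` with elements `raod_um`,
#'   `rald_um`, `boundaries_px` (outer_left, inner_left, inner_right,
#'   outer_right), `lobes`, `calib`, `config`, `profile`.
#' @examples
#' spec <- vessel_phantom_spec(130, 97)
#' prof <- generate_vessel_profile(spec, seed = 1)$profile
#' m <- measure_vessel(prof, calibrate_scale(200))
#' coef(m)
#' @export
measure_vessel <- function(profile, calib, config = densitometry_config()) {
  stopifnot(inherits(calib, "scale_calibration"))
  lobes <- detect_wall_lobes(profile, config)
  cl <- half_max_crossings(profile, lobes[[1L]])
  cr <- half_max_crossings(profile, lobes[[2L]])
  b <- c(outer_left = cl[1L], inner_left = cl[2L],
         inner_right = cr[1L], outer_right = cr[2L])
  if (any(diff(b) <= 0)) {
    stop("inconsistent boundaries: crossings are not strictly ordered", call. = FALSE)
  }
  raod <- (b[["outer_right"]] - b[["outer_left"]]) * calib$um_per_px
  rald <- (b[["inner_right"]] - b[["inner_left"]]) * calib$um_per_px
  if (!(raod > rald && rald > 0)) {
    stop("inconsistent boundaries: outer diameter must exceed lumen diameter", call. = FALSE)
  }
  structure(list(
    raod_um = raod, rald_um = rald,
    boundaries_px = b, lobes = lobes,
    calib = calib, config = config, profile = profile
  ), class = "vessel_measurement")
}

#' @export
coef.vessel_measurement <- function(object, ...) {
  c(raod_um = object$raod_um, rald_um = object$rald_um)
}

#' @export
print.vessel_measurement <- function(x, ...) {
  cat("FWHM vessel measurement\n")
  cat(sprintf("  outer diameter (RAOD): %8.2f um\n", x$raod_um))
  cat(sprintf("  lumen diameter (RALD): %8.2f um\n", x$rald_um))
  cat(sprintf("  boundaries (px): %s\n",
              paste(sprintf("%.2f", x$boundaries_px), collapse = ", ")))
  cat(sprintf("  scale: %.4f um/px\n", x$calib$um_per_px))
  invisible(x)
}

#' Plot a measured profile with its boundaries
#'
#' @param x a `vessel_measurement`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vessel_measurement <- function(x, ...) {
  graphics::plot(x$profile$positions, x$profile$intensities, type = "l",
                 xlab = "position (px)", ylab = "intensity", ...)
  graphics::abline(v = x$boundaries_px, col = "red", lty = 2)
  for (lobe in x$lobes) {
    graphics::abline(h = lobe$sign * lobe$half_level, col = "grey60", lty = 3)
  }
  invisible(x)
}

#' Read / write a profile CSV (position_px, intensity)
#'
#' @param path CSV file path.
#' @return [intensity_profile()] for the reader; invisible path for the
#'   writer.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("position_px", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("profile CSV missing columns: %s", paste(miss, collapse = ", ")), call. = FALSE)
  intensity_profile(df$position_px, df$intensity)
}

#' @param profile an [intensity_profile()].
#' @rdname read_profile_csv
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  utils::write.csv(data.frame(position_px = profile$positions,
                              intensity = profile$intensities),
                   path, row.names = FALSE)
  invisible(path)
}
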