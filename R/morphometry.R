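# Derived arterial morphometry: wall thickness, wall-to-lumen ratio and wall
# cross-sectional area from outer/lumen diameter pairs, duplicate averaging,
# and aggregation of the largest arteries into one value set per eye.

#' Arterial wall thickness from outer and lumen diameters
#'
#' `AWT = (RAOD - RALD) / 2`, i.e. one wall's thickness assuming a concentric
#' annulus.
#'
#' @param raod_um outer diameter, um.
#' @param rald_um lumen diameter, um; must satisfy `0 < rald_um < raod_um`.
#' @return wall thickness in um (vectorized).
#' @examples
#' compute_awt(130.71, 97.21)  # 16.75
#' @export
compute_awt <- function(raod_um, rald_um) {
  check_diameter_pair(raod_um, rald_um)
  (raod_um - rald_um) / 2
}

#' Wall-to-lumen ratio
#'
#' `WLR = (RAOD - RALD) / RALD`, a dimensionless marker of vascular
#' remodeling (equals `2 * AWT / RALD`).
#'
#' @inheritParams compute_awt
#' @return dimensionless ratio (vectorized).
#' @examples
#' compute_wlr(135.76, 100.38)  # 0.3525
#' @export
compute_wlr <- function(raod_um, rald_um) {
  check_diameter_pair(raod_um, rald_um)
  (raod_um - rald_um) / rald_um
}

#' Wall cross-sectional area
#'
#' `WCSA = (pi / 4) * (RAOD^2 - RALD^2)`, the annulus area between outer and
#' lumen circles (equals `pi * AWT * (RALD + AWT)`).
#'
#' @inheritParams compute_awt
#' @return area in um^2 (vectorized).
#' @export
compute_wcsa <- function(raod_um, rald_um) {
  check_diameter_pair(raod_um, rald_um)
  (pi / 4) * (raod_um^2 - rald_um^2)
}

check_diameter_pair <- function(raod_um, rald_um) {
  if (length(raod_um) != length(rald_um)) {
    stop("`raod_um` and `rald_um` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(raod_um)) || !all(is.finite(rald_um))) {
    stop("diameters must be finite", call. = FALSE)
  }
  if (any(rald_um <= 0) || any(raod_um <= rald_um)) {
    stop("diameter ordering violated: need raod_um > rald_um > 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Average duplicate diameter measurements
#'
#' Component-wise arithmetic mean of two repeat measurements of the same
#' vessel. The mean preserves the `raod > rald > 0` ordering whenever both
#' inputs satisfy it.
#'
#' @param repeat_a,repeat_b named numeric vectors with elements `raod_um` and
#'   `rald_um` (as returned by [coef.vessel_measurement()]).
#' @return named numeric vector `c(raod_um, rald_um)`.
#' @export
average_repeats <- function(repeat_a, repeat_b) {
  a <- as_pair(repeat_a, "repeat_a")
  b <- as_pair(repeat_b, "repeat_b")
  check_diameter_pair(a[["raod_um"]], a[["rald_um"]])
  check_diameter_pair(b[["raod_um"]], b[["rald_um"]])
  c(raod_um = (a[["raod_um"]] + b[["raod_um"]]) / 2,
    rald_um = (a[["rald_um"]] + b[["rald_um"]]) / 2)
}

as_pair <- function(x, name) {
  if (!is.numeric(x) || !all(c("raod_um", "rald_um") %in% names(x))) {
    stop(sprintf("`%s` must be a named numeric vector with raod_um and rald_um", name),
         call. = FALSE)
  }
  x[c("raod_um", "rald_um")]
}

#' Aggregate vessels into per-eye morphometry
#'
#' Selects the `n_largest` vessels by outer diameter (all vessels if fewer;
#' ties keep input order), computes per-vessel AWT, WLR and WCSA from the
#' duplicate-averaged diameters, then takes arithmetic means of RAOD, RALD,
#' AWT, WLR and WCSA across the selected vessels.
#'
#' With `derived = "from-mean-diameters"` the three derived parameters are
#' instead recomputed from the per-eye mean RAOD/RALD. The two conventions
#' agree for AWT (a linear statistic) but differ in general for WLR and WCSA.
#'
#' @param vessels data frame with columns `raod_um`, `rald_um` (one row per
#'   vessel, duplicate-averaged); optional `vessel_id`.
#' @param n_largest number of largest arteries to keep (default 4).
#' @param derived how per-eye WLR/WCSA are formed: mean of per-vessel values
#'   (default) or recomputed from mean diameters.
#' @return one-row data frame with `raod_um`, `rald_um`, `awt_um`, `wlr`,
#'   `wcsa_um2`, `n_vessels`.
#' @export
aggregate_eye <- function(vessels, n_largest = 4L,
                          derived = c("per-vessel", "from-mean-diameters")) {
  derived <- match.arg(derived)
  if (!is.data.frame(vessels) || nrow(vessels) == 0L) {
    stop("`vessels` must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("raod_um", "rald_um") %in% names(vessels))) {
    stop("`vessels` needs `raod_um` and `rald_um` columns", call. = FALSE)
  }
  if (n_largest < 1L) stop("`n_largest` must be >= 1", call. = FALSE)
  check_diameter_pair(vessels$raod_um, vessels$rald_um)
  keep <- order(-vessels$raod_um)[seq_len(min(n_largest, nrow(vessels)))]
  sel <- vessels[keep, , drop = FALSE]
  raod <- mean(sel$raod_um)
  rald <- mean(sel$rald_um)
  if (derived == "per-vessel") {
    awt <- mean(compute_awt(sel$raod_um, sel$rald_um))
    wlr <- mean(compute_wlr(sel$raod_um, sel$rald_um))
    wcsa <- mean(compute_wcsa(sel$raod_um, sel$rald_um))
  } else {
    awt <- compute_awt(raod, rald)
    wlr <- compute_wlr(raod, rald)
    wcsa <- compute_wcsa(raod, rald)
  }
  data.frame(raod_um = raod, rald_um = rald, awt_um = awt, wlr = wlr,
             wcsa_um2 = wcsa, n_vessels = nrow(sel))
}

#' Per-eye morphometry from a long repeat-measurement table
#'
#' Averages the two repeats of every vessel, then aggregates each eye's
#' largest arteries with [aggregate_eye()].
#'
#' @param measurements long data frame with columns `eye_id`, `vessel_id`,
#'   `session` (two sessions per vessel), `raod_um`, `rald_um`.
#' @inheritParams aggregate_eye
#' @return data frame with one row per eye.
#' @export
morphometry_by_eye <- function(measurements, n_largest = 4L,
                               derived = c("per-vessel", "from-mean-diameters")) {
  derived <- match.arg(derived)
  need <- c("eye_id", "vessel_id", "session", "raod_um", "rald_um")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop(sprintf("measurement table missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  per_vessel <- stats::aggregate(
    measurements[c("raod_um", "rald_um")],
    by = measurements[c("eye_id", "vessel_id")],
    FUN = mean
  )
  eyes <- split(per_vessel, per_vessel$eye_id)
  out <- do.call(rbind, lapply(names(eyes), function(id) {
    cbind(data.frame(eye_id = id, stringsAsFactors = FALSE),
          aggregate_eye(eyes[[id]], n_largest = n_largest, derived = derived))
  }))
  rownames(out) <- NULL
  out
}
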