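# SDS-PAGE apparent molecular weight calibration: second-order polynomial
# fit of log10(MW) against marker migration distance, the standard way gel
# apparent MWs are interpolated from a ladder.

#' Calibrate a gel from a marker ladder
#'
#' Least-squares quadratic fit of `log10(MW)` on migration distance
#' (direct-prediction direction, so [apparent_mw()] needs no
#' root-finding). Markers lying exactly on a quadratic are recovered to
#' machine precision. With `direction = "distance_on_logmw"` the reverse
#' fit is available.
#'
#' @param markers data.frame with columns `mw_kda` and `distance` (>= 3
#'   markers with distinct distances). For a valid gel the distances are
#'   monotone in MW; a violation is reported as a warning, not an error.
#' @param direction `"logmw_on_distance"` (default) or
#'   `"distance_on_logmw"`.
#' @return An object of class `gel_calibration`: `coefficients`
#'   (intercept, linear, quadratic), `residuals`, `markers`, `direction`.
#' @examples
#' ladder <- data.frame(mw_kda = c(250, 150, 100, 75, 50, 37, 25, 20, 15),
#'                      distance = 1:9)
#' cal <- gel_calibrate(ladder)
#' apparent_mw(cal, 4.5)
#' @export
gel_calibrate <- function(markers, direction = c("logmw_on_distance", "distance_on_logmw")) {
  direction <- match.arg(direction)
  if (!is.data.frame(markers) || !all(c("mw_kda", "distance") %in% names(markers))) {
    stop("markers must be a data.frame with columns mw_kda and distance", call. = FALSE)
  }
  if (nrow(markers) < 3L) stop("need at least 3 markers", call. = FALSE)
  if (anyDuplicated(markers$distance)) stop("marker distances must be distinct", call. = FALSE)
  if (any(markers$mw_kda <= 0)) stop("marker MWs must be positive", call. = FALSE)
  o <- order(markers$distance)
  if (is.unsorted(rev(markers$mw_kda[o])) && is.unsorted(markers$mw_kda[o])) {
    warning("marker MWs are not monotone in migration distance; gel may be invalid")
  }
  lmw <- log10(markers$mw_kda)
  fit <- if (direction == "logmw_on_distance") {
    stats::lm(lmw ~ distance + I(distance^2), data = data.frame(lmw = lmw, distance = markers$distance))
  } else {
    stats::lm(distance ~ lmw + I(lmw^2), data = data.frame(lmw = lmw, distance = markers$distance))
  }
  structure(list(coefficients = unname(stats::coef(fit)),
                 residuals = unname(stats::residuals(fit)),
                 markers = markers[o, ], direction = direction),
            class = "gel_calibration")
}

#' Apparent molecular weight of a band
#'
#' Evaluates the calibration at a migration distance:
#' `10^(c0 + c1*d + c2*d^2)` for the direct fit, or the quadratic root
#' inside the ladder range for the reverse fit.
#'
#' @param cal A [gel_calibrate()] result.
#' @param distance Migration distance(s) of the band(s).
#' @return Apparent MW(s) in kDa.
#' @export
apparent_mw <- function(cal, distance) {
  stopifnot(inherits(cal, "gel_calibration"))
  cf <- cal$coefficients
  if (cal$direction == "logmw_on_distance") {
    return(10^(cf[1] + cf[2] * distance + cf[3] * distance^2))
  }
  vapply(distance, function(d) {
    roots <- polyroot(c(cf[1] - d, cf[2], cf[3]))
    re <- Re(roots)[abs(Im(roots)) < 1e-8]
    lrange <- range(log10(cal$markers$mw_kda))
    pick <- re[re >= lrange[1] - 1 & re <= lrange[2] + 1]
    if (!length(pick)) stop("no calibration root near the ladder range", call. = FALSE)
    10^pick[1]
  }, 0)
}
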