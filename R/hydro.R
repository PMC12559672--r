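#' Inundation duration of a patch
#'
#' Number of days within the window on which the water level strictly
#' exceeds the patch elevation (ties count as dry). The default window is
#' 1 September to 30 November of the first September the series covers.
#'
#' @param h a [hydro_series()].
#' @param elevation patch elevation (m).
#' @param window length-2 Date vector (start, end); must lie within the
#'   series.
#' @return integer number of inundated days.
#' @export
inundation_duration <- function(h, elevation, window = NULL) {
  stopifnot(inherits(h, "hydro_series"))
  if (is.null(window)) {
    yrs <- unique(format(h$dates, "%Y"))
    sept <- yrs[vapply(yrs, function(y)
      as.Date(paste0(y, "-09-01")) %in% h$dates, logical(1L))]
    if (length(sept) == 0L) {
      stop("series does not cover a 1 September; give an explicit window",
           call. = FALSE)
    }
    window <- as.Date(paste0(sept[1L], c("-09-01", "-11-30")))
  }
  window <- as.Date(window)
  if (window[1L] < min(h$dates) || window[2L] > max(h$dates)) {
    stop("window extends outside the water-level series", call. = FALSE)
  }
  sel <- h$dates >= window[1L] & h$dates <= window[2L]
  sum(h$levels[sel] > elevation)
}

#' Classify inundation duration
#'
#' Under 20 days is class InD1, 20 to 70 days (inclusive) is InD2, longer
#' durations fall outside the two short-inundation classes ("Other").
#'
#' @param days non-negative integer day count.
#' @return one of "InD1", "InD2", "Other".
#' @export
classify_inundation <- function(days) {
  if (any(days < 0)) stop("negative duration", call. = FALSE)
  ifelse(days < 20, "InD1", ifelse(days <= 70, "InD2", "Other"))
}

#' Regime thresholds for October water-level classification
#'
#' Offsets (m) from the long-term reference mean separating extreme drought
#' (ED), early recession (ER) and late recession (LR) from a normal
#' recession (NR).
#'
#' @param ed_offset metres below reference for ED (default 4).
#' @param er_offset metres below reference for ER (default 1).
#' @param lr_offset metres above reference for LR (default 1).
#' @return list of the three offsets.
#' @export
regime_thresholds <- function(ed_offset = 4, er_offset = 1, lr_offset = 1) {
  if (!(ed_offset > er_offset && er_offset > 0 && lr_offset > 0)) {
    stop("need ed_offset > er_offset > 0 and lr_offset > 0", call. = FALSE)
  }
  list(ed_offset = ed_offset, er_offset = er_offset, lr_offset = lr_offset)
}

#' Classify the hydrological regime of a winter from its October levels
#'
#' The mean daily October water level m is compared with a long-term
#' reference mean: m <= ref - ed_offset is extreme drought (ED);
#' below ref - er_offset is early recession (ER); at or above
#' ref + lr_offset is late recession (LR); otherwise normal recession (NR).
#'
#' @param h a [hydro_series()] covering October.
#' @param reference_mean long-term mean October level (m).
#' @param thresholds a [regime_thresholds()] list.
#' @return one of "ED", "ER", "LR", "NR".
#' @export
classify_regime <- function(h, reference_mean,
                            thresholds = regime_thresholds()) {
  stopifnot(inherits(h, "hydro_series"))
  oct <- format(h$dates, "%m") == "10"
  if (!any(oct)) stop("series has no October days", call. = FALSE)
  m <- mean(h$levels[oct])
  if (m <= reference_mean - thresholds$ed_offset) "ED"
  else if (m <= reference_mean - thresholds$er_offset) "ER"
  else if (m >= reference_mean + thresholds$lr_offset) "LR"
  else "NR"
}

#' Shoreline-development shape index
#'
#' SI = L / (2 * sqrt(pi * A)): the ratio of a wetland's perimeter to the
#' perimeter of a circle with the same area, so a circular lake scores 1
#' and more convoluted shorelines score higher. (Printed renderings of this
#' formula often drop the root; the circle-normalized form is used here.)
#'
#' @param perimeter shoreline length L (km), positive.
#' @param area wetland area A (km^2), positive.
#' @return shape index >= 1 up to measurement noise.
#' @export
shape_index <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0)) {
    stop("perimeter and area must be positive", call. = FALSE)
  }
  perimeter / (2 * sqrt(pi * area))
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - R) / (NIR + R) from near-infrared and red reflectance.
#'
#' @param nir near-infrared reflectance.
#' @param red visible red reflectance; `nir + red` must be positive.
#' @return NDVI in \[-1, 1\].
#' @export
ndvi <- function(nir, red) {
  if (any(nir + red <= 0)) {
    stop("NDVI undefined: nir + red must be positive", call. = FALSE)
  }
  (nir - red) / (nir + red)
}
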