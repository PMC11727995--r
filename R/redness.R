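#' Red-membership parameters
#'
#' "Close to red" is a fuzzy notion: membership is 1 inside a hue window
#' around red, falls linearly to 0 on the circular hue distance between
#' `hue_full_deg` and `hue_zero_deg`, and is gated to 0 for washed-out or
#' dark pixels (low saturation or value), which separates erythema from pale
#' skin tones and shadows.
#'
#' @param hue_center_deg centre of the red hue window, degrees.
#' @param hue_full_deg half-width of the membership-1 hue window, degrees.
#' @param hue_zero_deg half-width of the membership support, degrees.
#' @param min_saturation,min_value gates below which membership is 0.
#' @return A `red_membership_params` list.
#' @export
red_membership_params <- function(hue_center_deg = 0, hue_full_deg = 10,
                                  hue_zero_deg = 30,
                                  min_saturation = 0.25, min_value = 0.2) {
  stopifnot(hue_full_deg >= 0, hue_full_deg <= hue_zero_deg,
            hue_zero_deg <= 180,
            min_saturation >= 0, min_saturation <= 1,
            min_value >= 0, min_value <= 1)
  structure(list(hue_center_deg = hue_center_deg,
                 hue_full_deg = hue_full_deg, hue_zero_deg = hue_zero_deg,
                 min_saturation = min_saturation, min_value = min_value),
            class = "red_membership_params")
}

#' Degree to which an HSV pixel is "close to red"
#'
#' Vectorised trapezoidal membership on the circular hue distance to
#' `hue_center_deg`, gated by minimum saturation and value.
#'
#' @param hue,sat,val HSV components (hue in degrees, sat/val in \[0, 1\]);
#'   recycled to a common length.
#' @param params a [red_membership_params()].
#' @return Membership degree(s) in \[0, 1\].
#' @export
#' @examples
#' red_membership(0, 1, 1)     # pure red -> 1
#' red_membership(20, 1, 1)    # on the ramp -> 0.5
#' red_membership(240, 1, 1)   # blue -> 0
red_membership <- function(hue, sat, val, params = red_membership_params()) {
  d <- abs(hue - params$hue_center_deg) %% 360
  d <- pmin(d, 360 - d)
  mem <- ifelse(d <= params$hue_full_deg, 1,
         ifelse(d >= params$hue_zero_deg, 0,
                (params$hue_zero_deg - d) /
                  (params$hue_zero_deg - params$hue_full_deg)))
  mem[sat < params$min_saturation | val < params$min_value] <- 0
  mem
}

#' Redness proportion over the wound region of interest
#'
#' The image-level infection score: the fraction of ROI pixels whose colour
#' is close to red. `"crisp"` (the default) counts pixels with membership at
#' least 0.5; `"weighted"` averages the membership degrees.
#'
#' @param image a [wound_image()].
#' @param roi H x W logical (or 0/1) ROI mask, non-empty.
#' @param params a [red_membership_params()].
#' @param method `"crisp"` or `"weighted"`.
#' @return A `redness_result` with `proportion`, `roi_pixel_count`,
#'   `method`; `threshold` and `positive` are filled by
#'   [classify_redness()].
#' @export
redness_proportion <- function(image, roi, params = red_membership_params(),
                               method = c("crisp", "weighted")) {
  method <- match.arg(method)
  stopifnot(inherits(image, "wound_image"))
  roi <- matrix(as.logical(roi), nrow(roi), ncol(roi))
  if (!all(dim(roi) == dim(image)[1:2])) stop("ROI shape must match image")
  n <- sum(roi)
  if (n < 1) stop("empty ROI")
  hsv <- to_hsv(image)
  mem <- red_membership(hsv[, , 1][roi], hsv[, , 2][roi], hsv[, , 3][roi],
                        params)
  p <- if (method == "crisp") mean(mem >= 0.5) else mean(mem)
  structure(list(proportion = p, threshold = NA_real_, positive = NA,
                 roi_pixel_count = n, method = method),
            class = "redness_result")
}

#' Classify an image-level redness score against the infection cutoff
#'
#' The default cutoff 0.63 is the study calibration constant for the red
#' proportion; it was fitted by ROC analysis on the original cohort and
#' should be recalibrated (see [roc_and_cutoff()]) for other imaging
#' settings. Ties count positive — the screen is sensitivity-first.
#'
#' @param x a `redness_result` from [redness_proportion()], or a bare
#'   proportion in \[0, 1\].
#' @param threshold cutoff in \[0, 1\].
#' @return For a `redness_result` input, the completed result; for a bare
#'   proportion, a logical.
#' @export
#' @examples
#' classify_redness(0.70)         # TRUE
#' classify_redness(0.63)         # tie -> TRUE
#' classify_redness(0.50)         # FALSE
classify_redness <- function(x, threshold = 0.63) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a number in [0, 1]")
  if (inherits(x, "redness_result")) {
    x$threshold <- threshold
    x$positive <- x$proportion >= threshold
    return(x)
  }
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop("proportion must lie in [0, 1]")
  x >= threshold
}

#' @export
print.redness_result <- function(x, ...) {
  cat(sprintf("<redness_result> proportion %.4f over %d ROI px (%s)",
              x$proportion, x$roi_pixel_count, x$method))
  if (!is.na(x$threshold))
    cat(sprintf("; threshold %.2f -> %s", x$threshold,
                if (x$positive) "POSITIVE" else "negative"))
  cat("\n")
  invisible(x)
}
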