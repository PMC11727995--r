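#' Wound photograph container
#'
#' A `wound_image` is an H x W x 3 numeric array of RGB intensities in
#' \[0, 1\] (rows = image rows, columns = image columns) carrying a source
#' identifier and an optional capture tag. The study protocol that this
#' pipeline models required uploads of at least 500 x 500 pixels; smaller
#' images are accepted but flagged, since the size floor was a device
#' inclusion criterion rather than an algorithmic requirement.
#'
#' @param pixels numeric H x W x 3 array with values in \[0, 1\].
#' @param source_id opaque identifier string (never a patient name).
#' @param capture_tag optional free-text capture note.
#' @param warn_undersized emit a warning for images below 500 x 500
#'   (default); the flag is recorded either way.
#'
#' @return A `wound_image` object with attributes `source_id`, `capture_tag`
#'   and logical `undersized` (TRUE when `min(H, W) < 500`).
#' @export
#' @examples
#' img <- wound_image(array(0.5, c(8, 8, 3)), source_id = "demo",
#'                    warn_undersized = FALSE)
#' dim(img)
wound_image <- function(pixels, source_id = "unknown", capture_tag = NULL,
                        warn_undersized = TRUE) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (!is.numeric(pixels) || anyNA(pixels))
    stop("`pixels` must be numeric without NA")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("channel values must lie in [0, 1]")
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < 1 || w < 1) stop("image must have at least one pixel")
  undersized <- min(h, w) < 500
  if (undersized && warn_undersized)
    warning(sprintf("image %s is %dx%d, below the recommended 500x500 minimum",
                    source_id, h, w), call. = FALSE)
  structure(pixels,
            source_id = as.character(source_id),
            capture_tag = capture_tag,
            undersized = undersized,
            class = c("wound_image", "array"))
}

#' @export
print.wound_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<wound_image> %d x %d px, source_id = \"%s\"%s\n",
              d[1], d[2], attr(x, "source_id"),
              if (isTRUE(attr(x, "undersized"))) " [undersized]" else ""))
  invisible(x)
}

#' @export
plot.wound_image <- function(x, ...) {
  op <- par(mar = c(0.5, 0.5, 1.5, 0.5)); on.exit(par(op))
  plot.new()
  plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = dim(x)[1] / dim(x)[2])
  rasterImage(unclass(x), 0, 0, 1, 1, ...)
  invisible(x)
}

#' Read a wound photograph from PNG or JPEG
#'
#' 8-bit channels are scaled to \[0, 1\]; grayscale files are replicated to
#' three channels and an alpha channel, if present, is dropped.
#'
#' @param path file path to a PNG or JPEG image.
#' @param source_id identifier recorded on the image; defaults to the file
#'   name without extension.
#' @return A [wound_image()].
#' @export
read_wound_image <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)          # x (col) major: W x H x C
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
  else px <- array(px[, , 1L], c(dim(px)[1:2], 3L))
  px <- aperm(px, c(2, 1, 3))            # to H x W x 3
  px[px < 0] <- 0; px[px > 1] <- 1
  if (is.null(source_id))
    source_id <- sub("\\.[^.]+$", "", basename(path))
  wound_image(px, source_id = source_id)
}

#' Write a wound image (or a binary mask) to PNG/JPEG
#'
#' @param x a [wound_image()] or an H x W numeric/logical matrix (masks are
#'   written as single-channel 0/255 PNG).
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_wound_image <- function(x, path) {
  if (is.matrix(x)) {
    dat <- t(x * 1)
    img <- EBImage::Image(dat, colormode = "Grayscale")
  } else {
    img <- EBImage::Image(aperm(unclass(x), c(2, 1, 3)), colormode = "Color")
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Convert a wound image to HSV
#'
#' Hue is reported in degrees in \[0, 360); achromatic pixels (saturation 0)
#' take hue 0 by convention, which makes "hue distance to red" well defined
#' for every pixel.
#'
#' @param image a [wound_image()].
#' @return An H x W x 3 array with slices `hue` (degrees), `sat`, `val`.
#' @export
#' @examples
#' img <- wound_image(array(c(1, 0, 0), c(1, 1, 3)), "px")
#' to_hsv(img)[1, 1, ]  # pure red: hue 0, sat 1, val 1
to_hsv <- function(image) {
  stopifnot(inherits(image, "wound_image"))
  d <- dim(image)
  m <- matrix(unclass(image), ncol = 3L)    # pixels x RGB
  hsv <- rgb2hsv(t(m), maxColorValue = 1)   # 3 x pixels, h in [0,1)
  out <- array(0, c(d[1], d[2], 3L), dimnames = list(NULL, NULL, c("hue", "sat", "val")))
  out[, , 1] <- (hsv[1, ] * 360) %% 360
  out[, , 2] <- hsv[2, ]
  out[, , 3] <- hsv[3, ]
  out[, , 1][out[, , 2] == 0] <- 0          # achromatic convention
  out
}
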