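#' Staple detection parameters
#'
#' Staples are modelled as the brightest thin elongated structures in the
#' photograph: a fuzzy white top-hat removes everything wide enough to
#' contain the structuring element, and the surviving components are kept if
#' they are bright, of plausible area, and elongated.
#'
#' @param se_size odd side of the flat square structuring element; must
#'   exceed the staple width (px).
#' @param brightness_threshold minimum top-hat response for a pixel to count
#'   as staple candidate.
#' @param min_area,max_area component area bounds in pixels; `NULL` scales
#'   them to the image (`max(15, 4e-5 * H * W)` and `5e-3 * H * W`).
#' @param min_elongation minimum major/minor axis ratio of a component.
#' @param max_saturation maximum median HSV saturation of a component:
#'   metallic staples are near-achromatic, which rejects bright but
#'   skin-coloured slivers (e.g. skin between two antiseptic stains).
#' @param roi_halfwidth half-width of the peri-wound band in px; `NULL`
#'   uses twice the median staple length.
#' @param logic a [fuzzy_logic_pair()] for the morphology.
#' @return A `staple_detect_params` list.
#' @export
staple_detect_params <- function(se_size = 7,
                                 brightness_threshold = 0.08,
                                 min_area = NULL, max_area = NULL,
                                 min_elongation = 2.5,
                                 max_saturation = 0.35,
                                 roi_halfwidth = NULL,
                                 logic = fuzzy_logic_pair("godel")) {
  stopifnot(se_size >= 3, se_size %% 2 == 1,
            brightness_threshold > 0, brightness_threshold < 1,
            min_elongation >= 1,
            max_saturation >= 0, max_saturation <= 1)
  structure(list(se_size = se_size,
                 brightness_threshold = brightness_threshold,
                 min_area = min_area, max_area = max_area,
                 min_elongation = min_elongation,
                 max_saturation = max_saturation,
                 roi_halfwidth = roi_halfwidth,
                 logic = logic),
            class = "staple_detect_params")
}

# centroid, area, axis lengths and orientation of labelled components;
# second moments carry the 1/12 single-pixel correction so 1-px-wide lines
# have a finite minor axis
component_features <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0L) return(NULL)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  n <- as.vector(rowsum(rep(1, length(idx)), lab))
  ids <- sort(unique(lab))
  mr <- as.vector(rowsum(rr, lab)) / n
  mc <- as.vector(rowsum(cc, lab)) / n
  vrr <- as.vector(rowsum(rr^2, lab)) / n - mr^2 + 1 / 12
  vcc <- as.vector(rowsum(cc^2, lab)) / n - mc^2 + 1 / 12
  vrc <- as.vector(rowsum(rr * cc, lab)) / n - mr * mc
  tr <- vrr + vcc
  det_ <- vrr * vcc - vrc^2
  disc <- pmax(0, tr^2 / 4 - det_)
  l1 <- tr / 2 + sqrt(disc)        # major eigenvalue
  l2 <- pmax(tr / 2 - sqrt(disc), 1e-9)
  # orientation of the major axis, from the column axis, in [0, 180)
  ang <- (atan2(2 * vrc, vcc - vrr) / 2) * 180 / pi
  ang <- ifelse(abs(vrc) < 1e-12 & vrr > vcc, 90, ang) %% 180
  data.frame(id = ids, area = n,
             centroid_row = mr, centroid_col = mc,
             length_px = sqrt(12 * l1),       # full extent of a uniform bar
             elongation = sqrt(l1 / l2),
             orientation_deg = ang)
}

#' Locate staples and the wound in a photograph
#'
#' Computes the fuzzy white top-hat of the brightness (value) channel,
#' thresholds it, labels connected components (row-major label order, so the
#' result is deterministic), filters them by area and elongation, and — when
#' at least two staples are found — fits the wound axis through the staple
#' centroids and builds the peri-wound region of interest around it.
#'
#' @param image a [wound_image()].
#' @param params a [staple_detect_params()].
#' @return A `staple_detection` list: `staple_mask` (H x W logical),
#'   `components` (data frame of centroid, area, length, orientation,
#'   elongation), `wound_axis` (list `point`, `direction` or `NULL`),
#'   `roi_mask` (logical or `NULL`), and `params`.
#' @export
detect_staples <- function(image, params = staple_detect_params()) {
  stopifnot(inherits(image, "wound_image"))
  h <- dim(image)[1]; w <- dim(image)[2]
  if (params$se_size > min(h, w)) stop("image smaller than structuring element")
  min_area <- if (is.null(params$min_area)) max(15, 4e-5 * h * w) else params$min_area
  max_area <- if (is.null(params$max_area)) 5e-3 * h * w else params$max_area

  val <- pmax(image[, , 1], image[, , 2], image[, , 3])
  th <- fuzzy_tophat(val, se_square(params$se_size), params$logic)
  cand <- th >= params$brightness_threshold

  labels <- t(EBImage::bwlabel(t(cand * 1)))   # EBImage is column-major
  feats <- component_features(labels)
  keep <- integer(0)
  if (!is.null(feats)) {
    cand_ids <- feats$id[feats$area >= min_area & feats$area <= max_area &
                         feats$elongation >= params$min_elongation]
    if (length(cand_ids)) {   # saturation gate only for surviving components
      mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
      sat <- ifelse(val > 0, (val - mn) / val, 0)
      in_cand <- labels %in% cand_ids
      med_sat <- vapply(split(sat[in_cand], labels[in_cand]), median,
                        numeric(1))
      keep <- cand_ids[med_sat[as.character(cand_ids)] <= params$max_saturation]
    }
    feats <- feats[feats$id %in% keep, , drop = FALSE]
    # deterministic row-major component order
    ord <- order(feats$centroid_row, feats$centroid_col)
    feats <- feats[ord, , drop = FALSE]
    feats$id <- NULL
    rownames(feats) <- NULL
  } else {
    feats <- data.frame(area = numeric(0), centroid_row = numeric(0),
                        centroid_col = numeric(0), length_px = numeric(0),
                        elongation = numeric(0), orientation_deg = numeric(0))
  }
  mask <- matrix(labels %in% keep, h, w)

  axis <- NULL; roi <- NULL
  if (nrow(feats) >= 2) {
    axis <- estimate_wound_axis(cbind(feats$centroid_row, feats$centroid_col))
    halfwidth <- if (is.null(params$roi_halfwidth))
      2 * median(feats$length_px) else params$roi_halfwidth
    # clip the band along the axis to the staple span plus one half-width,
    # so the ROI follows the incision instead of crossing the whole frame
    proj <- (feats$centroid_row - axis$point[1]) * axis$direction[1] +
            (feats$centroid_col - axis$point[2]) * axis$direction[2]
    axial <- max(abs(proj)) + halfwidth
    roi <- wound_roi(axis, halfwidth, c(h, w), axial_halflength = axial)
  }
  structure(list(staple_mask = mask, components = feats,
                 wound_axis = axis, roi_mask = roi,
                 params = list(se_size = params$se_size,
                               brightness_threshold = params$brightness_threshold,
                               min_area = min_area, max_area = max_area,
                               min_elongation = params$min_elongation,
                               max_saturation = params$max_saturation,
                               logic = params$logic$name)),
            class = "staple_detection")
}

#' @export
print.staple_detection <- function(x, ...) {
  cat(sprintf("<staple_detection> %d staple component(s)\n", nrow(x$components)))
  if (!is.null(x$wound_axis))
    cat(sprintf("  wound axis through (%.1f, %.1f), direction (%.3f, %.3f); ROI %d px\n",
                x$wound_axis$point[1], x$wound_axis$point[2],
                x$wound_axis$direction[1], x$wound_axis$direction[2],
                sum(x$roi_mask)))
  else cat("  wound axis undeterminable (< 2 staples)\n")
  invisible(x)
}

#' Total-least-squares wound axis through staple centroids
#'
#' Staples straddle the incision, so their centroids lie on the wound line.
#' The axis is the first principal component of the centroid scatter
#' (orthogonal regression); the direction is normalised so its first nonzero
#' component is positive, for determinism.
#'
#' @param centroids numeric matrix with columns `(row, col)`, at least two
#'   rows.
#' @return List with `point` (the centroid mean) and unit `direction`
#'   `(d_row, d_col)`.
#' @export
estimate_wound_axis <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) stop("axis undeterminable: fewer than 2 centroids")
  ctr <- colMeans(centroids)
  x <- sweep(centroids, 2, ctr)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  d <- ev$vectors[, 1]
  nz <- which(abs(d) > 1e-12)[1]
  if (d[nz] < 0) d <- -d
  list(point = as.numeric(ctr), direction = as.numeric(d / sqrt(sum(d^2))))
}

#' Peri-wound region of interest
#'
#' All pixels whose perpendicular distance to the wound axis is at most
#' `band_halfwidth_px`, optionally clipped along the axis.
#'
#' @param axis list with `point` `(row, col)` and unit `direction`.
#' @param band_halfwidth_px nonnegative half-width of the band in pixels.
#' @param shape integer `(H, W)` of the target image.
#' @param axial_halflength optional half-length of the band along the axis;
#'   `NULL` (default) leaves the band unbounded along the axis.
#' @return H x W logical mask.
#' @export
wound_roi <- function(axis, band_halfwidth_px, shape, axial_halflength = NULL) {
  stopifnot(band_halfwidth_px >= 0, length(shape) == 2)
  h <- shape[1]; w <- shape[2]
  rr <- matrix(seq_len(h), h, w) - axis$point[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - axis$point[2]
  perp <- abs(rr * axis$direction[2] - cc * axis$direction[1])
  m <- perp <= band_halfwidth_px
  if (!is.null(axial_halflength)) {
    along <- rr * axis$direction[1] + cc * axis$direction[2]
    m <- m & (abs(along) <= axial_halflength)
  }
  m
}

#' Reconstruct the image under the staple mask
#'
#' Diffusion (harmonic) inpainting: masked pixels are repeatedly replaced by
#' the mean of their 4-neighbours until the update falls below `tol` or the
#' iteration cap is reached, per channel. Unmasked pixels are never touched.
#' Computation runs on the bounding box of the mask for speed.
#'
#' @param image a [wound_image()].
#' @param mask H x W logical (or 0/1) matrix of pixels to reconstruct.
#' @param iterations iteration cap.
#' @param tol convergence tolerance on the largest per-iteration change.
#' @return A [wound_image()] with masked pixels filled in.
#' @export
inpaint_staples <- function(image, mask, iterations = 500, tol = 1e-5) {
  stopifnot(inherits(image, "wound_image"))
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!all(dim(mask) == dim(image)[1:2])) stop("mask shape must match image")
  if (all(mask)) stop("mask covers the entire image: nothing to diffuse from")
  if (!any(mask)) return(image)

  px <- unclass(image)
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1, min(idx[, 1]) - 2); r1 <- min(nrow(mask), max(idx[, 1]) + 2)
  c0 <- max(1, min(idx[, 2]) - 2); c1 <- min(ncol(mask), max(idx[, 2]) + 2)
  sub <- px[r0:r1, c0:c1, , drop = FALSE]
  m <- mask[r0:r1, c0:c1]
  if (all(m)) { # degenerate crop: widen to full image
    sub <- px; m <- mask; r0 <- 1; c0 <- 1; r1 <- nrow(mask); c1 <- ncol(mask)
  }

  # edge-replicating shift keeps border averages well defined
  shift_rep <- function(x, dr, dc) {
    h <- nrow(x); w <- ncol(x)
    x[pmin(pmax(seq_len(h) + dr, 1), h), pmin(pmax(seq_len(w) + dc, 1), w)]
  }
  for (ch in 1:3) {
    f <- sub[, , ch]
    f[m] <- mean(f[!m])                 # neutral start
    for (it in seq_len(iterations)) {
      avg <- (shift_rep(f, 1, 0) + shift_rep(f, -1, 0) +
              shift_rep(f, 0, 1) + shift_rep(f, 0, -1)) / 4
      delta <- max(abs(avg[m] - f[m]))
      f[m] <- avg[m]
      if (delta < tol) break
    }
    sub[, , ch] <- f
  }
  px[r0:r1, c0:c1, ] <- sub
  px[px < 0] <- 0; px[px > 1] <- 1
  wound_image(px, source_id = attr(image, "source_id"),
              capture_tag = attr(image, "capture_tag"), warn_undersized = FALSE)
}

# smallest absolute difference between two orientations, modulo 180 degrees
angle_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Write a staple detection report as JSON
#'
#' @param detection a `staple_detection`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(detection, path) {
  rep <- list(n_components = nrow(detection$components),
              components = detection$components,
              wound_axis = detection$wound_axis,
              roi_pixels = if (is.null(detection$roi_mask)) NULL else sum(detection$roi_mask),
              params = detection$params)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
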