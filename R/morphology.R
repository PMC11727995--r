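#' Fuzzy structuring element
#'
#' A structuring element is a small h x w raster of memberships in \[0, 1\]
#' probing the image in the fuzzy morphological operators. At least one
#' membership must equal 1 at or next to the origin, otherwise erosion would
#' not be anti-extensive at the origin.
#'
#' @param memberships numeric matrix of memberships in \[0, 1\]; odd
#'   dimensions recommended.
#' @param origin integer `(row, col)` of the origin inside the raster;
#'   defaults to the centre.
#' @return A `structuring_element` object.
#' @export
#' @examples
#' structuring_element(matrix(1, 3, 3))               # flat 3x3
#' se_line(9, angle_deg = 45)                          # oriented line
structuring_element <- function(memberships,
                                origin = (dim(memberships) + 1) %/% 2) {
  memberships <- as.matrix(memberships)
  if (anyNA(memberships) || min(memberships) < 0 || max(memberships) > 1)
    stop("memberships must lie in [0, 1]")
  origin <- as.integer(origin)
  if (length(origin) != 2L ||
      origin[1] < 1L || origin[1] > nrow(memberships) ||
      origin[2] < 1L || origin[2] > ncol(memberships))
    stop("origin must index a cell of the membership raster")
  nb <- memberships[max(1, origin[1] - 1):min(nrow(memberships), origin[1] + 1),
                    max(1, origin[2] - 1):min(ncol(memberships), origin[2] + 1)]
  if (max(nb) < 1)
    stop("a membership of 1 is required at or adjacent to the origin")
  structure(list(memberships = memberships, origin = origin),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> %d x %d, origin (%d, %d)%s\n",
              nrow(x$memberships), ncol(x$memberships),
              x$origin[1], x$origin[2],
              if (all(x$memberships %in% c(0, 1))) ", crisp" else ", fuzzy"))
  invisible(x)
}

#' Flat square structuring element
#' @param size odd side length in pixels.
#' @return A crisp `size` x `size` [structuring_element()].
#' @export
se_square <- function(size = 3) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("size must be odd and positive")
  structuring_element(matrix(1, size, size))
}

#' Oriented linear structuring element
#'
#' A crisp digital line of the given length and orientation, used to probe
#' elongated structures such as staples.
#'
#' @param length_px approximate length in pixels.
#' @param angle_deg orientation in degrees in \[0, 180): 0 points along image
#'   columns, 90 along rows.
#' @return A [structuring_element()].
#' @export
se_line <- function(length_px, angle_deg = 0) {
  length_px <- max(1L, as.integer(length_px))
  th <- angle_deg * pi / 180
  half <- (length_px - 1) / 2
  t <- seq(-half, half, by = 0.5)
  rr <- round(t * sin(th)); cc <- round(t * cos(th))
  rows <- rr - min(rr) + 1; cols <- cc - min(cc) + 1
  m <- matrix(0, max(rows), max(cols))
  m[cbind(rows, cols)] <- 1
  structuring_element(m, origin = c(1 - min(rr), 1 - min(cc)))
}

#' Fuzzy conjunction / residual implication pair
#'
#' The operator pair the fuzzy morphology is parameterised by: a left-
#' continuous t-norm and its residual implication. `"godel"` (minimum t-norm,
#' Goedel implication) is the default because with crisp structuring elements
#' it reduces exactly to classical flat gray-scale morphology;
#' `"lukasiewicz"` is provided as the usual alternative.
#'
#' @param name `"godel"` or `"lukasiewicz"`.
#' @return A `fuzzy_logic_pair` with vectorised functions `conj(b, a)` and
#'   `impl(b, a)`.
#' @export
fuzzy_logic_pair <- function(name = c("godel", "lukasiewicz")) {
  name <- match.arg(name)
  if (name == "godel") {
    conj <- function(b, a) pmin(b, a)
    impl <- function(b, a) ifelse(b <= a, 1, a)
  } else {
    conj <- function(b, a) pmax(0, a + b - 1)
    impl <- function(b, a) pmin(1, 1 - b + a)
  }
  structure(list(name = name, conj = conj, impl = impl),
            class = "fuzzy_logic_pair")
}

# shift a matrix by (dr, dc) with constant padding:
# result[i, j] = m[i + dr, j + dc] when inside, `pad` otherwise
shift_mat <- function(m, dr, dc, pad) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(pad, h, w)
  sr <- max(1, 1 + dr):min(h, h + dr)
  sc <- max(1, 1 + dc):min(w, w + dc)
  if (length(sr) > 0 && length(sc) > 0)
    out[sr - dr, sc - dc] <- m[sr, sc]
  out
}

check_channel <- function(f, se) {
  f <- as.matrix(f)
  if (anyNA(f) || min(f) < 0 || max(f) > 1)
    stop("gray channel values must lie in [0, 1]")
  if (nrow(se$memberships) > nrow(f) || ncol(se$memberships) > ncol(f))
    stop("structuring element larger than image")
  f
}

se_offsets <- function(se) {
  idx <- which(se$memberships > 0, arr.ind = TRUE)
  list(dr = idx[, 1] - se$origin[1],
       dc = idx[, 2] - se$origin[2],
       b  = se$memberships[idx])
}

# fast path: crisp full-rectangle SE with the Goedel pair is a classical
# flat min/max filter, separable into row and column passes
is_flat_rect <- function(se, logic) {
  logic$name == "godel" && all(se$memberships == 1) &&
    all(se$origin == (dim(se$memberships) + 1) %/% 2) &&
    all(dim(se$memberships) %% 2 == 1)
}

running_extreme <- function(f, half_h, half_w, pad, fun) {
  if (half_w > 0) {
    acc <- f
    for (d in seq_len(half_w)) acc <- fun(acc, shift_mat(f, 0, -d, pad), shift_mat(f, 0, d, pad))
    f <- acc
  }
  if (half_h > 0) {
    acc <- f
    for (d in seq_len(half_h)) acc <- fun(acc, shift_mat(f, -d, 0, pad), shift_mat(f, d, 0, pad))
    f <- acc
  }
  f
}

#' Fuzzy gray-scale erosion
#'
#' `(f erode B)(x) = inf_y I(B(y - x), f(y))`, the standard fuzzy
#' generalisation of flat erosion, with `I` the residual implication of the
#' chosen t-norm. Out-of-image pixels are treated as 1 (erosion-neutral), so
#' the border does not generate spurious dark responses.
#'
#' @param f numeric matrix with values in \[0, 1\] (a gray channel).
#' @param se a [structuring_element()].
#' @param logic a [fuzzy_logic_pair()].
#' @return A matrix of the same shape, values in \[0, 1\].
#' @export
fuzzy_erode <- function(f, se, logic = fuzzy_logic_pair("godel")) {
  f <- check_channel(f, se)
  if (is_flat_rect(se, logic)) {
    d <- dim(se$memberships)
    return(running_extreme(f, (d[1] - 1) %/% 2, (d[2] - 1) %/% 2, 1,
                           function(a, b, c) pmin(a, b, c)))
  }
  off <- se_offsets(se)            # cells with B > 0; I(0, a) = 1 is neutral
  out <- matrix(1, nrow(f), ncol(f))
  for (k in seq_along(off$b))
    out <- pmin(out, logic$impl(off$b[k], shift_mat(f, off$dr[k], off$dc[k], 1)))
  out
}

#' Fuzzy gray-scale dilation
#'
#' `(f dilate B)(x) = sup_y C(B(x - y), f(y))` with `C` the t-norm; the
#' adjoint of [fuzzy_erode()]. Out-of-image pixels are treated as 0
#' (dilation-neutral).
#'
#' @inheritParams fuzzy_erode
#' @return A matrix of the same shape, values in \[0, 1\].
#' @export
fuzzy_dilate <- function(f, se, logic = fuzzy_logic_pair("godel")) {
  f <- check_channel(f, se)
  if (is_flat_rect(se, logic)) {
    d <- dim(se$memberships)
    return(running_extreme(f, (d[1] - 1) %/% 2, (d[2] - 1) %/% 2, 0,
                           function(a, b, c) pmax(a, b, c)))
  }
  off <- se_offsets(se)            # C(0, a) = 0 never attains the sup
  out <- matrix(0, nrow(f), ncol(f))
  for (k in seq_along(off$b))
    out <- pmax(out, logic$conj(off$b[k], shift_mat(f, -off$dr[k], -off$dc[k], 0)))
  out
}

#' Fuzzy opening
#'
#' Erosion followed by dilation with the same element; removes bright
#' structures too thin to contain the element.
#'
#' @inheritParams fuzzy_erode
#' @return A matrix of the same shape, values in \[0, 1\].
#' @export
fuzzy_open <- function(f, se, logic = fuzzy_logic_pair("godel")) {
  fuzzy_dilate(fuzzy_erode(f, se, logic), se, logic)
}

#' Fuzzy white top-hat
#'
#' `f - open(f)`: isolates bright structures thinner than the structuring
#' element — for this pipeline, the metallic staples on skin. The adjunction
#' guarantees `open(f) <= f`; tiny negative values from floating point are
#' clamped to 0.
#'
#' @inheritParams fuzzy_erode
#' @return A matrix of the same shape, values in \[0, 1\].
#' @export
fuzzy_tophat <- function(f, se, logic = fuzzy_logic_pair("godel")) {
  f <- check_channel(f, se)
  out <- f - fuzzy_open(f, se, logic)
  out[out < 0] <- 0
  out
}
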