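# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals: plain double
# loops over pixels and structuring-element cells.

logic_fns <- function(name) {
  if (name == "godel") {
    list(conj = function(b, a) min(b, a),
         impl = function(b, a) if (b <= a) 1 else a)
  } else {
    list(conj = function(b, a) max(0, a + b - 1),
         impl = function(b, a) min(1, 1 - b + a))
  }
}

# (f erode B)(x) = inf_y I(B(y - x), f(y)); out-of-image f = 1
brute_erode <- function(f, memb, origin, logic_name = "godel") {
  lg <- logic_fns(logic_name)
  h <- nrow(f); w <- ncol(f)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 1
    for (bi in seq_len(nrow(memb))) for (bj in seq_len(ncol(memb))) {
      yi <- i + bi - origin[1]; yj <- j + bj - origin[2]
      fy <- if (yi >= 1 && yi <= h && yj >= 1 && yj <= w) f[yi, yj] else 1
      acc <- min(acc, lg$impl(memb[bi, bj], fy))
    }
    out[i, j] <- acc
  }
  out
}

# (f dilate B)(x) = sup_y C(B(x - y), f(y)); out-of-image f = 0
brute_dilate <- function(f, memb, origin, logic_name = "godel") {
  lg <- logic_fns(logic_name)
  h <- nrow(f); w <- ncol(f)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (bi in seq_len(nrow(memb))) for (bj in seq_len(ncol(memb))) {
      yi <- i - (bi - origin[1]); yj <- j - (bj - origin[2])
      fy <- if (yi >= 1 && yi <= h && yj >= 1 && yj <= w) f[yi, yj] else 0
      acc <- max(acc, lg$conj(memb[bi, bj], fy))
    }
    out[i, j] <- acc
  }
  out
}

brute_open <- function(f, memb, origin, logic_name = "godel") {
  brute_dilate(brute_erode(f, memb, origin, logic_name), memb, origin,
               logic_name)
}

# classical flat gray-scale morphology: min/max over the crisp support
classical_erode <- function(f, memb, origin) {
  h <- nrow(f); w <- ncol(f)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- 1
    for (bi in seq_len(nrow(memb))) for (bj in seq_len(ncol(memb))) {
      if (memb[bi, bj] == 1) {
        yi <- i + bi - origin[1]; yj <- j + bj - origin[2]
        v <- if (yi >= 1 && yi <= h && yj >= 1 && yj <= w) f[yi, yj] else 1
        vals <- c(vals, v)
      }
    }
    out[i, j] <- min(vals)
  }
  out
}

classical_dilate <- function(f, memb, origin) {
  h <- nrow(f); w <- ncol(f)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- 0
    for (bi in seq_len(nrow(memb))) for (bj in seq_len(ncol(memb))) {
      if (memb[bi, bj] == 1) {
        yi <- i - (bi - origin[1]); yj <- j - (bj - origin[2])
        v <- if (yi >= 1 && yi <= h && yj >= 1 && yj <= w) f[yi, yj] else 0
        vals <- c(vals, v)
      }
    }
    out[i, j] <- max(vals)
  }
  out
}

# Cohen's kappa straight from its definition via the contingency table
brute_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in lev) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  (po - pe) / (1 - pe)
}

# exhaustive threshold enumeration for the best Youden J
brute_best_youden <- function(scores, truth) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  best <- -Inf
  for (t in cand) {
    tpr <- sum(scores >= t & truth == 1) / sum(truth == 1)
    fpr <- sum(scores >= t & truth == 0) / sum(truth == 0)
    best <- max(best, tpr - fpr)
  }
  best
}

# orthogonal-regression direction by sweeping angles on a 0.1 degree grid
brute_axis_angle <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  angles <- seq(0, 179.9, by = 0.1)
  sse <- vapply(angles, function(a) {
    th <- a * pi / 180
    d <- c(sin(th), cos(th))
    sum((x[, 1] * d[2] - x[, 2] * d[1])^2)
  }, numeric(1))
  angles[which.min(sse)]
}

# small helpers for fixtures
make_img <- function(px, id = "test") {
  wound_image(px, source_id = id, warn_undersized = FALSE)
}

solid_img <- function(h, w, rgb) {
  px <- array(0, c(h, w, 3))
  for (k in 1:3) px[, , k] <- rgb[k]
  make_img(px)
}

rand_channel <- function(h = 8, w = 8) matrix(runif(h * w), h, w)

rand_crisp_se <- function() {
  m <- matrix(rbinom(9, 1, 0.6), 3, 3)
  m[2, 2] <- 1
  structuring_element(m)
}

rand_fuzzy_se <- function() {
  m <- matrix(runif(9), 3, 3)
  m[2, 2] <- 1
  structuring_element(m)
}

complete_record <- function(...) {
  base <- list(vas = 0, redness = 0, burning = 0, opening = 0, swelling = 0,
               secretion = 0, fever = 0)
  modifyList(base, list(...))
}
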