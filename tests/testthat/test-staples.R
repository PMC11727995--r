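test_that("wound axis through collinear centroids is exact", {
  a <- estimate_wound_axis(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(a$direction, c(sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(a$point, c(1, 1))
  b <- estimate_wound_axis(rbind(c(0, 0), c(0, 5), c(0, 9)))
  expect_equal(b$direction, c(0, 1))
  expect_error(estimate_wound_axis(rbind(c(1, 1))), "fewer than 2")
})

test_that("TLS axis matches a brute-force angle sweep on noisy points", {
  set.seed(42)
  for (rep in 1:5) {
    th <- runif(1, 0, 180) * pi / 180
    d <- c(sin(th), cos(th))
    t <- runif(20, -50, 50)
    pts <- cbind(100 + t * d[1] + rnorm(20, 0, 1),
                 100 + t * d[2] + rnorm(20, 0, 1))
    a <- estimate_wound_axis(pts)
    est_deg <- (atan2(a$direction[1], a$direction[2]) * 180 / pi) %% 180
    sweep_deg <- brute_axis_angle(pts)
    true_deg <- (th * 180 / pi) %% 180
    expect_lt(min(abs(est_deg - true_deg), 180 - abs(est_deg - true_deg)), 5)
    expect_lt(min(abs(est_deg - sweep_deg), 180 - abs(est_deg - sweep_deg)), 0.1)
  }
})

test_that("wound_roi counts pixels of a horizontal band exactly and clips at borders", {
  axis <- list(point = c(10, 0), direction = c(0, 1))
  for (hwid in c(0, 2.5, 4)) {
    m <- wound_roi(axis, hwid, c(21, 15))
    expect_equal(sum(m), 15 * (2 * floor(hwid) + 1))
  }
  # axis near the top border: band is clipped strictly below its full size
  near <- wound_roi(list(point = c(2, 0), direction = c(0, 1)), 4, c(21, 15))
  expect_lt(sum(near), 15 * 9)
  # axial clipping restricts the band along the axis
  clipped <- wound_roi(axis, 2, c(21, 15), axial_halflength = 3)
  expect_lt(sum(clipped), sum(wound_roi(axis, 2, c(21, 15))))
})

test_that("inpainting is identity off the mask and exact on trivial cases", {
  set.seed(9)
  px <- array(runif(12 * 12 * 3), c(12, 12, 3))
  img <- make_img(px)
  empty <- matrix(FALSE, 12, 12)
  expect_identical(inpaint_staples(img, empty), img)   # bit for bit

  solid <- solid_img(12, 12, c(0.4, 0.5, 0.6))
  mask <- matrix(FALSE, 12, 12); mask[4:6, 4:8] <- TRUE
  out <- inpaint_staples(solid, mask)
  expect_lt(max(abs(unclass(out) - unclass(solid))), 1e-6)
})

test_that("inpainting never touches unmasked pixels and errors on a full mask", {
  set.seed(10)
  px <- array(runif(10 * 10 * 3), c(10, 10, 3))
  img <- make_img(px)
  mask <- matrix(FALSE, 10, 10); mask[3:4, 5:7] <- TRUE
  out <- unclass(inpaint_staples(img, mask))
  for (k in 1:3) {
    a <- out[, , k]; b <- px[, , k]
    expect_identical(a[!mask], b[!mask])
  }
  expect_error(inpaint_staples(img, matrix(TRUE, 10, 10)), "entire image")
})

test_that("a synthetic staple over uniform skin is reconstructed to the skin colour", {
  skin <- c(0.78, 0.6, 0.47)
  px <- array(0, c(40, 40, 3))
  for (k in 1:3) px[, , k] <- skin[k]
  mask <- matrix(FALSE, 40, 40); mask[10:30, 19:21] <- TRUE  # staple-like bar
  for (k in 1:3) { ch <- px[, , k]; ch[mask] <- 0.95; px[, , k] <- ch }
  out <- unclass(inpaint_staples(make_img(px), mask))
  for (k in 1:3)
    expect_lt(max(abs(out[, , k][mask] - skin[k])), 0.02)
})

test_that("staple detection recovers count, position and orientation on synthetic scenes", {
  pr <- wound_scene_params(seed = 1234, erythema_intensity = 0.3,
                           artifacts = list(stain_probability = 0,
                                            stain_color = c(0.6, 0.2, 0.18),
                                            dressing_probability = 0))
  sc <- generate_wound_image(pr)
  det <- detect_staples(sc$image)
  expect_equal(nrow(det$components), 6)
  # match each found centroid to the nearest generated one
  d2 <- outer(det$components$centroid_row, sc$truth$staple_centroids[, 1], "-")^2 +
    outer(det$components$centroid_col, sc$truth$staple_centroids[, 2], "-")^2
  expect_lt(max(sqrt(apply(d2, 1, min))), 3)
  expect_true(all(angle_ok <- abs(vapply(det$components$orientation_deg, function(a) {
    d <- abs(a - sc$truth$staple_orientation_deg) %% 180; min(d, 180 - d)
  }, numeric(1))) < 10))
  expect_false(is.null(det$wound_axis))
  expect_false(is.null(det$roi_mask))
})

test_that("detection is deterministic and finds nothing on staple-free skin", {
  pr <- wound_scene_params(seed = 77, n_staples = 1)
  sc <- generate_wound_image(pr)
  d1 <- detect_staples(sc$image); d2 <- detect_staples(sc$image)
  expect_identical(d1$staple_mask, d2$staple_mask)
  expect_equal(nrow(d1$components), 1)
  dd <- abs(d1$components$orientation_deg - sc$truth$staple_orientation_deg) %% 180
  expect_lt(min(dd, 180 - dd), 10)
  expect_null(d1$wound_axis)   # one staple cannot fix an axis

  bare <- generate_wound_image(wound_scene_params(seed = 78, n_staples = 0))
  db <- detect_staples(bare$image)
  expect_equal(nrow(db$components), 0)
  expect_equal(sum(db$staple_mask), 0)
})
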