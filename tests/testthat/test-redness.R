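test_that("red membership follows the trapezoid on hue distance with sat/val gates", {
  expect_equal(red_membership(0, 1, 1), 1)
  expect_equal(red_membership(355, 1, 1), 1)     # circular distance 5 <= 10
  expect_equal(red_membership(20, 1, 1), 0.5)    # ramp (30 - 20) / (30 - 10)
  expect_equal(red_membership(25, 1, 1), 0.25)
  expect_equal(red_membership(240, 1, 1), 0)     # blue
  expect_equal(red_membership(0, 0.1, 1), 0)     # washed out
  expect_equal(red_membership(0, 1, 0.1), 0)     # too dark
})

test_that("redness proportion counts red pixels exactly", {
  red <- c(1, 0, 0); blue <- c(0, 0, 1)
  px <- array(0, c(10, 10, 3))
  for (k in 1:3) px[, 1:5, k] <- red[k]
  for (k in 1:3) px[, 6:10, k] <- blue[k]
  img <- make_img(px)
  roi <- matrix(TRUE, 10, 10)
  expect_equal(redness_proportion(img, roi, method = "crisp")$proportion, 0.5)
  allred <- solid_img(5, 5, red); allblue <- solid_img(5, 5, blue)
  r5 <- matrix(TRUE, 5, 5)
  for (m in c("crisp", "weighted")) {
    expect_equal(redness_proportion(allred, r5, method = m)$proportion, 1)
    expect_equal(redness_proportion(allblue, r5, method = m)$proportion, 0)
  }
  expect_error(redness_proportion(img, matrix(FALSE, 10, 10)), "empty ROI")
})

test_that("crisp proportion equals brute-force per-pixel counting on random images", {
  set.seed(61)
  params <- red_membership_params()
  for (rep in 1:10) {
    px <- array(runif(16 * 16 * 3), c(16, 16, 3))
    img <- make_img(px)
    roi <- matrix(runif(256) < 0.7, 16, 16)
    if (!any(roi)) roi[1, 1] <- TRUE
    got <- redness_proportion(img, roi, params, "crisp")$proportion
    # oracle: per-pixel HSV + membership, explicit loop
    cnt <- 0; tot <- 0
    for (i in 1:16) for (j in 1:16) {
      if (!roi[i, j]) next
      tot <- tot + 1
      hv <- grDevices::rgb2hsv(px[i, j, 1], px[i, j, 2], px[i, j, 3],
                               maxColorValue = 1)
      hue <- (hv[1] * 360) %% 360
      d <- min(hue, 360 - hue)
      mem <- if (hv[2] < params$min_saturation || hv[3] < params$min_value) 0
      else if (d <= params$hue_full_deg) 1
      else if (d >= params$hue_zero_deg) 0
      else (params$hue_zero_deg - d) / (params$hue_zero_deg - params$hue_full_deg)
      if (mem >= 0.5) cnt <- cnt + 1
    }
    expect_equal(got, cnt / tot)
  }
})

test_that("recolouring pixels toward red never decreases the proportion", {
  set.seed(62)
  px <- array(runif(12 * 12 * 3), c(12, 12, 3))
  img <- make_img(px)
  roi <- matrix(TRUE, 12, 12)
  p0 <- redness_proportion(img, roi)$proportion
  # push five pixels to saturated pure red
  px2 <- px
  for (k in 1:3) px2[1:5, 1, k] <- c(1, 0, 0)[k]
  p1 <- redness_proportion(make_img(px2), roi)$proportion
  expect_gte(p1, p0)
})

test_that("classification against the cutoff is >= with ties positive", {
  expect_true(classify_redness(0.70))
  expect_false(classify_redness(0.50))
  expect_true(classify_redness(0.63))          # tie counts positive
  expect_true(classify_redness(0.4, threshold = 0.4))
  expect_error(classify_redness(1.2), "\\[0, 1\\]")
  expect_error(classify_redness(0.5, threshold = -0.1), "\\[0, 1\\]")
  r <- redness_proportion(solid_img(4, 4, c(1, 0, 0)), matrix(TRUE, 4, 4))
  r <- classify_redness(r)
  expect_true(r$positive)
  expect_equal(r$threshold, 0.63)
})

test_that("mean redness proportion increases with the generator's erythema intensity", {
  intensities <- seq(0.02, 0.98, length.out = 25)
  props <- vapply(seq_along(intensities), function(i) {
    sc <- generate_wound_image(wound_scene_params(
      seed = 500 + i, erythema_intensity = intensities[i],
      image_size = c(512, 512),
      artifacts = list(stain_probability = 0, stain_color = c(0.6, 0.2, 0.18),
                       dressing_probability = 0)))
    roi <- wound_roi(sc$truth$incision_axis, 50, dim(sc$image)[1:2],
                     axial_halflength = 150)
    redness_proportion(sc$image, roi)$proportion
  }, numeric(1))
  expect_gt(cor(props, intensities, method = "spearman"), 0.9)
})
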