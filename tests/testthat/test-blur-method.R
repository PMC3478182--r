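test_that("mean blur reproduces hand-computed window means", {
  # uniform in-mask brightness is a fixed point
  m <- matrix(TRUE, 6, 6)
  g <- green_image(matrix(100, 6, 6))
  bl <- mean_blur(g, m, blur_params(3, 2, TRUE))
  expect_equal(bl$values, matrix(100, 6, 6))

  # single bright pixel 90 on zero background, 3 x 3 window:
  # neighbours of the centre average to 90 / 9 = 10
  v <- matrix(0, 5, 5); v[3, 3] <- 90
  bl2 <- mean_blur(green_image(v), matrix(TRUE, 5, 5), blur_params(3, 2, TRUE))
  expect_equal(bl2$values[2, 2], 10)
  expect_equal(bl2$values[3, 3], 10)
  expect_equal(bl2$values[1, 1], 0)   # window misses the bright pixel

  # mask-aware strictly exceeds naive at the edge of a bright tooth
  m4 <- rect_mask(4, 4, 1:4, 1:2)
  v4 <- matrix(0, 4, 4); v4[m4] <- 100
  aware <- mean_blur(green_image(v4), m4, blur_params(3, 2, TRUE))
  naive <- mean_blur(green_image(v4), m4, blur_params(3, 2, FALSE))
  expect_equal(aware$values[2, 2], 100)
  expect_lt(naive$values[2, 2], aware$values[2, 2])
  # both are zero outside the mask
  expect_true(all(aware$values[!m4] == 0))
})

test_that("mean blur matches the double-loop oracle on random fixtures", {
  set.seed(41)
  for (i in 1:10) {
    h <- sample(4:12, 1); w <- sample(4:12, 1)
    mask <- random_masked_grid(h, w)
    g <- matrix(runif(h * w, 0, 255), h, w)
    size <- sample(2:6, 1)
    for (aware in c(TRUE, FALSE)) {
      got <- mean_blur(green_image(g), mask, blur_params(size, 2, aware))$values
      want <- brute_blur(g, mask, size, aware)
      want[!mask] <- 0
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("unsharp difference clamps at zero and vanishes off-mask", {
  m <- rect_mask(5, 5, 2:4, 2:4)
  g <- matrix(50, 5, 5)
  # identical images give an all-zero loss map
  lm0 <- unsharp_difference(green_image(g), green_image(g), m)
  expect_true(all(lm0$values == 0))
  expect_false(lm0$threshold_applied)

  # a dip of 20 below a flat blurred surface appears as loss 20
  gd <- g; gd[3, 3] <- 30
  lm1 <- unsharp_difference(green_image(gd), green_image(g), m)
  expect_equal(lm1$values[3, 3], 20)
  expect_equal(sum(lm1$values), 20)

  # brighter-than-blur pixels clamp to zero, never negative
  gb <- g; gb[3, 3] <- 90
  lm2 <- unsharp_difference(green_image(gb), green_image(g), m)
  expect_equal(lm2$values[3, 3], 0)
  expect_true(all(lm2$values >= 0))
  # zero outside the mask even when the images differ there
  g_out <- g; g_out[1, 1] <- 0
  lm3 <- unsharp_difference(green_image(g_out), green_image(g), m)
  expect_equal(lm3$values[1, 1], 0)
})

test_that("lesion selection applies the k-SD rule on reference statistics", {
  m <- matrix(TRUE, 4, 6)
  # reference loss values {0, 0, 0, 4}: mean 1, SD 2 -> cut at 1 + 2*2 = 5
  loss <- matrix(0, 4, 6)
  loss[1, 1:4] <- c(0, 0, 0, 4)
  loss[2, 1] <- 6   # selected: 6 > 5
  loss[2, 2] <- 4   # not selected
  loss[2, 3] <- 5   # boundary: not selected (strict >)
  ref <- structure(list(pixels = rect_mask(4, 6, 1, 1:4)), class = "fq_reference")
  lm <- loss_map(loss, FALSE, "blur")
  sel <- select_lesion_pixels(lm, m, ref, blur_params(30, 2))
  expect_true(sel[2, 1])
  expect_false(sel[2, 2])
  expect_false(sel[2, 3])

  # k_sd = 0 selects everything above the base mean
  sel0 <- select_lesion_pixels(lm, m, ref, blur_params(30, 0))
  expect_true(all(sel0[loss > 1]))
  expect_false(any(sel0[loss < 1]))

  # all-zero loss yields an empty lesion mask (SD = 0 degenerate rule)
  lz <- loss_map(matrix(0, 4, 6), FALSE, "blur")
  expect_false(any(select_lesion_pixels(lz, m, ref, blur_params())))
})

test_that("blur metrics follow the arithmetic definitions", {
  m <- matrix(TRUE, 5, 10)
  blurred <- green_image(matrix(200, 5, 10))
  loss <- matrix(0, 5, 10); loss[1, ] <- 20      # 10 lesion pixels of loss 20
  lesion <- loss > 0
  lm <- loss_map(loss, FALSE, "blur")
  g <- green_image(matrix(180, 5, 10))

  # with 0.1 mm/px: dF = 10%, Area = 0.1 mm^2, dQ = 1.0
  met <- blur_metrics(g, lm, lesion, blurred, mm_per_pixel = 0.1)
  expect_equal(met$delta_f, 10)
  expect_equal(met$area, 0.1)
  expect_equal(met$delta_q, 1.0)
  expect_equal(met$n_lesion_px, 10L)
  expect_equal(met$area_unit, "mm2")

  # without scale, area is the flagged pixel count
  met_px <- blur_metrics(g, lm, lesion, blurred)
  expect_equal(met_px$area, 10)
  expect_equal(met_px$area_unit, "px")

  # empty lesion gives (0, 0, 0)
  met0 <- blur_metrics(g, lm, lesion & FALSE, blurred)
  expect_equal(c(met0$area, met0$delta_f, met0$delta_q), c(0, 0, 0))

  # linearity: doubling the loss doubles dF and dQ, leaves area unchanged
  lm2 <- loss_map(2 * loss, FALSE, "blur")
  met2 <- blur_metrics(g, lm2, lesion, blurred, mm_per_pixel = 0.1)
  expect_equal(met2$delta_f, 2 * met$delta_f)
  expect_equal(met2$delta_q, 2 * met$delta_q)
  expect_equal(met2$area, met$area)

  # zero-blur pixels are skipped and counted
  bl0 <- green_image(matrix(c(0, rep(200, 49)), 5, 10))
  lesion0 <- matrix(FALSE, 5, 10); lesion0[1, 1] <- TRUE; lesion0[2, 1] <- TRUE
  loss0 <- matrix(0, 5, 10); loss0[1, 1] <- 5; loss0[2, 1] <- 20
  met_skip <- blur_metrics(g, loss_map(loss0, FALSE, "blur"), lesion0, bl0)
  expect_equal(met_skip$n_skipped_px, 1L)
  expect_equal(met_skip$n_lesion_px, 1L)
})

test_that("blur pipeline is shift invariant and keeps the dQ identity", {
  ph <- make_phantom(phantom_spec(lesion_area_fraction = 0.2,
                                  lesion_depth_fraction = 0.1,
                                  noise_sd = 0, seed = 5))
  g <- extract_green(ph$image)
  gp <- locate_gingival_point(ph$masks)
  ref <- select_reference_area(ph$masks, gp, g)
  res <- analyze_blur_tooth(g, ph$masks$UR1, ref, blur_params())
  expect_equal(res$metrics$delta_q, res$metrics$delta_f * res$metrics$area,
               tolerance = 1e-12)
  # loss is zero outside the mask
  expect_true(all(res$loss$values[!ph$masks$UR1] == 0))

  # translate image + masks together: metrics unchanged
  sh <- make_repeat(ph$image, ph$masks, translation = c(3, 2), gain = 1,
                    noise_sd = 0, seed = 1)
  g2 <- extract_green(sh$image)
  ref2 <- select_reference_area(sh$masks, locate_gingival_point(sh$masks), g2)
  res2 <- analyze_blur_tooth(g2, sh$masks$UR1, ref2, blur_params())
  expect_equal(res2$metrics$area, res$metrics$area)
  expect_equal(res2$metrics$delta_f, res$metrics$delta_f, tolerance = 1e-10)
})
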