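test_that("morphological opening removes specks and is idempotent", {
  m <- matrix(TRUE, 5, 5)
  # uniform image unchanged
  u <- green_image(matrix(80, 5, 5))
  expect_equal(open_image(u, m, hull_params())$values, matrix(80, 5, 5))

  # single bright speck removed by a radius-1 disk
  v <- matrix(50, 5, 5); v[3, 3] <- 200
  op <- open_image(green_image(v), m, hull_params(opening_radius_px = 1))
  expect_equal(op$values, matrix(50, 5, 5))

  # opening twice equals opening once
  set.seed(7)
  g <- matrix(sample(0:255, 49, TRUE), 7, 7)
  mask <- random_masked_grid(7, 7)
  once <- open_image(green_image(g), mask, hull_params(opening_radius_px = 1))
  twice <- open_image(once, mask, hull_params(opening_radius_px = 1))
  expect_equal(twice$values, once$values)

  # radius 0 disables the opening
  expect_equal(open_image(green_image(g), mask,
                          hull_params(opening_radius_px = 0))$values[mask],
               g[mask])
})

test_that("opening matches the double-loop mask-aware oracle", {
  set.seed(17)
  for (i in 1:8) {
    h <- sample(5:10, 1); w <- sample(5:10, 1)
    mask <- random_masked_grid(h, w)
    g <- matrix(sample(0:255, h * w, TRUE), h, w)
    r <- sample(1:2, 1)
    got <- open_image(green_image(g), mask, hull_params(opening_radius_px = r))$values
    expect_equal(got, brute_opening(g, mask, r), tolerance = 1e-12)
  }
})

test_that("clean surface handles degenerate and canonical cases exactly", {
  # 3 x 1 strip [10, 2, 10]: 1D upper envelope fills the dip
  cs <- upper_hull_surface(green_image(matrix(c(10, 2, 10), 1, 3)),
                          matrix(TRUE, 1, 3))
  expect_equal(as.vector(cs$values), c(10, 10, 10))

  # planar ramp is its own hull: zero loss everywhere
  v <- outer(1:6, 1:7, function(r, c) 40 + 2 * r + 3 * c)
  cs2 <- upper_hull_surface(green_image(v), matrix(TRUE, 6, 7))
  expect_equal(cs2$values, v)

  # dome with a central dark pit: pit filled, rim untouched, dominance holds
  x <- matrix(rep(1:9, each = 9), 9, 9); y <- matrix(rep(1:9, 9), 9, 9)
  dome <- 200 - 0.5 * ((x - 5)^2 + (y - 5)^2)
  pit <- dome; pit[4:6, 4:6] <- pit[4:6, 4:6] - 30
  cs3 <- upper_hull_surface(green_image(pit), matrix(TRUE, 9, 9))
  expect_true(all(cs3$values[4:6, 4:6] > pit[4:6, 4:6] + 20))
  expect_equal(cs3$values[1, ], dome[1, ])
  expect_true(all(cs3$values >= pit - 1e-9))

  # fewer than 3 pixels errors
  expect_error(upper_hull_surface(green_image(matrix(1, 1, 2)),
                                  matrix(TRUE, 1, 2)), "3 in-mask")
})

test_that("clean surface equals the brute-force upper envelope on random grids", {
  set.seed(23)
  for (i in 1:12) {
    h <- sample(4:10, 1); w <- sample(4:10, 1)
    mask <- random_masked_grid(h, w, density = 0.6)
    if (sum(mask) > 45) mask[sample(which(mask), sum(mask) - 45)] <- FALSE
    rc0 <- which(mask, arr.ind = TRUE)
    if (length(unique(rc0[, 1])) < 2 || length(unique(rc0[, 2])) < 2) next
    g <- matrix(runif(h * w, 0, 255), h, w)
    cs <- upper_hull_surface(green_image(g), mask)
    rc <- which(mask, arr.ind = TRUE)
    want <- brute_upper_envelope(rc[, 2], rc[, 1], g[mask])
    expect_equal(cs$values[mask], want, tolerance = 1e-6)
  }
})

test_that("strip envelopes match the 1D chain oracle", {
  set.seed(29)
  for (i in 1:5) {
    n <- sample(4:12, 1)
    z <- runif(n, 0, 255)
    cs <- upper_hull_surface(green_image(matrix(z, 1, n)), matrix(TRUE, 1, n))
    expect_equal(as.vector(cs$values), brute_envelope_1d(seq_len(n), z),
                 tolerance = 1e-9)
  }
})

test_that("loss thresholding keeps values at or above the level", {
  m <- matrix(TRUE, 2, 3)
  op <- green_image(matrix(c(100, 100, 96, 95, 100, 100), 2, 3))
  clean <- structure(list(values = matrix(100, 2, 3), mask = m), class = "fq_clean")
  lm <- loss_and_threshold(clean, op, m, hull_params(threshold_level = 5))
  expect_equal(lm$values[1, 2], 0)   # loss 4 -> zeroed
  expect_equal(lm$values[2, 2], 5)   # loss 5 -> retained at raw value
  expect_true(lm$threshold_applied)

  # threshold 0 leaves the map unchanged
  lm0 <- loss_and_threshold(clean, op, m, hull_params(threshold_level = 0))
  expect_equal(lm0$values, pmax(matrix(100, 2, 3) - op$values, 0))
})

test_that("hull metrics follow the fraction definitions and their identity", {
  # 100-pixel mask, 25 lesion pixels with fractional loss 0.08
  m <- matrix(TRUE, 10, 10)
  clean <- structure(list(values = matrix(200, 10, 10), mask = m),
                     class = "fq_clean")
  loss <- matrix(0, 10, 10); loss[1:5, 1:5] <- 16   # 16/200 = 0.08
  lm <- loss_map(loss, TRUE, "hull", threshold_level = 5)
  met <- hull_metrics(lm, m, clean)
  expect_equal(met$area, 0.25)
  expect_equal(met$delta_f, 0.08)
  expect_equal(met$delta_q, 0.02)
  expect_equal(met$delta_q, met$area * met$delta_f, tolerance = 1e-14)

  # zero loss gives (0, 0, 0)
  met0 <- hull_metrics(loss_map(matrix(0, 10, 10), TRUE, "hull", 5), m, clean)
  expect_equal(c(met0$area, met0$delta_f, met0$delta_q), c(0, 0, 0))

  # every pixel lesioned at fractional loss f: area 1, dF = dQ = f
  lf <- loss_map(matrix(20, 10, 10), TRUE, "hull", 5)
  metf <- hull_metrics(lf, m, clean)
  expect_equal(metf$area, 1)
  expect_equal(metf$delta_f, 0.1)
  expect_equal(metf$delta_q, 0.1)
})

test_that("hull loss is equivariant to brightness shifts and zero off-mask", {
  ph <- make_phantom(phantom_spec(lesion_area_fraction = 0.25,
                                  lesion_depth_fraction = 0.1,
                                  noise_sd = 0, quantize = FALSE, seed = 13))
  g <- extract_green(ph$image)
  m <- ph$masks$UR1
  r1 <- analyze_hull_tooth(g, m, hull_params(threshold_level = 0,
                                             opening_radius_px = 0))
  # add a constant to all in-mask brightness: raw loss unchanged
  g2 <- g; g2$values[m] <- g2$values[m] + 30
  r2 <- analyze_hull_tooth(g2, m, hull_params(threshold_level = 0,
                                              opening_radius_px = 0))
  expect_equal(r2$loss$values, r1$loss$values, tolerance = 1e-8)
  expect_true(all(r1$loss$values[!m] == 0))
  # clean surface dominates the opened image in-mask
  expect_true(all(r1$clean$values[m] >= r1$opened$values[m] - 1e-9))
  # dQ identity on an analyzed phantom
  expect_equal(r1$metrics$delta_q, r1$metrics$area * r1$metrics$delta_f,
               tolerance = 1e-12)
})
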