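test_that("hue convention places red at 0 and cyan at +/- pi", {
  red <- to_hsv(solid_image(255, 0, 0))
  expect_equal(unique(as.vector(red$hue)), 0)
  cyan <- to_hsv(solid_image(0, 255, 255))
  expect_true(all(abs(abs(cyan$hue) - pi) < 1e-12))
  grey <- to_hsv(solid_image(128, 128, 128))
  expect_equal(unique(as.vector(grey$sat)), 0)
  expect_equal(unique(as.vector(grey$val)), 128 / 255)
  expect_error(to_hsv(matrix(0, 4, 4)), "3 array")
})

test_that("circular hue statistics match the vector-sum oracle", {
  # half red (hue 0), half green (hue 2*pi/3)
  img <- solid_image(255, 0, 0)
  img[5:8, , 1L] <- 0L; img[5:8, , 2L] <- 255L
  hs <- hue_stats(to_hsv(img))
  angles <- c(rep(0, 32), rep(2 * pi / 3, 32))
  C <- mean(cos(angles)); S <- mean(sin(angles))
  expect_equal(hs$mean, atan2(S, C))
  expect_equal(hs$mean, pi / 3)
  expect_equal(hs$sd, sqrt(2 * (1 - sqrt(C^2 + S^2))))

  # uniform image: zero dispersion
  hs_red <- hue_stats(to_hsv(solid_image(255, 0, 0)))
  expect_equal(hs_red$mean, 0)
  expect_equal(hs_red$sd, 0)
})

test_that("degenerate hue distributions are flagged, not silently zero", {
  # all-achromatic image
  hs <- hue_stats(to_hsv(solid_image(77, 77, 77)))
  expect_true(hs$achromatic)
  expect_true(is.na(hs$mean))
  # antipodal: half red, half cyan -> resultant length ~ 0
  img <- solid_image(255, 0, 0)
  img[5:8, , 1L] <- 0L; img[5:8, , 2L] <- 255L; img[5:8, , 3L] <- 255L
  hs2 <- hue_stats(to_hsv(img))
  expect_true(hs2$unstable)
  expect_lt(hs2$R, 1e-8)
})

test_that("saturation/brightness moments are population statistics", {
  black <- channel_stats(to_hsv(solid_image(0, 0, 0)))
  expect_equal(black$bright_mean, 0)
  expect_equal(black$bright_sd, 0)
  white <- channel_stats(to_hsv(solid_image(255, 255, 255)))
  expect_equal(white$bright_mean, 1)
  expect_equal(white$sat_mean, 0)
  # half black / half white: two-point distribution, sd = 1/2
  img <- solid_image(0, 0, 0); img[5:8, , ] <- 255L
  cs <- channel_stats(to_hsv(img))
  expect_equal(cs$bright_mean, 0.5)
  expect_equal(cs$bright_sd, 0.5)
})

test_that("color ratios count band membership per pixel", {
  green <- solid_image(0, 200, 30)
  expect_equal(color_ratio(green, c(70, 170)), 1)
  expect_equal(color_ratio(solid_image(255, 0, 0), c(70, 170)), 0)
  # exact 25%-area green rectangle on red, vs per-pixel membership count
  img <- solid_image(255, 0, 0, 16, 16)
  img[1:8, 1:8, 1L] <- 0L; img[1:8, 1:8, 2L] <- 200L; img[1:8, 1:8, 3L] <- 30L
  expect_equal(color_ratio(img, c(70, 170)), 64 / 256)
  expect_error(color_ratio(img, c(90, 90)), "distinct")
})

test_that("sky ratio handles blue, overcast and fully-masked images", {
  cfg <- extraction_config()
  black <- solid_image(0, 0, 0, 20, 10)
  expect_equal(sky_ratio(black, cfg), 0)
  # top 30% pure blue, remainder mask black
  img <- solid_image(0, 0, 0, 20, 10)
  img[1:6, , 3L] <- 255L
  expect_equal(sky_ratio(img, cfg), 0.3)
  # top 30% white (overcast), remainder mask black
  ovc <- solid_image(0, 0, 0, 20, 10)
  ovc[1:6, , ] <- 245L
  expect_equal(sky_ratio(ovc, cfg), 0.3)
  expect_error(sky_ratio(img, cfg, original = solid_image(0, 0, 0, 5, 5)),
               "dimensions")
})

test_that("chromatic statistics are invariant to 90-degree rotation", {
  set.seed(42)
  img <- array(sample(0:255, 24 * 16 * 3, replace = TRUE),
               c(24L, 16L, 3L))
  rot <- rotate90(img)
  expect_equal(img_entropy(img), img_entropy(rot))
  expect_equal(channel_stats(to_hsv(img)), channel_stats(to_hsv(rot)))
  expect_equal(color_ratio(img, c(70, 170)), color_ratio(rot, c(70, 170)))
  expect_equal(color_ratio(img, c(170, 260)), color_ratio(rot, c(170, 260)))
})
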