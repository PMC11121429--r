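test_that("largest-remainder rounding always hits the target total", {
  expect_equal(largest_remainder(c(0.3, 0.5, 0.2)), c(30L, 50L, 20L))
  expect_equal(largest_remainder(c(33.4, 33.3, 33.3)), c(34L, 33L, 33L))
  set.seed(2)
  for (i in 1:50) {
    p <- runif(3); p <- p / sum(p)
    expect_equal(sum(largest_remainder(p)), 100L)
  }
})

test_that("rating rows satisfy the sum-100 constraint for any seed", {
  truth <- c(sky = 0.2, green = 0.5, built = 0.3)
  coeffs <- cohort_spec()$rating_coeffs
  for (s in 1:40) {
    r <- generate_ratings(truth, coeffs, seed = s)
    expect_equal(r$pct_nature + r$pct_manmade + r$pct_sky, 100L)
    expect_true(all(unlist(r[c("quality", "brightness_rating",
                               "green_visibility",
                               "long_distance_view")]) >= 0))
  }
  # zero noise reproduces the exact composition
  coeffs0 <- coeffs; coeffs0$pct_noise <- 0
  r0 <- generate_ratings(c(sky = 0.2, green = 0.5, built = 0.3), coeffs0,
                         seed = 7)
  expect_equal(c(r0$pct_nature, r0$pct_manmade, r0$pct_sky),
               c(50L, 30L, 20L))
})

test_that("planted negative-affect composite survives the item round trip", {
  coeffs <- cohort_spec()$outcome_coeffs
  coeffs$stadi_item_noise <- 0L
  oc <- generate_outcomes(brightness_rating = 70, k = 0.01,
                          coeffs = coeffs, seed = 5)
  # with zero item noise the items encode the planted composite exactly
  expect_equal(score_stadi(oc$stadi_items), oc$negative_affect)
  # noisy items still preserve the sum by construction
  coeffs$stadi_item_noise <- 8L
  oc2 <- generate_outcomes(70, 0.01, coeffs, seed = 5)
  expect_equal(score_stadi(oc2$stadi_items), oc2$negative_affect)
  expect_true(all(oc2$stadi_items %in% 1:4))
})

test_that("scene rendering is deterministic down to the PNG bytes", {
  sp <- scene_spec(p_sky = 0.3, p_green = 0.4, built_density = 0.6,
                   seed = 77)
  sc1 <- generate_scene(sp)
  sc2 <- generate_scene(sp)
  expect_identical(sc1$image, sc2$image)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  write_view_image(sc1$image, f1); write_view_image(sc2$image, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("scene ground truth and feasibility rules hold", {
  expect_error(scene_spec(p_sky = 0.7, p_green = 0.5), "infeasible")
  sc <- generate_scene(scene_spec(p_sky = 1, p_green = 0, seed = 4))
  expect_equal(unname(sc$realized["sky"]), 1)
  fv <- extract_features(sc$image, sc$masked)
  expect_lt(abs(fv[["sky_ratio"]] - 1), 0.01)
  # rectilinear-only scene: straight edges dominate, no green
  scr <- generate_scene(scene_spec(p_sky = 0.2, p_green = 0,
                                   built_density = 0.9, seed = 7))
  fvr <- extract_features(scr$image, scr$masked)
  expect_lt(fvr[["green_ratio"]], 0.02)
  expect_gt(fvr[["straight_edge_density"]] / fvr[["edge_density"]], 0.5)
})

test_that("image-count distribution matches the cohort parameterization", {
  counts <- unlist(lapply(1:6, function(s) {
    gt <- with_seed_helper(s, viewfeat:::draw_cohort_truth(cohort_spec(
      n_participants = 60, seed = s)))
    vapply(gt$participants, function(p) length(p$scene_seeds), numeric(1))
  }))
  expect_true(all(counts >= 1))
  expect_lt(abs(mean(counts) - 5.58), 0.5)
})

test_that("a tiny cohort writes the full dataset tree with ground truth", {
  dir <- file.path(tempdir(), "cohort5")
  unlink(dir, recursive = TRUE)
  res <- generate_cohort(cohort_spec(n_participants = 5, img_mean = 2,
                                     img_sd = 1, missing_na = 1,
                                     missing_auc = 1, width = 48,
                                     height = 48, seed = 3), dir)
  expect_length(list.dirs(dir, recursive = FALSE), 5L)
  expect_true(all(file.exists(file.path(dir,
    c("ratings.csv", "demographics.csv", "stadi_items.csv",
      "choices.csv", "ground_truth.json")))))
  # one diverse participant, injected missingness honoured
  expect_equal(sum(res$demographics$sex == "diverse"), 1L)
  expect_equal(nrow(res$stadi_items), 4L)
  # masks pair 1:1 with images
  p1 <- list.files(file.path(dir, "p001"))
  expect_equal(sum(grepl("_skymask", p1)), sum(!grepl("_skymask", p1)))
  unlink(dir, recursive = TRUE)
})
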