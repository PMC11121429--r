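test_that("negative-affect composite reverses euthymia and sums", {
  facets <- stadi_facets()
  # floor: all non-euthymia at 1, euthymia at 4 (reversed to 1)
  lo <- ifelse(facets == "euthymia", 4L, 1L)
  expect_equal(score_stadi(lo), 20L)
  hi <- ifelse(facets == "euthymia", 1L, 4L)
  expect_equal(score_stadi(hi), 80L)
  # uniform responses of 2: 15 items stay 2, 5 euthymia become 3
  expect_equal(score_stadi(rep(2L, 20)), 45L)
  expect_error(score_stadi(rep(2L, 19)), "20")
  expect_error(score_stadi(c(rep(2L, 19), 5L)), "1..4")
})

test_that("composite stays within [20, 80] over random response patterns", {
  set.seed(4)
  for (i in 1:200) {
    s <- score_stadi(sample(1:4, 20, replace = TRUE))
    expect_gte(s, 20L); expect_lte(s, 80L)
  }
})

test_that("staircase reproduces the worked examples and halving schedule", {
  s <- staircase_init()
  expect_equal(s$offer, 50)
  expect_equal(staircase_step(s, "immediate")$offer, 25)
  expect_equal(staircase_step(s, "delayed")$offer, 75)
  # two delayed choices: 50 + 25 + 12.5
  s2 <- staircase_step(staircase_step(s, "delayed"), "delayed")
  expect_equal(s2$offer, 87.5)
  expect_equal(s2$trial, 3L)
  s_end <- Reduce(function(st, ch) staircase_step(st, ch),
                  rep("delayed", 6), accumulate = FALSE, init = s)
  expect_error(staircase_step(s_end, "delayed"), "6 trials")
})

test_that("indifference points agree with exhaustive choice-tree oracle", {
  expect_equal(indifference_point(rep("delayed", 6)), 100 * (1 - 2^-7))
  expect_equal(indifference_point(rep("immediate", 6)), 100 * 2^-7)
  # all 64 choice sequences against the closed-form oracle
  grid <- expand.grid(rep(list(c("immediate", "delayed")), 6),
                      stringsAsFactors = FALSE)
  ips <- apply(grid, 1, function(ch) indifference_point(unname(ch)))
  oracle <- apply(grid, 1, staircase_oracle_ip)
  expect_equal(unname(ips), unname(oracle))
  expect_true(all(ips > 0 & ips < 100))
  expect_error(indifference_point(rep("delayed", 5)), "6 choices")
})

test_that("AUC trapezoids match hand-computed limits and stay monotone", {
  expect_equal(discounting_auc(rep(100, 7)), 1)
  # all-zero curve: only the anchor triangle remains
  x1 <- 0.25 / 1825
  expect_equal(discounting_auc(rep(0, 7)), x1 / 2)
  # always-delayed agent
  ip <- 100 * (1 - 2^-7)
  expect_equal(discounting_auc(rep(ip, 7)),
               x1 * (1 + ip / 100) / 2 + (1 - x1) * ip / 100)
  expect_error(discounting_auc(c(rep(50, 6), 101)), "\\[0, 100\\]")
  # monotone non-decreasing in every coordinate
  set.seed(12)
  for (i in 1:20) {
    base <- runif(7, 0, 99)
    j <- sample(7, 1)
    bumped <- base; bumped[j] <- bumped[j] + runif(1, 0, 100 - bumped[j])
    expect_gte(discounting_auc(bumped), discounting_auc(base))
  }
  # without the anchor the area is computed between observed delays only
  expect_equal(discounting_auc(rep(100, 7), anchor = FALSE), 1 - x1)
})

test_that("hyperbolic agents discount more steeply with larger k", {
  ks <- c(0, 0.001, 0.01, 0.1, 1)
  aucs <- vapply(seq_along(ks), function(i) {
    oc <- generate_outcomes(brightness_rating = 60, k = ks[i], seed = 100 + i)
    score_choice_log(cbind(participant_id = "p", oc$choices))$auc
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
  # k = 0: the delayed reward always wins (max offer 98.4375 < 100)
  oc0 <- generate_outcomes(60, k = 0, seed = 1)
  expect_true(all(oc0$choices$choice == "delayed"))
  # k = 10 at five years: subjective value << smallest offer
  oc10 <- generate_outcomes(60, k = 10, seed = 1)
  blk <- oc10$choices[oc10$choices$delay_label == "5y", ]
  expect_true(all(blk$choice == "immediate"))
})

test_that("choice-log scoring returns 7 indifference points per person", {
  oc <- generate_outcomes(50, k = 0.02, seed = 9)
  expect_equal(nrow(oc$choices), 42L)
  expect_equal(as.integer(table(oc$choices$delay_label)), rep(6L, 7))
  scored <- score_choice_log(cbind(participant_id = "x", oc$choices))
  expect_equal(nrow(scored), 1L)
  expect_length(grep("^ip_", names(scored)), 7L)
  expect_true(scored$auc >= 0 && scored$auc <= 1)
})
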