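test_that("exclusion bookkeeping matches the cohort design", {
  tab <- make_analysis_table(110, seed = 3)
  tab$sex[17] <- "diverse"
  tab$negative_affect[c(5, 9)] <- NA
  ex <- exclude_participants(tab)
  expect_equal(nrow(ex), 109L)
  expect_equal(attr(ex, "n_diverse_removed"), 1L)
  ex2 <- exclude_participants(tab, "negative_affect")
  expect_equal(nrow(ex2), 107L)
  expect_equal(attr(ex2, "n_missing_removed"), 2L)
  # nothing to exclude: identity
  clean <- make_analysis_table(20, seed = 4)
  expect_equal(nrow(exclude_participants(clean, "auc")), 20L)
})

test_that("feature models recover a planted green-ratio effect", {
  tab <- make_analysis_table(109, seed = 11, b_green = 80, noise_pct = 6)
  res <- design_A_feature_models(tab)
  s1 <- res$pct_nature$stage1
  expect_true("green_ratio" %in% s1$selected)
  expect_gt(s1$table$B[s1$table$variable == "green_ratio"], 0)
  # brightness features are never candidates by default
  expect_false(any(c("bright_mean", "bright_sd") %in%
                     unlist(lapply(res, function(r) r$stage1$selected))))
  expect_error(design_A_feature_models(within(tab, quality <- 50)),
               class = "simpleError")
})

test_that("stage 2 keeps the stage-1 model when controls carry no signal", {
  tab <- make_analysis_table(109, seed = 13)
  # orthogonalize every control against the stage-1 residuals so no
  # control can reduce the RSS: stage 2 must return the stage-1 model
  roles <- analysis_roles()
  ex <- exclude_participants(tab, "pct_nature")
  s1 <- stepwise_lm(ex, "pct_nature", candidates = roles$llvf)
  r1 <- residuals(s1)
  for (ctrl in setdiff(roles$controls, "sex")) {
    keep <- ex[[ctrl]]
    ex[[ctrl]] <- residuals(lm(keep ~ r1)) + mean(keep)
  }
  ex$sex <- 0  # constant: uninformative
  s2 <- tryCatch(
    stepwise_lm(ex, "pct_nature", candidates = setdiff(roles$controls, "sex"),
                forced = s1$selected),
    error = function(e) NULL)
  expect_false(is.null(s2))
  expect_identical(s2$selected, character(0))
  expect_setequal(s2$terms, s1$selected)
})

test_that("outcome models keep the forced block and find planted effects", {
  tab <- make_analysis_table(110, seed = 17, b_bright = -0.3, noise_na = 5)
  tab$sex[4] <- "diverse"
  tab$negative_affect[c(50, 51)] <- NA
  tab$auc[60] <- NA
  res <- design_B_outcome_models(tab)
  roles <- analysis_roles()
  for (oc in c("negative_affect", "auc"))
    expect_true(all(roles$controls %in% res[[oc]]$table$variable))
  expect_equal(res$negative_affect$n, 107L)
  expect_equal(res$auc$n, 108L)
  m <- res$negative_affect
  expect_true("brightness_rating" %in% m$selected)
  expect_lt(m$table$B[m$table$variable == "brightness_rating"], 0)
  # the sky percentage is withheld from the candidate set (collinear with
  # the other two composition shares)
  expect_false("pct_sky" %in% unlist(lapply(res, `[[`, "selected")))
})
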