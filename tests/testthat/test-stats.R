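test_that("spearman matrix matches the rank-then-pearson oracle", {
  d <- data.frame(x = c(3, 1, 4, 1, 5, 9, 2, 6),
                  y = c(2, 7, 1, 8, 2, 8, 1, 8))  # ties in both margins
  sm <- spearman_matrix(d, c("x", "y"))
  oracle <- pearson_oracle(avg_ranks(d$x), avg_ranks(d$y))
  expect_equal(sm$rho["x", "y"], oracle)
  # p from the t approximation
  n <- 8; r <- oracle
  expect_equal(sm$p["x", "y"],
               2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2))
  # monotone sequences hit the bounds exactly
  d2 <- data.frame(a = 1:9, up = (1:9)^3, down = -(1:9)^2)
  sm2 <- spearman_matrix(d2)
  expect_equal(sm2$rho["a", "up"], 1)
  expect_equal(sm2$rho["a", "down"], -1)
})

test_that("spearman matrix is symmetric with flagged degenerate entries", {
  set.seed(21)
  d <- data.frame(a = rnorm(15), b = rnorm(15), c = rep(1, 15))
  d$b[3] <- NA
  sm <- spearman_matrix(d)
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(diag(sm$rho), c(a = 1, b = 1, c = 1))
  expect_true(all(abs(sm$rho[!is.na(sm$rho)]) <= 1))
  expect_true(is.na(sm$rho["a", "c"]))  # zero-variance margin
  expect_equal(sm$n["a", "b"], 14)
})

test_that("ols fit reproduces exact relations and the algebraic identity", {
  d <- data.frame(x = 1:12)
  d$y <- 2 * d$x
  fit <- suppressWarnings(fit_ols(d, "y", "x"))  # exact fit
  expect_equal(fit$table$B[fit$table$variable == "x"], 2)
  expect_equal(fit$adj_r2, 1)
  # single predictor: standardized beta equals the pearson correlation
  set.seed(31)
  d2 <- data.frame(x = rnorm(40))
  d2$y <- 1.5 * d2$x + rnorm(40)
  f2 <- fit_ols(d2, "y", "x")
  expect_equal(f2$table$beta[f2$table$variable == "x"],
               pearson_oracle(d2$x, d2$y))
})

test_that("ols coefficients match the normal-equations oracle to 1e-10", {
  set.seed(5)
  d <- data.frame(x1 = rnorm(12), x2 = runif(12), x3 = rnorm(12))
  d$y <- 1 + 0.5 * d$x1 - 2 * d$x2 + rnorm(12)
  fit <- fit_ols(d, "y", c("x1", "x2", "x3"))
  X <- cbind(1, d$x1, d$x2, d$x3)
  b <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$table$B, as.vector(b), tolerance = 1e-10)
  # SEs from the unbiased residual variance
  res <- d$y - X %*% b
  s2 <- sum(res^2) / (12 - 4)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(fit$table$SE, unname(se), tolerance = 1e-10)
  # the reported AIC follows the full Gaussian-likelihood form
  rss <- sum(res^2); n <- 12; k <- 3
  expect_equal(fit$aic, n * log(rss / n) + 2 * (k + 2) + n * (log(2 * pi) + 1))
  expect_error(fit_ols(cbind(d, x4 = d$x1), "y", c("x1", "x4")),
               "collinear")
})

test_that("stepwise degenerates to forced-only fit without candidates", {
  set.seed(41)
  d <- data.frame(age = rnorm(30), sexn = rbinom(30, 1, 0.5))
  d$y <- 0.5 * d$age + rnorm(30)
  sw <- stepwise_lm(d, "y", candidates = character(), forced = c("age", "sexn"))
  ref <- fit_ols(d, "y", c("age", "sexn"))
  expect_equal(sw$table, ref$table)
  expect_equal(sw$aic, ref$aic)
  expect_identical(sw$selected, character(0))
})

test_that("candidates orthogonal to the outcome are never selected", {
  set.seed(51)
  n <- 60
  Z <- matrix(rnorm(n * 5), n, 5)
  y0 <- rnorm(n)
  # project the candidate block out of the outcome: every addition then
  # leaves RSS unchanged and costs 2 AIC points
  y <- residuals(lm(y0 ~ Z))
  d <- data.frame(y = y, Z)
  sw <- stepwise_lm(d, "y", candidates = paste0("X", 1:5))
  expect_identical(sw$selected, character(0))
  expect_equal(nrow(sw$trace), 1L)
})

test_that("stepwise recovers planted predictors and is locally optimal", {
  set.seed(61)
  hits <- 0L
  for (rep in 1:20) {
    n <- 109
    X <- matrix(rnorm(n * 12), n, 12)
    colnames(X) <- paste0("v", 1:12)
    y <- 3 * X[, 1] - 2 * X[, 2] + rnorm(n, 0, sqrt(13))  # R^2 ~ 0.5
    d <- data.frame(y = y, X)
    sw <- stepwise_lm(d, "y", candidates = colnames(X))
    if (all(c("v1", "v2") %in% sw$selected)) hits <- hits + 1L
    # local optimality: no single move improves the final AIC
    for (tm in sw$selected)
      expect_gte(fit_ols(d, "y", setdiff(sw$selected, tm))$aic,
                 sw$aic - 1e-8)
    for (tm in setdiff(colnames(X), sw$selected))
      expect_gte(fit_ols(d, "y", c(sw$selected, tm))$aic, sw$aic - 1e-8)
  }
  expect_gte(hits, 19L)
})

test_that("stepwise path reaches the best-subset AIC on easy signals", {
  set.seed(71)
  match_count <- 0L
  for (rep in 1:10) {
    n <- 80
    X <- matrix(rnorm(n * 6), n, 6)
    colnames(X) <- paste0("v", 1:6)
    y <- 2.5 * X[, 1] - 2 * X[, 3] + rnorm(n)
    d <- data.frame(y = y, X)
    sw <- stepwise_lm(d, "y", candidates = colnames(X))
    # exhaustive oracle over all 2^6 subsets
    best <- Inf
    for (mask in 0:63) {
      terms <- colnames(X)[bitwAnd(mask, 2^(0:5)) > 0]
      best <- min(best, fit_ols(d, "y", terms)$aic)
    }
    expect_gte(sw$aic, best - 1e-8)
    if (abs(sw$aic - best) < 1e-8) match_count <- match_count + 1L
  }
  expect_gte(match_count, 9L)
})

test_that("bidirectional selection agrees with the reference stepper", {
  set.seed(81)
  n <- 70
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("v", 1:6)
  y <- 1.8 * X[, 2] + 0.9 * X[, 5] + rnorm(n)
  d <- data.frame(y = y, X)
  sw <- stepwise_lm(d, "y", candidates = colnames(X))
  ref <- step(lm(y ~ 1, data = d),
              scope = list(lower = ~1, upper = reformulate(colnames(X))),
              direction = "both", trace = 0)
  expect_setequal(sw$selected, setdiff(names(coef(ref)), "(Intercept)"))
  expect_equal(sw$aic, AIC(ref))
})

test_that("forced terms survive selection and the trace is decreasing", {
  set.seed(91)
  n <- 60
  d <- data.frame(age = rnorm(n), inc = rnorm(n),
                  x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 2 * d$x1 + 0.3 * d$age + rnorm(n)
  sw <- stepwise_lm(d, "y", candidates = c("x1", "x2"),
                    forced = c("age", "inc"))
  expect_true(all(c("age", "inc") %in% sw$table$variable))
  expect_true("x1" %in% sw$selected)
  expect_true(all(diff(sw$trace$aic) < 0))
  expect_error(stepwise_lm(d, "y", candidates = "age", forced = "age"),
               "disjoint")
})
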