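# OLS fits carrying the coefficient table layout used throughout:
# B, SE, standardized beta, t, p, plus AIC and adjusted R^2.

#' Fit an ordinary least-squares model with standardized coefficients
#'
#' Wraps [stats::lm()] and augments the summary with standardized betas
#' (`beta_j = B_j * sd(x_j) / sd(y)`, computed on the analysis rows) and the
#' full Gaussian-likelihood AIC of [stats::AIC()],
#' `n*log(RSS/n) + 2*(k+2) + n*(log(2*pi) + 1)`.
#'
#' @param data Data frame holding outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param terms Character vector of predictor columns (may be empty for an
#'   intercept-only model).
#' @return An object of class `view_ols`: list with `table` (data frame
#'   `variable`, `B`, `SE`, `beta`, `t`, `p`), `adj_r2`, `r2`, `aic`, `n`,
#'   `outcome`, `terms`, and the underlying `lm` fit.
#' @export
fit_ols <- function(data, outcome, terms = character()) {
  stopifnot(is.data.frame(data), is_string(outcome))
  cols <- c(outcome, terms)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- data[complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(d); k <- length(terms)
  if (n <= k + 1L)
    stop("too few complete rows (", n, ") for ", k, " predictors",
         call. = FALSE)
  if (sd(d[[outcome]]) == 0)
    stop("outcome '", outcome, "' has zero variance", call. = FALSE)
  fml <- if (k == 0L) reformulate("1", response = outcome)
         else reformulate(terms, response = outcome)
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  sy <- sd(d[[outcome]])
  beta <- rep(NA_real_, nrow(ct))
  if (k > 0L) {
    sx <- vapply(terms, function(v) sd(d[[v]]), numeric(1))
    beta[match(terms, rownames(ct))] <- ct[terms, 1L] * sx / sy
  }
  tab <- data.frame(variable = rownames(ct), B = ct[, 1L], SE = ct[, 2L],
                    beta = beta, t = ct[, 3L], p = ct[, 4L],
                    row.names = NULL)
  structure(list(table = tab, adj_r2 = sm$adj.r.squared,
                 r2 = sm$r.squared, aic = AIC(fit), n = n,
                 outcome = outcome, terms = terms, fit = fit),
            class = "view_ols")
}

#' @export
print.view_ols <- function(x, digits = 3, ...) {
  cat("OLS model: ", x$outcome, " ~ ",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "\n", sep = "")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("n = %d, adjusted R^2 = %.4f, AIC = %.2f\n",
              x$n, x$adj_r2, x$aic))
  invisible(x)
}

#' @export
coef.view_ols <- function(object, ...) coef(object$fit)

#' @export
predict.view_ols <- function(object, newdata = NULL, ...)
  predict(object$fit, newdata = newdata, ...)

#' @export
residuals.view_ols <- function(object, ...) residuals(object$fit)

#' @export
summary.view_ols <- function(object, ...) object$table

#' Spearman rank correlation matrix with p-values
#'
#' Tie-corrected (average-rank) Spearman correlations between all pairs of
#' the requested variables, with two-sided p-values from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. Pairs are computed on complete observations; a pair with a
#' zero-variance margin or fewer than 3 complete cases is flagged `NA`.
#'
#' @param data Data frame.
#' @param variables Columns to correlate (default: all numeric columns).
#' @return Object of class `spearman_matrix`: list of matrices `rho`, `p`,
#'   `n` (symmetric, unit diagonal on `rho`).
#' @export
spearman_matrix <- function(data, variables = NULL) {
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  stopifnot(all(variables %in% names(data)))
  k <- length(variables)
  rho <- p <- nmat <- matrix(NA_real_, k, k,
                             dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- data[[variables[i]]]; y <- data[[variables[j]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    r <- cor(rank(x[ok]), rank(y[ok]))
    rho[i, j] <- rho[j, i] <- r
    pv <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
    p[i, j] <- p[j, i] <- pv
  }
  diag(nmat) <- vapply(variables,
                       function(v) sum(!is.na(data[[v]])), numeric(1))
  structure(list(rho = rho, p = p, n = nmat), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix (", nrow(x$rho), " variables)\n",
      sep = "")
  print(round(x$rho, digits))
  invisible(x)
}
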