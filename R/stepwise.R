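# Bidirectional AIC-stepwise model selection with forced-entry terms.

#' Bidirectional stepwise regression by AIC with forced terms
#'
#' Starts from the model containing only the forced terms (plus intercept)
#' and greedily improves the AIC: each iteration evaluates every single
#' addition from the remaining candidates and every single deletion of a
#' non-forced current term, applies the best move if it lowers the AIC, and
#' stops at a local AIC minimum. Forced terms are never dropped. At
#' (numerical) AIC ties the smaller model wins, then the candidate listed
#' earliest.
#'
#' @param data Data frame; rows with missing values on the involved columns
#'   are dropped once, up front (listwise).
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param forced Character vector of always-included predictor columns
#'   (disjoint from `candidates`).
#' @return Object of class `stepwise_lm`: the final [fit_ols()] result plus
#'   `forced`, `selected` (chosen candidates, in inclusion order), and
#'   `trace` (data frame `step`, `action`, `term`, `aic` — step 0 is the
#'   forced-only model).
#' @seealso [fit_ols()]
#' @export
stepwise_lm <- function(data, outcome, candidates, forced = character()) {
  stopifnot(is.data.frame(data), is_string(outcome))
  if (length(intersect(candidates, forced)))
    stop("candidates and forced terms must be disjoint", call. = FALSE)
  cols <- c(outcome, forced, candidates)
  d <- data[complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  if (nrow(d) <= length(forced) + 2L)
    stop("too few complete rows for stepwise selection", call. = FALSE)

  current <- character()  # selected candidates, inclusion order
  cur_fit <- fit_ols(d, outcome, forced)
  trace <- data.frame(step = 0L, action = "start", term = NA_character_,
                      aic = cur_fit$aic)
  step_i <- 0L
  repeat {
    moves <- list()
    for (tm in current)  # deletions first: preferred at ties (smaller model)
      moves[[length(moves) + 1L]] <- list(action = "drop", term = tm,
                                          rank = match(tm, candidates))
    for (tm in setdiff(candidates, current))
      moves[[length(moves) + 1L]] <- list(action = "add", term = tm,
                                          rank = match(tm, candidates))
    if (length(moves) == 0L) break
    aics <- vapply(moves, function(mv) {
      terms <- if (mv$action == "add") c(current, mv$term)
               else setdiff(current, mv$term)
      tryCatch(fit_ols(d, outcome, c(forced, terms))$aic,
               error = function(e) Inf)
    }, numeric(1))
    ord <- order(aics,
                 vapply(moves, function(m) m$action != "drop", logical(1)),
                 vapply(moves, `[[`, numeric(1), "rank"))
    best <- ord[1L]
    if (!(aics[best] < cur_fit$aic - 1e-8)) break
    mv <- moves[[best]]
    current <- if (mv$action == "add") c(current, mv$term)
               else setdiff(current, mv$term)
    cur_fit <- fit_ols(d, outcome, c(forced, current))
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, action = mv$action,
                                     term = mv$term, aic = cur_fit$aic))
  }
  structure(c(unclass(cur_fit),
              list(forced = forced, selected = current, trace = trace)),
            class = c("stepwise_lm", "view_ols"))
}

#' @export
print.stepwise_lm <- function(x, digits = 3, ...) {
  cat("Bidirectional AIC-stepwise model for '", x$outcome, "'\n", sep = "")
  cat("forced:   ",
      if (length(x$forced)) paste(x$forced, collapse = ", ") else "(none)",
      "\n", sep = "")
  cat("selected: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n", sep = "")
  NextMethod()
}

#' @export
summary.stepwise_lm <- function(object, ...) {
  list(table = object$table, forced = object$forced,
       selected = object$selected, trace = object$trace,
       adj_r2 = object$adj_r2, aic = object$aic, n = object$n)
}
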