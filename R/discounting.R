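# Adaptive delay-discounting staircase, indifference points, and AUC.

#' Delays of the discounting task, in days
#'
#' Seven delays: six hours, one day, one week, one month, three months, one
#' year, five years (0.25, 1, 7, 30, 91, 365, 1825 days).
#'
#' @return Named numeric vector of length 7.
#' @export
discounting_delays <- function() {
  c(`6h` = 0.25, `1d` = 1, `1w` = 7, `1m` = 30, `3m` = 91,
    `1y` = 365, `5y` = 1825)
}

#' Initialize a staircase block
#'
#' Each block opens with the choice between EUR 50 immediately and EUR 100
#' at the block's delay; six titration trials follow.
#'
#' @param delay_days Delay of the block in days (one of
#'   [discounting_delays()]; only recorded, not used by the titration).
#' @return A `staircase_state` list: `delay_days`, `trial` (1-based),
#'   `offer` (current immediate offer, EUR), `delayed_amount` (100).
#' @export
staircase_init <- function(delay_days = 0.25) {
  structure(list(delay_days = delay_days, trial = 1L, offer = 50,
                 delayed_amount = 100),
            class = "staircase_state")
}

#' Advance the staircase by one choice
#'
#' Choosing the immediate reward halves the remaining step and lowers the
#' next offer; choosing the delayed reward raises it. The adjustment after
#' trial `t` is `100 / 2^(t+1)` EUR — 25, 12.5, 6.25, 3.125, 1.5625 — so the
#' offers titrate toward the participant's indifference point with
#' increasingly smaller changes.
#'
#' @param state A `staircase_state`.
#' @param choice `"immediate"` or `"delayed"`.
#' @return The next `staircase_state` (trial incremented, offer adjusted).
#' @examples
#' s <- staircase_init()
#' staircase_step(s, "immediate")$offer  # 25
#' staircase_step(s, "delayed")$offer    # 75
#' @export
staircase_step <- function(state, choice = c("immediate", "delayed")) {
  stopifnot(inherits(state, "staircase_state"))
  choice <- match.arg(choice)
  if (state$trial > 6L)
    stop("a staircase block has exactly 6 trials", call. = FALSE)
  adj <- state$delayed_amount / 2^(state$trial + 1L)
  state$offer <- state$offer + if (choice == "immediate") -adj else adj
  state$trial <- state$trial + 1L
  state
}

#' Indifference point implied by one block of choices
#'
#' Runs the six recorded choices through the staircase and returns the
#' immediate amount that would be offered on a hypothetical seventh trial
#' (the limit of the titration): the final offer plus or minus
#' `100 / 2^7 = 0.78125` EUR.
#'
#' @param choices Character vector of exactly 6 choices
#'   (`"immediate"`/`"delayed"`).
#' @param delay_days Delay of the block, in days.
#' @return Indifference point in EUR, inside `(0, 100)`.
#' @export
indifference_point <- function(choices, delay_days = 0.25) {
  if (length(choices) != 6L)
    stop("exactly 6 choices per block are required", call. = FALSE)
  s <- staircase_init(delay_days)
  for (ch in choices) s <- staircase_step(s, ch)
  # The sixth transition applies the final half-step of 100 / 2^7, so the
  # state's offer is already the hypothetical trial-7 offer.
  s$offer
}

#' Normalized area under the indifference-point curve
#'
#' Delays are normalized by the maximum delay (1825 days) and indifference
#' points by the delayed amount (EUR 100); the area under the resulting
#' curve is accumulated trapezoid by trapezoid, anchored at `(0, 1)` because
#' the delayed reward is worth its face value at zero delay. The AUC lies in
#' `[0, 1]`; larger values mean less discounting by delay, i.e. less
#' impulsive decision-making.
#'
#' @param indiff Numeric vector of 7 indifference points (EUR, in
#'   `[0, 100]`), ordered by increasing delay.
#' @param delays Delays in days; default [discounting_delays()].
#' @param anchor Include the zero-delay anchor point `(0, 1)`; set `FALSE`
#'   to integrate only between observed delays.
#' @return AUC in `[0, 1]`.
#' @examples
#' discounting_auc(rep(100, 7))  # 1: no discounting at all
#' @export
discounting_auc <- function(indiff, delays = discounting_delays(),
                            anchor = TRUE) {
  if (length(indiff) != 7L || anyNA(indiff))
    stop("7 indifference points are required", call. = FALSE)
  if (any(indiff < 0) || any(indiff > 100))
    stop("indifference points must lie in [0, 100] EUR", call. = FALSE)
  x <- delays / max(delays)
  y <- indiff / 100
  if (anchor) { x <- c(0, x); y <- c(1, y) }
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Score a cohort's delay-discounting choice log
#'
#' @param choices Data frame with columns `participant_id`, `delay_label`
#'   (names of [discounting_delays()]), `trial_index` (1-6), `choice`
#'   (`"immediate"`/`"delayed"`).
#' @param anchor Passed to [discounting_auc()].
#' @return Data frame: one row per participant with the 7 indifference
#'   points (`ip_6h`, ..., `ip_5y`) and `auc`.
#' @export
score_choice_log <- function(choices, anchor = TRUE) {
  need <- c("participant_id", "delay_label", "trial_index", "choice")
  if (!all(need %in% names(choices)))
    stop("choice log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  delays <- discounting_delays()
  rows <- lapply(split(choices, choices$participant_id), function(d) {
    ips <- vapply(names(delays), function(lbl) {
      blk <- d[d$delay_label == lbl, , drop = FALSE]
      blk <- blk[order(blk$trial_index), , drop = FALSE]
      indifference_point(as.character(blk$choice), delays[[lbl]])
    }, numeric(1))
    data.frame(participant_id = d$participant_id[1L],
               as.list(setNames(ips, paste0("ip_", names(delays)))),
               auc = discounting_auc(unname(ips), anchor = anchor),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
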