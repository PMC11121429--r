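# State negative-affect composite from the 20-item state scale.

#' Facet labels of the 20 state items
#'
#' The state scale has four facets of five items each: emotionality and
#' worry (anxiety), euthymia and dysthymia (depression). Items are laid out
#' in that order.
#'
#' @return Character vector of length 20.
#' @export
stadi_facets <- function() {
  rep(c("emotionality", "worry", "euthymia", "dysthymia"), each = 5L)
}

#' Score the state negative-affect composite
#'
#' Each of the 20 state items is answered on 1 ("not at all") to 4 ("very
#' much so"). Euthymia items are reversely scored (a response r becomes
#' 5 - r), then the
#' state anxiety and state depression subscales are summed into one
#' composite; higher scores reflect higher state negative affect. The
#' composite ranges from 20 to 80.
#'
#' @param responses Integer vector of 20 raw item responses in 1-4, ordered
#'   as [stadi_facets()].
#' @return Integer composite in `[20, 80]`.
#' @examples
#' score_stadi(rep(2L, 20))  # 15*2 + 5*3 = 45
#' @export
score_stadi <- function(responses) {
  if (length(responses) != 20L || anyNA(responses))
    stop("exactly 20 non-missing item responses are required", call. = FALSE)
  if (!all(responses == as.integer(responses)) ||
      any(responses < 1L) || any(responses > 4L))
    stop("item responses must be integers in 1..4", call. = FALSE)
  r <- as.integer(responses)
  rev_idx <- stadi_facets() == "euthymia"
  r[rev_idx] <- 5L - r[rev_idx]
  sum(r)
}
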