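#' Gray-level Shannon entropy of an image
#'
#' The image is converted to 8-bit grayscale (BT.601 luma) and the Shannon
#' entropy `-sum(p * log2(p))` of its 256-bin histogram is returned, in bits.
#' A constant image has entropy 0; a histogram that is exactly uniform over
#' all 256 levels attains the maximum of 8. Complex, randomly arranged scenes
#' sit near the top of the range, which is why entropy is used as an image
#' randomness index.
#'
#' @param img `H x W x 3` RGB array, values 0-255.
#' @return Entropy in bits, in `[0, 8]`.
#' @export
img_entropy <- function(img) {
  g <- pmin(pmax(round(luma(img)), 0), 255)
  p <- tabulate(g + 1L, nbins = 256L) / length(g)
  p <- p[p > 0]
  -sum(p * log2(p))
}
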