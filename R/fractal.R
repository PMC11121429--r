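# Box-counting fractal dimension on Otsu-binarized images.

#' Otsu threshold of a grayscale matrix
#'
#' Exhaustive between-class variance maximization over the 256-bin histogram
#' of an 8-bit grayscale plane. Returns the threshold `t` such that the
#' classes are `x <= t` and `x > t`.
#'
#' @param g Numeric matrix with values in 0-255.
#' @return Threshold in 0-254, or `NA` if the image has fewer than two
#'   distinct gray levels.
#' @export
otsu_threshold <- function(g) {
  h <- tabulate(pmin(pmax(round(g), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  if (sum(p > 0) < 2L) return(NA_real_)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- -Inf
  which.max(bcv[1:255]) - 1
}

#' Count occupied boxes of a binary mask
#'
#' For each box size `s`, overlays the origin-anchored `s x s` grid and
#' counts boxes containing at least one foreground pixel.
#'
#' @param mask Logical matrix (foreground = `TRUE`).
#' @param sizes Integer vector of box sizes (each at least 2).
#' @return Integer vector of box counts, one per size.
#' @export
box_counts <- function(mask, sizes) {
  stopifnot(is.logical(mask), is.matrix(mask), all(sizes >= 2))
  idx <- which(mask, arr.ind = TRUE)
  vapply(sizes, function(s) {
    if (nrow(idx) == 0L) return(0L)
    bi <- (idx[, 1L] - 1L) %/% s
    bj <- (idx[, 2L] - 1L) %/% s
    nbj <- (ncol(mask) - 1L) %/% s + 1L
    length(unique(bi * nbj + bj))
  }, integer(1))
}

#' Box-counting dimension of a binary mask
#'
#' Least-squares slope of `log N(s)` against `log s` over the supplied box
#' sizes, negated. A filled region approaches 2, a thin line 1; estimates
#' outside `[1, 2]` are legal but flagged, since natural-scene values are
#' expected in that range.
#'
#' @param mask Logical matrix.
#' @param sizes Box sizes; default is the dyadic ladder
#'   `2, 4, ..., floor(min(dim(mask)) / 4)`.
#' @return A list: `fd` (estimate, `NA` if the mask is empty), `sizes`,
#'   `counts`, and logical flags `degenerate` (empty mask) and
#'   `out_of_range` (estimate outside `[1, 2]`).
#' @export
box_count_dimension <- function(mask, sizes = NULL) {
  if (is.null(sizes)) sizes <- dyadic_sizes(dim(mask))
  if (length(sizes) < 3L)
    stop("box counting needs at least 3 usable box sizes ",
         "(image at least 32 px on its smaller side)", call. = FALSE)
  n <- box_counts(mask, sizes)
  if (all(n == 0L))
    return(list(fd = NA_real_, sizes = sizes, counts = n,
                degenerate = TRUE, out_of_range = TRUE))
  ls <- log(sizes); ln <- log(n)
  slope <- sum((ls - mean(ls)) * (ln - mean(ln))) / sum((ls - mean(ls))^2)
  fd <- -slope
  list(fd = fd, sizes = sizes, counts = n, degenerate = FALSE,
       out_of_range = fd < 1 || fd > 2)
}

dyadic_sizes <- function(d) {
  smax <- min(d) %/% 4L
  s <- 2L
  out <- integer(0)
  while (s <= smax) { out <- c(out, s); s <- s * 2L }
  out
}

#' Box-counting fractal dimension of an image
#'
#' Binarizes the BT.601 luma plane at the Otsu threshold (foreground side
#' set by `cfg$fd_foreground`; the default takes the dark class, i.e.
#' structure against a bright sky) and estimates the box-counting dimension.
#'
#' @param img `H x W x 3` RGB array, values 0-255.
#' @param cfg An [extraction_config()].
#' @return As [box_count_dimension()]; `fd` is `NA` with
#'   `degenerate = TRUE` when binarization yields no foreground (e.g. a
#'   constant image).
#' @export
fractal_dimension <- function(img, cfg = extraction_config()) {
  g <- luma(img)
  thr <- otsu_threshold(g)
  if (is.na(thr)) {
    sizes <- if (is.null(cfg$box_sizes)) dyadic_sizes(dim(g)) else cfg$box_sizes
    return(list(fd = NA_real_, sizes = sizes,
                counts = rep(0L, length(sizes)),
                degenerate = TRUE, out_of_range = TRUE))
  }
  mask <- if (cfg$fd_foreground == "dark") g <= thr else g > thr
  box_count_dimension(mask, cfg$box_sizes %||%
                        dyadic_sizes(dim(mask)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
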