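#' Convert an RGB image to hue/saturation/value planes
#'
#' Hue is mapped from the standard 0-360 degree color wheel to radians in
#' `(-pi, pi]`, which places red at 0 and cyan at +/- pi; because hue is
#' circular the two ends meet. Saturation and value follow the hexcone model
#' and lie in `[0, 1]`. Achromatic pixels (saturation 0) carry hue 0 by
#' convention of [grDevices::rgb2hsv()]; hue statistics exclude them, since
#' their hue is undefined.
#'
#' @param img `H x W x 3` RGB array, values 0-255.
#' @return An object of class `hsv_image`: a list with matrices `hue`
#'   (radians), `sat`, `val`, and the image `dim`.
#' @export
to_hsv <- function(img) {
  check_rgb(img)
  d <- dim(img)[1:2]
  m <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
             as.vector(img[, , 3L]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  hue <- hsv[1L, ] * 2 * pi
  hue <- ifelse(hue > pi, hue - 2 * pi, hue)  # wrap to (-pi, pi]
  structure(list(hue = matrix(hue, d[1L], d[2L]),
                 sat = matrix(hsv[2L, ], d[1L], d[2L]),
                 val = matrix(hsv[3L, ], d[1L], d[2L]),
                 dim = d),
            class = "hsv_image")
}

#' Circular mean and angular deviation of image hue
#'
#' Hue is an angle, so its mean is the direction of the mean unit vector over
#' all chromatic pixels and its spread is the angular deviation
#' `sqrt(2 * (1 - R))`, where `R` is the mean resultant length. The angular
#' deviation lies in `[0, sqrt(2)]`. Achromatic pixels (saturation exactly 0)
#' are excluded; if no chromatic pixel exists, or the hue distribution is
#' (near-)antipodal so that `R` is essentially 0, the mean is unstable and the
#' result is flagged rather than silently returned as 0.
#'
#' @param hsv An `hsv_image` from [to_hsv()].
#' @return A list: `mean` (radians, `NA` if undefined), `sd` (angular
#'   deviation), `R` (mean resultant length), `n_chromatic`, and logical
#'   flags `achromatic` and `unstable`.
#' @export
hue_stats <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_image"))
  keep <- hsv$sat > 0
  th <- hsv$hue[keep]
  if (length(th) == 0L)
    return(list(mean = NA_real_, sd = NA_real_, R = NA_real_,
                n_chromatic = 0L, achromatic = TRUE, unstable = TRUE))
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  unstable <- R < 1e-8
  list(mean = if (unstable) NA_real_ else atan2(S, C),
       sd = sqrt(2 * (1 - R)),
       R = R, n_chromatic = length(th),
       achromatic = FALSE, unstable = unstable)
}

#' Mean and spread of saturation and brightness
#'
#' Plain arithmetic means and population standard deviations (divisor `n`) of
#' the saturation and value planes, all in `[0, 1]`.
#'
#' @param hsv An `hsv_image` from [to_hsv()].
#' @return Named list `sat_mean`, `sat_sd`, `bright_mean`, `bright_sd`.
#' @export
channel_stats <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_image"))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(sat_mean = mean(hsv$sat), sat_sd = pop_sd(hsv$sat),
       bright_mean = mean(hsv$val), bright_sd = pop_sd(hsv$val))
}

#' Fraction of pixels within a hue band
#'
#' A pixel counts toward the ratio when its hue falls in the half-open band
#' `[lo, hi)` (degrees on the 0-360 wheel; bands may wrap past 360) and it is
#' chromatic enough: saturation at least `s_min` and value at least `v_min`.
#' The denominator is all pixels of the image.
#'
#' @param img `H x W x 3` RGB array.
#' @param band Two hue angles in degrees, `[lo, hi)`.
#' @param s_min,v_min Chromaticity thresholds.
#' @return Ratio in `[0, 1]`.
#' @examples
#' g <- array(0L, c(4, 4, 3)); g[, , 2] <- 255L
#' color_ratio(g, c(70, 170))  # 1: a saturated pure-green image
#' @export
color_ratio <- function(img, band, s_min = 0.15, v_min = 0.10) {
  check_rgb(img)
  if (length(band) != 2L || band[1L] == band[2L])
    stop("hue band must be two distinct angles in degrees", call. = FALSE)
  hsv <- to_hsv(img)
  mean(hue_in_band(hsv$hue, band) & hsv$sat >= s_min & hsv$val >= v_min)
}

# Band membership for hue in radians (-pi, pi]; band in degrees, may wrap.
hue_in_band <- function(hue_rad, band_deg) {
  deg <- (hue_rad * 180 / pi) %% 360
  lo <- band_deg[1L] %% 360; hi <- band_deg[2L] %% 360
  if (lo < hi) deg >= lo & deg < hi else deg >= lo | deg < hi
}

#' Sky pixel ratio from a sky-masked image
#'
#' Consumes the companion image in which everything that is not sky has been
#' blackened, and returns the fraction of all pixels that are sky: blue-band
#' pixels plus grey/white pixels (overcast sky: saturation at most
#' `grey_s_max` and value at least `grey_v_min`). Mask-black pixels (value
#' below `mask_black_v`) never count. The denominator is all pixels of the
#' image, so the ratio is directly the sky area fraction of the view.
#'
#' @param masked Sky-masked `H x W x 3` RGB array.
#' @param cfg An [extraction_config()].
#' @param original Optional paired original image; if supplied, dimensions
#'   are checked to match.
#' @return Ratio in `[0, 1]`.
#' @export
sky_ratio <- function(masked, cfg = extraction_config(), original = NULL) {
  check_rgb(masked, "masked")
  if (!is.null(original)) {
    check_rgb(original, "original")
    if (!identical(dim(masked)[1:2], dim(original)[1:2]))
      stop("sky mask dimensions do not match the original image",
           call. = FALSE)
  }
  hsv <- to_hsv(masked)
  not_black <- hsv$val >= cfg$mask_black_v
  blue <- hue_in_band(hsv$hue, cfg$blue_band) &
    hsv$sat >= cfg$s_min & hsv$val >= cfg$v_min
  greywhite <- hsv$sat <= cfg$grey_s_max & hsv$val >= cfg$grey_v_min
  mean(not_black & (blue | greywhite))
}
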