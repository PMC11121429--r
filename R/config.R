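#' Feature-extraction configuration
#'
#' Bundles every tunable threshold of the low-level visual feature extractor.
#' The defaults are the package's calibration for schematic and photographic
#' window views; none of them is dictated by the feature definitions
#' themselves, so all are overridable (also via the YAML run config).
#'
#' @param green_band Hue band (degrees, `[lo, hi)`) classified as green.
#' @param blue_band Hue band (degrees) classified as blue.
#' @param s_min,v_min Minimum saturation / value for a pixel to count as
#'   chromatic in the green/blue ratio classifiers.
#' @param grey_s_max,grey_v_min Grey/white sky classifier: saturation at most
#'   `grey_s_max` and value at least `grey_v_min`.
#' @param mask_black_v Value below which a pixel of a sky-masked image is
#'   treated as mask black (manually blackened, i.e. not sky).
#' @param edge_sigma Gaussian smoothing standard deviation (pixels) of the
#'   Canny detector.
#' @param edge_low,edge_high Hysteresis thresholds, expressed as fractions of
#'   the gradient response to a full black-to-white step, so they are
#'   absolute: a featureless noisy image yields an empty edge map.
#' @param line_vote_frac Hough vote threshold as a fraction of the image
#'   diagonal.
#' @param line_minlen_frac Minimum supported length of an accepted line, as a
#'   fraction of the diagonal.
#' @param line_tol Distance (pixels) within which an edge pixel is assigned
#'   to a detected line.
#' @param line_gap Largest gap (pixels, along the line) bridged inside one
#'   straight segment; larger gaps split the support into separate
#'   segments, each of which must reach the minimum length on its own.
#' @param box_sizes Box-counting sizes; `NULL` selects the dyadic ladder
#'   `2, 4, ..., floor(min(H, W) / 4)` per image.
#' @param fd_foreground Which side of the Otsu threshold is foreground for
#'   box counting: `"dark"` (structure against bright sky) or `"bright"`.
#' @param resize_max Optional maximum image dimension; larger images are
#'   block-averaged down before extraction. `NULL` (default) disables
#'   resizing. Edge density is resolution dependent, so resizing matters for
#'   cross-camera comparability.
#' @return An object of class `extraction_config` (a validated list).
#' @export
extraction_config <- function(green_band = c(70, 170),
                              blue_band = c(170, 260),
                              s_min = 0.15, v_min = 0.10,
                              grey_s_max = 0.15, grey_v_min = 0.55,
                              mask_black_v = 0.02,
                              edge_sigma = 1.4,
                              edge_low = 0.10, edge_high = 0.20,
                              line_vote_frac = 0.05,
                              line_minlen_frac = 0.10,
                              line_tol = 1,
                              line_gap = 1.5,
                              box_sizes = NULL,
                              fd_foreground = c("dark", "bright"),
                              resize_max = NULL) {
  cfg <- list(green_band = as.numeric(green_band),
              blue_band = as.numeric(blue_band),
              s_min = s_min, v_min = v_min,
              grey_s_max = grey_s_max, grey_v_min = grey_v_min,
              mask_black_v = mask_black_v,
              edge_sigma = edge_sigma,
              edge_low = edge_low, edge_high = edge_high,
              line_vote_frac = line_vote_frac,
              line_minlen_frac = line_minlen_frac,
              line_tol = line_tol,
              line_gap = line_gap,
              box_sizes = box_sizes,
              fd_foreground = match.arg(fd_foreground),
              resize_max = resize_max)
  validate_extraction_config(cfg)
  class(cfg) <- "extraction_config"
  cfg
}

validate_extraction_config <- function(cfg) {
  for (band in c("green_band", "blue_band")) {
    b <- cfg[[band]]
    if (length(b) != 2L || any(b < 0) || any(b >= 360))
      stop(band, " must be two hue angles within [0, 360)", call. = FALSE)
    if (b[1L] == b[2L])
      stop(band, " is empty", call. = FALSE)
  }
  thr <- c("s_min", "v_min", "grey_s_max", "grey_v_min", "mask_black_v",
           "edge_low", "edge_high", "line_vote_frac", "line_minlen_frac")
  for (nm in thr) {
    x <- cfg[[nm]]
    if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 1)
      stop(nm, " must be a single number in [0, 1]", call. = FALSE)
  }
  if (cfg$edge_low > cfg$edge_high)
    stop("edge_low must not exceed edge_high", call. = FALSE)
  if (cfg$edge_sigma <= 0) stop("edge_sigma must be positive", call. = FALSE)
  if (cfg$line_tol < 0) stop("line_tol must be non-negative", call. = FALSE)
  if (cfg$line_gap < 0) stop("line_gap must be non-negative", call. = FALSE)
  if (!is.null(cfg$box_sizes)) {
    s <- cfg$box_sizes
    if (any(s < 2) || any(diff(s) <= 0))
      stop("box_sizes must be strictly increasing and >= 2", call. = FALSE)
  }
  invisible(cfg)
}

# Merge a named list of overrides (e.g. parsed from YAML) into the defaults.
as_extraction_config <- function(x) {
  if (inherits(x, "extraction_config")) return(x)
  if (is.null(x)) return(extraction_config())
  stopifnot(is.list(x))
  do.call(extraction_config, x)
}
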