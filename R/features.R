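# The 14-feature extractor and per-participant aggregation.

#' Canonical feature names, in output column order
#'
#' Order follows the field's customary listing: hue moments, saturation and
#' brightness moments, the three pixel ratios, the three edge densities,
#' entropy, fractal dimension.
#'
#' @return Character vector of length 14.
#' @export
feature_names <- function() {
  c("hue_mean", "hue_sd", "sat_mean", "sat_sd", "bright_mean", "bright_sd",
    "green_ratio", "blue_ratio", "sky_ratio",
    "edge_density", "straight_edge_density", "nonstraight_edge_density",
    "entropy", "fractal_dim")
}

#' Extract all 14 low-level visual features from one view image
#'
#' Computes circular hue statistics, saturation/brightness moments,
#' green/blue pixel ratios, the sky pixel ratio (from the companion
#' sky-masked image), Canny edge density split into straight and
#' non-straight parts, gray-level entropy, and the box-counting fractal
#' dimension. Deterministic: identical input and configuration give a
#' bit-identical result.
#'
#' Objective brightness (`bright_mean`, `bright_sd`) is computed but flagged
#' unreliable for ecological photographs in the result's `flags`: apparent
#' brightness varies with camera settings and time of day, so downstream
#' analyses exclude it by default.
#'
#' @param img `H x W x 3` RGB array, values 0-255 (at least 8 px per side).
#' @param masked Optional companion sky-masked image (same dimensions,
#'   non-sky blackened). If `NULL`, `sky_ratio` is `NA`.
#' @param cfg An [extraction_config()].
#' @return An object of class `feature_vector`: a named numeric vector of
#'   the 14 features with a `flags` attribute (named logical vector:
#'   `hue_undefined`, `hue_unstable`, `fd_degenerate`, `fd_out_of_range`,
#'   `brightness_unreliable`, `sky_missing`).
#' @export
extract_features <- function(img, masked = NULL, cfg = extraction_config()) {
  check_rgb(img)
  if (any(dim(img)[1:2] < 8L))
    stop("image must be at least 8 x 8 px for feature validity",
         call. = FALSE)
  if (!is.null(cfg$resize_max)) {
    img <- resize_image(img, cfg$resize_max)
    if (!is.null(masked)) masked <- resize_image(masked, cfg$resize_max)
  }
  hsv <- to_hsv(img)
  hs <- hue_stats(hsv)
  cs <- channel_stats(hsv)
  sky <- if (is.null(masked)) NA_real_ else sky_ratio(masked, cfg, img)
  ed <- edge_densities(edge_map(img, cfg), cfg)
  fd <- fractal_dimension(img, cfg)
  v <- c(hue_mean = if (is.na(hs$mean)) NA_real_ else hs$mean,
         hue_sd = hs$sd,
         sat_mean = cs$sat_mean, sat_sd = cs$sat_sd,
         bright_mean = cs$bright_mean, bright_sd = cs$bright_sd,
         green_ratio = color_ratio(img, cfg$green_band, cfg$s_min, cfg$v_min),
         blue_ratio = color_ratio(img, cfg$blue_band, cfg$s_min, cfg$v_min),
         sky_ratio = sky,
         edge_density = ed$edge_density,
         straight_edge_density = ed$straight_edge_density,
         nonstraight_edge_density = ed$nonstraight_edge_density,
         entropy = img_entropy(img),
         fractal_dim = fd$fd)
  structure(v[feature_names()],
            flags = c(hue_undefined = hs$achromatic,
                      hue_unstable = hs$unstable,
                      fd_degenerate = fd$degenerate,
                      fd_out_of_range = fd$out_of_range,
                      brightness_unreliable = TRUE,
                      sky_missing = is.null(masked)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, digits = 4, ...) {
  cat("Low-level visual features (14):\n")
  print(round(unclass(x), digits))
  fl <- attr(x, "flags")
  on <- names(fl)[fl & names(fl) != "brightness_unreliable"]
  if (length(on)) cat("flags:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Average feature vectors across a participant's windows
#'
#' Unweighted arithmetic mean of each feature over all window images of one
#' participant, yielding one value per feature per participant. The mean hue
#' is averaged circularly (direction of the summed unit vectors), since hue
#' is an angle: hues of +3 and -3 radians average near +/- pi, not 0.
#'
#' @param features List of `feature_vector` objects (length at least 1).
#' @return A `feature_vector` of per-participant averages (a feature that is
#'   `NA` for some image yields `NA`, except `hue_mean`, which averages the
#'   defined entries).
#' @export
aggregate_participant <- function(features) {
  if (length(features) == 0L) stop("no feature vectors to aggregate",
                                   call. = FALSE)
  stopifnot(all(vapply(features, inherits, logical(1), "feature_vector")))
  m <- do.call(rbind, lapply(features, unclass))
  out <- colMeans(m)
  th <- m[, "hue_mean"]
  th <- th[!is.na(th)]
  out["hue_mean"] <- if (length(th) == 0L) NA_real_ else
    atan2(mean(sin(th)), mean(cos(th)))
  flags <- Reduce(`|`, lapply(features, attr, "flags"))
  structure(out, flags = flags, class = "feature_vector")
}

# Block-average an image so its larger dimension is at most max_dim.
resize_image <- function(img, max_dim) {
  d <- dim(img)[1:2]
  f <- ceiling(max(d) / max_dim)
  if (f <= 1L) return(img)
  nr <- d[1L] %/% f; nc <- d[2L] %/% f
  img <- img[seq_len(nr * f), seq_len(nc * f), , drop = FALSE]
  out <- array(0, c(nr, nc, 3L))
  for (ch in 1:3) {
    m <- img[, , ch]
    m <- rowsum(m, rep(seq_len(nr), each = f)) / f
    m <- t(rowsum(t(m), rep(seq_len(nc), each = f)) / f)
    out[, , ch] <- m
  }
  round(out)
}

#' Extract features for every image of a cohort directory
#'
#' Walks `cohort_dir/<participant>/window_<j>.png` (PNG or JPEG), pairs each
#' image with its `<stem>_skymask.png` companion when present, and returns
#' per-image features plus per-participant averages. A missing mask yields a
#' warning and `NA` sky ratio for that image.
#'
#' @param cohort_dir Dataset root (one subdirectory per participant).
#' @param cfg An [extraction_config()].
#' @return List with data frames `per_image` (participant_id, image, the 14
#'   feature columns) and `per_participant` (participant_id, n_images, the
#'   14 feature columns).
#' @export
extract_cohort_features <- function(cohort_dir, cfg = extraction_config()) {
  parts <- sort(list.dirs(cohort_dir, recursive = FALSE))
  if (length(parts) == 0L)
    stop("no participant directories under ", cohort_dir, call. = FALSE)
  per_image <- list(); per_part <- list()
  for (pd in parts) {
    pid <- basename(pd)
    imgs <- sort(list.files(pd, pattern = "^window_\\d+\\.(png|jpe?g)$",
                            full.names = TRUE))
    if (length(imgs) == 0L) next
    fvs <- list()
    for (f in imgs) {
      mask_path <- find_sky_mask(f)
      masked <- if (is.na(mask_path)) {
        warning("no sky mask for ", f, "; sky_ratio set to NA",
                call. = FALSE)
        NULL
      } else read_view_image(mask_path)
      fvs[[f]] <- extract_features(read_view_image(f), masked, cfg)
    }
    per_image[[pid]] <- data.frame(participant_id = pid,
                                   image = basename(imgs),
                                   do.call(rbind, lapply(fvs, unclass)),
                                   row.names = NULL)
    agg <- aggregate_participant(fvs)
    per_part[[pid]] <- data.frame(participant_id = pid,
                                  n_images = length(fvs),
                                  as.data.frame(t(unclass(agg))),
                                  row.names = NULL)
  }
  list(per_image = do.call(rbind, c(per_image, list(make.row.names = FALSE))),
       per_participant = do.call(rbind, c(per_part,
                                          list(make.row.names = FALSE))))
}
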