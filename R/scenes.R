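# Procedural window-view scenes with exact ground truth.
#
# Scenes are schematic, not photorealistic: the extractor consumes pixel
# statistics, not semantics, and schematic rendering lets every ground-truth
# area fraction be exact. A scene stacks a sky band (blue gradient or
# overcast grey), a background wall, rectilinear buildings with window grids
# (straight edges), and green foliage from midpoint-displacement noise
# (irregular outlines, high fractal dimension).

#' Specify a synthetic window-view scene
#'
#' @param p_sky Target sky area fraction of the whole image, `[0, 1]`.
#' @param sky_kind `"blue"` or `"overcast"` (grey/white) sky.
#' @param p_green Target green (foliage) fraction of the whole image.
#' @param built_density Density of built structure in the non-sky region,
#'   `[0, 1]` (controls the number and size of building rectangles).
#' @param foliage_roughness Persistence of the midpoint-displacement noise
#'   in `(0, 1)`; larger values give more ragged foliage outlines.
#' @param width,height Image size in pixels.
#' @param seed Integer seed; the render is deterministic given the spec.
#' @return Object of class `scene_spec` (validated list).
#' @export
scene_spec <- function(p_sky = 0.25, sky_kind = c("blue", "overcast"),
                       p_green = 0.3, built_density = 0.5,
                       foliage_roughness = 0.8,
                       width = 96L, height = 96L, seed = 1L) {
  sky_kind <- match.arg(sky_kind)
  if (p_sky < 0 || p_sky > 1 || p_green < 0 || p_green > 1)
    stop("p_sky and p_green must lie in [0, 1]", call. = FALSE)
  if (p_sky + p_green > 1)
    stop("infeasible scene: p_sky + p_green > 1", call. = FALSE)
  stopifnot(built_density >= 0, built_density <= 1,
            width >= 32, height >= 32)
  structure(list(p_sky = p_sky, sky_kind = sky_kind, p_green = p_green,
                 built_density = built_density,
                 foliage_roughness = foliage_roughness,
                 width = as.integer(width), height = as.integer(height),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Midpoint-displacement (diamond-square) noise field covering at least
# n x n; returns the cropped h x w matrix, values roughly centred on 0.
midpoint_noise <- function(h, w, roughness) {
  k <- ceiling(log2(max(h, w, 2)))
  n <- 2L^k + 1L
  f <- matrix(0, n, n)
  f[c(1L, n), c(1L, n)] <- rnorm(4)
  step <- n - 1L
  amp <- 1
  while (step > 1L) {
    half <- step %/% 2L
    # diamond
    ci <- seq(1L + half, n, by = step)
    for (i in ci) for (j in ci)
      f[i, j] <- mean(c(f[i - half, j - half], f[i - half, j + half],
                        f[i + half, j - half], f[i + half, j + half])) +
        rnorm(1, 0, amp)
    # square
    for (i in seq(1L, n, by = half)) {
      off <- if (((i - 1L) %/% half) %% 2L == 0L) half + 1L else 1L
      for (j in seq(off, n, by = step)) {
        nb <- c(if (i - half >= 1L) f[i - half, j],
                if (i + half <= n) f[i + half, j],
                if (j - half >= 1L) f[i, j - half],
                if (j + half <= n) f[i, j + half])
        f[i, j] <- mean(nb) + rnorm(1, 0, amp)
      }
    }
    step <- half
    amp <- amp * roughness
  }
  f[seq_len(h), seq_len(w)]
}

#' Render a synthetic scene
#'
#' Produces the RGB image, its sky-masked companion (everything that is not
#' sky blackened), a per-pixel label matrix, and the realized ground-truth
#' area fractions. Foliage is placed on the highest-noise pixels of the
#' non-sky region so the realized green fraction matches the target to
#' within one pixel.
#'
#' @param spec A [scene_spec()].
#' @return List: `image` (`H x W x 3`, 0-255), `masked` (same, non-sky
#'   black), `labels` (`H x W` character matrix: `"sky"`, `"green"`,
#'   `"built"`, `"bg"`), `realized` (named fractions `sky`, `green`,
#'   `built`), `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, render_scene(spec))
}

render_scene <- function(spec) {
  h <- spec$height; w <- spec$width
  img <- array(0, c(h, w, 3L))
  labels <- matrix("bg", h, w)
  n_sky <- round(spec$p_sky * h)

  # background wall: muted warm beige with mild texture
  jit <- matrix(rnorm(h * w, 0, 4), h, w)
  img[, , 1L] <- 180 + jit; img[, , 2L] <- 170 + jit; img[, , 3L] <- 152 + jit

  # buildings: rectangles rising from the bottom, with dark window grids
  n_b <- round(spec$built_density * 4)
  if (n_b > 0 && n_sky < h) {
    for (b in seq_len(n_b)) {
      bw <- sample(seq(max(6L, w %/% 8L), max(8L, w %/% 3L)), 1L)
      x0 <- sample(seq_len(max(1L, w - bw)), 1L)
      top <- sample(seq(n_sky + 1L, max(n_sky + 1L, h - h %/% 4L)), 1L)
      shade <- runif(1, 120, 165)
      rows <- top:h; cols <- x0:(x0 + bw - 1L)
      for (ch in 1:3) img[rows, cols, ch] <-
        shade + c(-5, -10, -18)[ch] + rnorm(1, 0, 2)
      labels[rows, cols] <- "built"
      # window grid: few large panes, so facades carry long straight edges
      wh <- max(6L, length(rows) %/% 4L); ww <- max(5L, bw %/% 3L)
      if (top + 3L > h - wh || x0 + 3L > x0 + bw - ww - 2L) next
      ri <- seq(top + 3L, h - wh, by = wh + 4L)
      ci <- seq(x0 + 3L, x0 + bw - ww - 2L, by = ww + 4L)
      for (r in ri) for (cc in ci)
        for (ch in 1:3) img[r:(r + wh - 1L), cc:(cc + ww - 1L), ch] <-
          c(60, 62, 68)[ch]
    }
  }

  # foliage: highest-noise non-sky pixels, exactly the target pixel count
  n_green <- round(spec$p_green * h * w)
  if (n_green > 0) {
    f <- midpoint_noise(h, w, spec$foliage_roughness)
    nonsky <- which(row(f) > n_sky)
    if (n_green > length(nonsky)) n_green <- length(nonsky)
    pick <- nonsky[order(f[nonsky], decreasing = TRUE)[seq_len(n_green)]]
    t_ <- (f[pick] - min(f[pick])) / max(1e-9, diff(range(f[pick])))
    # per-pixel shading noise: foliage interiors are speckled, not smooth,
    # so their internal edges are irregular like leaf texture
    t_ <- pmin(pmax(t_ + rnorm(n_green, 0, 0.25), 0), 1)
    col_r <- 30 + 60 * t_; col_g <- 70 + 100 * t_; col_b <- 25 + 35 * t_
    idx <- arrayInd(pick, c(h, w))
    img[cbind(idx, 1L)] <- col_r
    img[cbind(idx, 2L)] <- col_g
    img[cbind(idx, 3L)] <- col_b
    labels[pick] <- "green"
  }

  # sky band on top
  if (n_sky > 0) {
    t_ <- matrix((seq_len(n_sky) - 1L) / max(1L, n_sky - 1L), n_sky, w)
    sj <- matrix(rnorm(n_sky * w, 0, 2), n_sky, w)
    if (spec$sky_kind == "blue") {
      img[seq_len(n_sky), , 1L] <- 112 + 46 * t_ + sj
      img[seq_len(n_sky), , 2L] <- 160 + 42 * t_ + sj
      img[seq_len(n_sky), , 3L] <- 228 + 12 * t_ + sj
    } else {
      g <- 200 + 32 * t_ + sj
      img[seq_len(n_sky), , 1L] <- g
      img[seq_len(n_sky), , 2L] <- g + 2
      img[seq_len(n_sky), , 3L] <- g + 6
    }
    labels[seq_len(n_sky), ] <- "sky"
  }

  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  masked <- img
  nonsky_mask <- labels != "sky"
  for (ch in 1:3) {
    plane <- masked[, , ch]
    plane[nonsky_mask] <- 0L
    masked[, , ch] <- plane
  }
  realized <- c(sky = mean(labels == "sky"),
                green = mean(labels == "green"),
                built = mean(labels == "built"))
  list(image = img, masked = masked, labels = labels,
       realized = realized, spec = spec)
}
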