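# Canny edge detection and Hough-based straight/non-straight split.
#
# Implemented on the BT.601 luma plane with replicate-padded separable
# Gaussian smoothing, Sobel gradients, 4-sector non-maximum suppression and
# hysteresis linking. Gradient magnitudes are normalized by the pipeline's
# own response to a full black-to-white step (smoothing included), so the
# hysteresis thresholds are absolute local-contrast fractions: an edge of
# contrast c (on the 0-1 luma scale) has magnitude ~c, and low-amplitude
# noise stays below the thresholds and yields an empty map.

# Peak gradient magnitude the smoothing+Sobel cascade assigns to a unit
# step, used to normalize magnitudes to contrast units. Memoized per sigma.
step_response <- local({
  cache <- list()
  function(sigma) {
    key <- format(sigma, digits = 10)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- max(1L, ceiling(3 * sigma))
    n <- 4L * r + 8L
    m <- matrix(0, 8L, n)
    m[, (n %/% 2L + 1L):n] <- 1
    g <- gauss_smooth(m, sigma)
    gx <- (shift_rep(g, -1L, 1L) + 2 * shift_rep(g, 0L, 1L) +
             shift_rep(g, 1L, 1L)) -
          (shift_rep(g, -1L, -1L) + 2 * shift_rep(g, 0L, -1L) +
             shift_rep(g, 1L, -1L))
    cache[[key]] <<- max(abs(gx))
    cache[[key]]
  }
})

# Shift a matrix by (di, dj), replicating border rows/columns.
shift_rep <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian smoothing with replicate padding.
gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_rep(m, (-r:r)[i], 0L)
  res <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) res <- res + k[i] * shift_rep(out, 0L, (-r:r)[i])
  res
}

#' Canny edge map of an image
#'
#' Detects well-defined edges, curves and lines: Gaussian smoothing, Sobel
#' gradient, non-maximum suppression along the gradient direction, and
#' hysteresis thresholding (strong seeds grown through 8-connected weak
#' pixels). Deterministic for a fixed input and configuration.
#'
#' @param img `H x W x 3` RGB array, values 0-255.
#' @param cfg An [extraction_config()]; `edge_sigma`, `edge_low`,
#'   `edge_high` are used (thresholds as fractions of a full-contrast step
#'   response).
#' @return Logical `H x W` matrix marking edge pixels.
#' @export
edge_map <- function(img, cfg = extraction_config()) {
  check_rgb(img)
  d <- dim(img)[1:2]
  if (any(d <= 2L))
    stop("image too small for edge detection (each side must exceed 2 px)",
         call. = FALSE)
  g <- gauss_smooth(luma(img) / 255, cfg$edge_sigma)
  # Sobel; rows index y (downwards), columns x.
  gx <- (shift_rep(g, -1L, 1L) + 2 * shift_rep(g, 0L, 1L) + shift_rep(g, 1L, 1L)) -
        (shift_rep(g, -1L, -1L) + 2 * shift_rep(g, 0L, -1L) + shift_rep(g, 1L, -1L))
  gy <- (shift_rep(g, 1L, -1L) + 2 * shift_rep(g, 1L, 0L) + shift_rep(g, 1L, 1L)) -
        (shift_rep(g, -1L, -1L) + 2 * shift_rep(g, -1L, 0L) + shift_rep(g, -1L, 1L))
  mag <- sqrt(gx^2 + gy^2) / step_response(cfg$edge_sigma)
  if (max(mag) == 0) return(matrix(FALSE, d[1L], d[2L]))

  # Non-maximum suppression: quantize direction into 4 sectors and compare
  # against the two neighbours along the gradient. The strict/non-strict
  # asymmetry keeps plateau edges one pixel thin.
  ang <- atan2(gy, gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, d[1L], d[2L])
  for (s in 0:3) {
    o <- off[[s + 1L]]
    n1 <- shift_rep(mag, o[1L], o[2L])
    n2 <- shift_rep(mag, -o[1L], -o[2L])
    nms <- nms | (sector == s & mag > n1 & mag >= n2)
  }
  strong <- nms & mag >= cfg$edge_high
  weak <- nms & mag >= cfg$edge_low
  hysteresis_link(strong, weak)
}

# Grow strong seeds through 8-connected weak pixels until stable.
hysteresis_link <- function(strong, weak) {
  keep <- strong
  repeat {
    dil <- keep
    for (di in -1:1) for (dj in -1:1)
      if (di != 0L || dj != 0L) dil <- dil | shift_rep(keep, di, dj)
    grown <- weak & dil
    if (sum(grown) == sum(keep)) return(keep)
    keep <- grown
  }
}

#' Detect straight-line support pixels in an edge map
#'
#' A Hough transform over 180 one-degree orientations finds candidate lines
#' (accumulator cells with at least `line_vote_frac * diagonal` votes). The
#' edge pixels within `line_tol` pixels of a candidate line are projected
#' onto it and split into contiguous segments (gaps above `line_gap` pixels
#' break a segment); every segment at least `line_minlen_frac * diagonal`
#' long marks its supporters as straight. Curves fail the test because
#' within the pixel tolerance they can only follow a chord for a short run:
#' a circular arc of radius R stays within tolerance t of a chord for about
#' `sqrt(8 R t)` pixels.
#'
#' @param edges Logical edge matrix from [edge_map()].
#' @param cfg An [extraction_config()].
#' @return Logical matrix of the same shape marking edge pixels that lie on
#'   detected straight lines.
#' @export
straight_pixels <- function(edges, cfg = extraction_config()) {
  stopifnot(is.logical(edges), is.matrix(edges))
  straight <- edges & FALSE
  idx <- which(edges, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(straight)
  diag_len <- sqrt(nrow(edges)^2 + ncol(edges)^2)
  vote_thr <- cfg$line_vote_frac * diag_len
  minlen <- cfg$line_minlen_frac * diag_len
  gap <- cfg$line_gap %||% 2
  x <- idx[, 2L]; y <- idx[, 1L]
  thetas <- (0:179) * pi / 180
  rmax <- ceiling(diag_len)
  for (th in thetas) {
    co <- cos(th); si <- sin(th)
    rho <- x * co + y * si
    bin <- round(rho) + rmax + 1L  # offset into a non-negative bin index
    votes <- tabulate(bin, nbins = 2L * rmax + 2L)
    peaks <- which(votes >= vote_thr)
    if (length(peaks) == 0L) next
    # keep one accumulator cell per local vote maximum: neighbouring cells
    # describe the same physical line and the tolerance band covers them
    nb_lo <- votes[pmax(peaks - 1L, 1L)]
    nb_hi <- votes[pmin(peaks + 1L, length(votes))]
    peaks <- peaks[votes[peaks] >= nb_lo & votes[peaks] > nb_hi |
                     (votes[peaks] >= nb_lo & peaks == length(votes))]
    if (length(peaks) == 0L) next
    tpos <- -x * si + y * co  # position along the line direction
    ord_rho <- order(rho)
    rho_s <- rho[ord_rho]
    for (ctr in peaks - rmax - 1L) {
      lo <- findInterval(ctr - cfg$line_tol, rho_s, left.open = TRUE) + 1L
      hi <- findInterval(ctr + cfg$line_tol, rho_s)
      if (hi - lo + 1L < minlen) next
      near <- ord_rho[lo:hi]
      ord <- near[order(tpos[near])]
      t_s <- tpos[ord]
      brk <- c(0L, which(diff(t_s) > gap), length(t_s))
      for (b in seq_len(length(brk) - 1L)) {
        if (brk[b + 1L] - brk[b] < 2L) next
        if ((t_s[brk[b + 1L]] - t_s[brk[b] + 1L] + 1) >= minlen)
          straight[idx[ord[(brk[b] + 1L):brk[b + 1L]], , drop = FALSE]] <- TRUE
      }
    }
  }
  straight
}

#' Overall, straight and non-straight edge density
#'
#' Edge density is the fraction of image pixels lying on detected edges.
#' Straight edge density counts the edge pixels assigned to straight lines
#' (horizontal, vertical or oblique) by the Hough detector; non-straight edge
#' density counts the remaining edge pixels (curved or fragmented contours).
#' The split is a strict partition, so
#' `straight_edge_density + nonstraight_edge_density == edge_density` exactly.
#'
#' @param edges Logical edge matrix from [edge_map()].
#' @param cfg An [extraction_config()].
#' @return Named list `edge_density`, `straight_edge_density`,
#'   `nonstraight_edge_density`.
#' @export
edge_densities <- function(edges, cfg = extraction_config()) {
  stopifnot(is.logical(edges), is.matrix(edges))
  n <- length(edges)
  straight <- straight_pixels(edges, cfg)
  ed <- sum(edges) / n
  sed <- sum(straight) / n
  list(edge_density = ed,
       straight_edge_density = sed,
       nonstraight_edge_density = ed - sed)
}
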