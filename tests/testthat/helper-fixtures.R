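# Fixture builders and independent oracles used across the suite.

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

solid_image <- function(r, g, b, h = 8L, w = 8L) {
  img <- array(0L, c(h, w, 3L))
  img[, , 1L] <- as.integer(r); img[, , 2L] <- as.integer(g)
  img[, , 3L] <- as.integer(b)
  img
}

# grayscale image whose 256-level histogram is exactly uniform
uniform_histogram_image <- function() {
  g <- matrix(rep(0:255, each = 4L), 32L, 32L)
  array(c(g, g, g), c(32L, 32L, 3L))
}

rotate90 <- function(img) {
  out <- array(0L, c(dim(img)[2L], dim(img)[1L], 3L))
  for (ch in 1:3) out[, , ch] <- t(img[dim(img)[1L]:1, , ch])
  out
}

# depth-limited Sierpinski triangle mask (right-angle form, side `size`):
# the depth-`depth` subdivision pattern expanded to filled cells
sierpinski_mask <- function(size = 512L, depth = 7L) {
  n <- 2L^depth
  cell <- size %/% n
  keep <- outer(0:(n - 1L), 0:(n - 1L),
                function(i, j) bitwAnd(i, j) == 0L)
  keep[rep(seq_len(n), each = cell), rep(seq_len(n), each = cell)]
}

# independent triple-loop box counter
brute_box_count <- function(mask, s) {
  h <- nrow(mask); w <- ncol(mask)
  count <- 0L
  for (bi in seq_len(ceiling(h / s))) {
    for (bj in seq_len(ceiling(w / s))) {
      rows <- ((bi - 1L) * s + 1L):min(bi * s, h)
      cols <- ((bj - 1L) * s + 1L):min(bj * s, w)
      hit <- FALSE
      for (r in rows) {
        for (cc in cols) if (mask[r, cc]) { hit <- TRUE; break }
        if (hit) break
      }
      if (hit) count <- count + 1L
    }
  }
  count
}

# independent staircase oracle: closed-form cumulative half-steps
staircase_oracle_ip <- function(choices) {
  signs <- ifelse(choices == "delayed", 1, -1)
  50 + sum(signs * 100 / 2^(seq_along(choices) + 1L))
}

# independent average-rank computation (no base rank())
avg_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

make_fv <- function(...) {
  v <- setNames(rep(NA_real_, 14L), viewfeat::feature_names())
  args <- c(...)
  v[names(args)] <- args
  structure(v, flags = setNames(rep(FALSE, 6L),
                                c("hue_undefined", "hue_unstable",
                                  "fd_degenerate", "fd_out_of_range",
                                  "brightness_unreliable", "sky_missing")),
            class = "feature_vector")
}

# analysis table with planted structure, no images involved
make_analysis_table <- function(n = 80L, seed = 1L,
                                b_green = 80, b_bright = -0.15,
                                noise_pct = 6, noise_na = 4) {
  set.seed(seed)
  green <- runif(n, 0, 0.6)
  tab <- data.frame(participant_id = sprintf("p%03d", seq_len(n)))
  for (f in viewfeat::feature_names())
    tab[[f]] <- runif(n)
  tab$green_ratio <- green
  pn <- pmin(pmax(5 + b_green * green + rnorm(n, 0, noise_pct), 0), 98)
  ps <- pmin(runif(n, 5, 30), 100 - pn - 1)
  tab$pct_nature <- round(pn)
  tab$pct_sky <- round(ps)
  tab$pct_manmade <- 100L - tab$pct_nature - tab$pct_sky
  tab$quality <- runif(n, 20, 90)
  tab$brightness_rating <- runif(n, 30, 95)
  tab$green_visibility <- runif(n, 0, 100)
  tab$vegetation_rooms <- rbinom(n, 8, 0.4)
  tab$long_distance_view <- runif(n, 0, 100)
  tab$age <- round(runif(n, 18, 60))
  tab$sex <- sample(c("male", "female"), n, replace = TRUE)
  tab$income <- sample(1:7, n, replace = TRUE)
  tab$living_space <- runif(n, 20, 150)
  tab$time_home_pre <- runif(n, 4, 24)
  tab$time_home_covid <- runif(n, 8, 24)
  tab$image_count <- pmax(1, rpois(n, 5))
  tab$negative_affect <- round(pmin(pmax(
    58 + b_bright * tab$brightness_rating + rnorm(n, 0, noise_na), 20), 80))
  tab$auc <- runif(n)
  tab
}
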