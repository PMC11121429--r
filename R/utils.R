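# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Stages of the pipeline consume independent RNG streams so any stage can be
#' rerun in isolation without correlating with the others. The stage seed is a
#' deterministic hash of the master seed and the stage label, kept below
#' `2^31` so it is always a valid R integer seed.
#'
#' @param master_seed Integer master seed.
#' @param label Character stage label (e.g. `"simulate"`).
#' @return A single integer seed.
#' @export
stage_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(label), length(label) == 1L)
  h <- digest::digest(list(as.integer(master_seed), label), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1L, 7L), base = 16L))
}

check_rgb <- function(img, what = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop(what, " must be an H x W x 3 array of 8-bit RGB values",
         call. = FALSE)
  if (min(img) < 0 || max(img) > 255)
    stop(what, " channel values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

# ITU-R BT.601 luma, returned on the same scale as the input channels.
luma <- function(img) {
  check_rgb(img)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
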