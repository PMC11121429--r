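#' Read a window-view photograph
#'
#' Reads an 8-bit RGB image from a PNG or JPEG file into the plain
#' `H x W x 3` integer array used throughout the package (values 0-255).
#' Grayscale files are expanded to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An `H x W x 3` integer array with values in 0-255.
#' @seealso [extract_features()], [find_sky_mask()]
#' @export
read_view_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' (PNG or JPEG expected): ",
         path, call. = FALSE)
  )
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  nc <- dim(raw)[3L]
  img <- if (nc == 1L) array(raw[, , 1L], c(dim(raw)[1:2], 3L))
         else raw[, , 1:3, drop = FALSE]
  storage.mode(img) <- "double"
  img <- round(img * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write an RGB array as a PNG file
#'
#' @param img `H x W x 3` array, values 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_view_image <- function(img, path) {
  check_rgb(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Locate the companion sky mask of an image
#'
#' Sky masks are sibling files named `<stem>_skymask.png` in which every
#' non-sky pixel has been blackened (exact RGB 0,0,0). Masks are produced
#' manually (or by the synthetic scene generator); the package only consumes
#' them.
#'
#' @param image_path Path of the original image.
#' @return The mask path, or `NA_character_` if no mask file exists.
#' @export
find_sky_mask <- function(image_path) {
  stem <- tools::file_path_sans_ext(image_path)
  mask <- paste0(stem, "_skymask.png")
  if (file.exists(mask)) mask else NA_character_
}
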