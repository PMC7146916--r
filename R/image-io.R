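#' Read a plant image as an 8-bit RGB array
#'
#' Reads a PNG, JPEG or TIFF photograph and returns it in the package's
#' raster convention: an array of dimension rows x cols x 3 with row 1 at the
#' top of the frame and channel values on the 0--255 scale. Greyscale files
#' are replicated across the three channels.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @return A numeric array `rows x cols x 3` with values in `[0, 255]`.
#' @export
read_plant_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {
    dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  } else if (dim(dat)[3L] > 3L) {
    dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  }
  # EBImage stores [x = col, y = row]; transpose into [row, col, channel]
  out <- aperm(dat, c(2L, 1L, 3L)) * 255
  out
}

#' Write a binary mask as a 1-bit-style PNG
#'
#' @param mask Logical matrix, `TRUE` = root.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png")
  invisible(path)
}

#' Read a mask PNG written by [write_mask()]
#'
#' Any pixel with intensity above 0.5 is treated as root.
#'
#' @param path PNG path.
#' @return Logical matrix in row/col orientation.
#' @export
read_mask <- function(path) {
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 3L) dat <- dat[, , 1L]
  t(dat) > 0.5
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path Text file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[[1L]])
    val <- trimws(paste(p[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
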