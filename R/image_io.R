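#' Read and write tile images and instance masks
#'
#' Tiles are 8-bit RGB PNG; instance label masks are single-channel 16-bit
#' TIFF (0 = background, k = instance k). In memory, tiles are H x W x 3
#' integer arrays with values in 0..255 and masks are H x W integer
#' matrices.
#'
#' @param image H x W x 3 integer array, values in 0..255.
#' @param mask H x W integer matrix of instance labels.
#' @param path file path.
#' @return Readers return the in-memory form; writers return `path`
#'   invisibly.
#' @name tile_io
NULL

#' @rdname tile_io
#' @export
write_tile <- function(image, path) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  png::writePNG(array(image / 255, dim(image)), path)
  invisible(path)
}

#' @rdname tile_io
#' @export
read_tile <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim(a))
}

#' @rdname tile_io
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask < 65536))
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname tile_io
#' @export
read_mask <- function(path) {
  a <- tiff::readTIFF(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  matrix(as.integer(round(a * 65535)), nrow(a), ncol(a))
}
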