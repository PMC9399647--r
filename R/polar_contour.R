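#' Polar-ray contour representation of a nucleus instance
#'
#' An instance footprint is summarised as a center plus 36 ray lengths,
#' ray k (k = 0..35) pointing at angle 10*k degrees measured
#' counter-clockwise from the +x (column) axis. Decoding connects the 36
#' ray endpoints in angular order into a closed polygon.
#'
#' @param center numeric length 2, subpixel (row, col), 1-based.
#' @param rays numeric length 36, non-negative ray lengths in pixels.
#' @param instance_id integer id.
#' @return object of class `polar_instance`.
#' @export
polar_instance <- function(center, rays, instance_id = 1L) {
  rays <- as.numeric(rays)
  stopifnot(length(center) == 2, length(rays) == 36,
            all(is.finite(rays)), all(rays >= 0))
  structure(list(center = as.numeric(center), rays = rays,
                 instance_id = as.integer(instance_id)),
            class = "polar_instance")
}

polar_angles <- function() (0:35) * 10 * pi / 180

#' Encode a binary instance mask as 36 polar rays
#'
#' For each of the 36 angles the ray length is the distance from the
#' center to the farthest foreground pixel along that direction, probed
#' at 0.5 px steps (so mild non-convexity along a ray is bridged to the
#' outermost crossing). A ray is 0 when no foreground lies in that
#' direction.
#'
#' @param instance_mask logical/integer matrix; nonzero = foreground.
#' @param center optional (row, col); defaults to the foreground centroid.
#' @param instance_id id stored in the result.
#' @return a [polar_instance()].
#' @export
encode_polar <- function(instance_mask, center = NULL, instance_id = 1L) {
  fg <- which(instance_mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("encode_polar: empty mask")
  if (is.null(center)) center <- colMeans(fg)
  nr <- nrow(instance_mask); nc <- ncol(instance_mask)
  tmax <- sqrt(nr^2 + nc^2)
  tgrid <- seq(0, tmax, by = 0.5)
  ang <- polar_angles()
  rays <- vapply(ang, function(a) {
    rr <- round(center[1] + tgrid * sin(a))
    cc <- round(center[2] + tgrid * cos(a))
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (!any(ok)) return(0)
    hit <- ok
    hit[ok] <- instance_mask[cbind(rr[ok], cc[ok])] != 0
    if (!any(hit)) 0 else max(tgrid[hit])
  }, numeric(1))
  polar_instance(center, rays, instance_id)
}

#' Decode 36 polar rays into a polygon and a rasterized mask
#'
#' Vertex k is `center + rays[k] * (cos(10k deg), sin(10k deg))` in
#' (x, y) = (col, row) geometry; vertices are joined in angular order
#' starting from 0 degrees into a closed polygon, which is rasterized by
#' an even-odd point-in-polygon test over pixel centers. All-zero rays
#' yield an empty mask.
#'
#' @param p a [polar_instance()].
#' @param dim optional c(nrow, ncol) of the output mask; defaults to the
#'   smallest frame containing the polygon.
#' @return list with `polygon` (36 x 2 matrix, columns x, y), `mask`
#'   (integer matrix) and `center`.
#' @export
decode_polar <- function(p, dim = NULL) {
  stopifnot(inherits(p, "polar_instance"))
  ang <- polar_angles()
  x <- p$center[2] + p$rays * cos(ang)
  y <- p$center[1] + p$rays * sin(ang)
  poly <- cbind(x = x, y = y)
  if (is.null(dim)) dim <- c(ceiling(max(y) + 1), ceiling(max(x) + 1))
  mask <- rasterize_polygon(poly, dim)
  list(polygon = poly, mask = mask, center = p$center)
}

# Even-odd rasterization of a closed polygon over 1-based pixel centers.
rasterize_polygon <- function(poly, dim) {
  mask <- matrix(0L, dim[1], dim[2])
  if (all(abs(poly) < 1e-12) || nrow(poly) < 3) return(mask)
  r0 <- max(1L, floor(min(poly[, "y"]))); r1 <- min(dim[1], ceiling(max(poly[, "y"])))
  c0 <- max(1L, floor(min(poly[, "x"]))); c1 <- min(dim[2], ceiling(max(poly[, "x"])))
  if (r0 > r1 || c0 > c1) return(mask)
  g <- expand.grid(row = r0:r1, col = c0:c1)
  px <- g$col; py <- g$row
  inside <- rep(FALSE, nrow(g))
  n <- nrow(poly)
  for (k in seq_len(n)) {
    x1 <- poly[k, "x"]; y1 <- poly[k, "y"]
    j <- if (k == n) 1L else k + 1L
    x2 <- poly[j, "x"]; y2 <- poly[j, "y"]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  mask[cbind(g$row[inside], g$col[inside])] <- 1L
  mask
}

#' Shoelace area of a closed polygon
#'
#' @param poly n x 2 matrix of vertices (x, y) in order.
#' @return absolute area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Serialize / read a set of polar instances as JSON
#'
#' Each element is stored as `{id, center: [r, c], rays: [36 floats]}`.
#'
#' @param instances list of [polar_instance()] objects.
#' @param path JSON file path.
#' @return `read_polar_json` returns the list of instances.
#' @export
write_polar_json <- function(instances, path) {
  payload <- lapply(instances, function(p)
    list(id = p$instance_id, center = p$center, rays = p$rays))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polar_json
#' @export
read_polar_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i)
    polar_instance(unlist(payload$center[i]), unlist(payload$rays[i]),
                   payload$id[i]))
}

#' Classical fallback nucleus segmenter
#'
#' Stands in for a trained detector so the pipeline runs from images
#' alone: grayscale conversion, Otsu threshold (nuclei darker than
#' background), removal of objects below `min_size` pixels, then a
#' distance-transform watershed to split touching nuclei. Labels are
#' renumbered 1..n.
#'
#' @param image H x W x 3 integer array (0..255) or numeric in 0..1.
#' @param min_size minimum object size in pixels (default 20).
#' @param tolerance watershed tolerance on the distance map (default 1):
#'   minimum height of an object peak relative to its merge saddle.
#' @param ext watershed neighborhood radius in pixels (default 3).
#' @return integer label matrix (0 = background).
#' @export
fallback_segment <- function(image, min_size = 20, tolerance = 1, ext = 3) {
  stopifnot(length(dim(image)) == 3)
  if (max(image) > 1) image <- image / 255
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  thr <- EBImage::otsu(EBImage::Image(gray))
  bin <- gray < thr
  if (!any(bin)) return(matrix(0L, nrow(gray), ncol(gray)))
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance,
                                               ext = ext))
  relabel_filter(matrix(as.integer(lab), nrow(gray), ncol(gray)), min_size)
}

# Drop objects below min_size pixels and renumber labels 1..n.
relabel_filter <- function(lab, min_size) {
  if (!any(lab > 0)) return(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  map <- integer(length(sizes))
  map[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}
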