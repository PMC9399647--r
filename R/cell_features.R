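#' Shape features of a nucleus instance
#'
#' Eight morphological descriptors of a binary footprint: major and minor
#' axis length of the second-moments ellipse, orientation of the major
#' axis (radians in \[-pi/2, pi/2), measured from the +column axis),
#' eccentricity, roundness (circularity 4*pi*A/P^2), area (pixel count),
#' solidity (area / convex hull area) and perimeter. The perimeter is the
#' Kulpa-corrected 8-connected chain length of the boundary, which is
#' nearly unbiased for smooth shapes (a raw chain length overestimates a
#' circle's circumference by ~5%).
#'
#' @param instance_mask logical/integer matrix, nonzero = foreground.
#' @return named numeric vector of length 8.
#' @export
shape_features <- function(instance_mask) {
  fg <- which(instance_mask != 0, arr.ind = TRUE)
  n <- nrow(fg)
  if (n == 0) stop("shape_features: empty mask")
  area <- n
  # second-moments ellipse in (x, y) = (col, row) geometry
  x <- fg[, 2]; y <- fg[, 1]
  mxx <- mean(x^2) - mean(x)^2
  myy <- mean(y^2) - mean(y)^2
  mxy <- mean(x * y) - mean(x) * mean(y)
  tr <- mxx + myy
  det2 <- sqrt(max(0, (mxx - myy)^2 / 4 + mxy^2))
  l1 <- tr / 2 + det2
  l2 <- max(0, tr / 2 - det2)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  orientation <- if (abs(mxy) < 1e-12 && abs(mxx - myy) < 1e-12) 0 else
    0.5 * atan2(2 * mxy, mxx - myy)
  if (orientation >= pi / 2) orientation <- orientation - pi
  if (orientation < -pi / 2) orientation <- orientation + pi
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0

  per <- mask_perimeter(instance_mask)
  roundness <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
  solidity <- mask_solidity(fg, area)
  c(major_axis_length = major, minor_axis_length = minor,
    orientation = orientation, eccentricity = ecc,
    roundness = roundness, area = area, solidity = solidity,
    perimeter = per)
}

# Kulpa-weighted boundary chain length: 0.948 per axial step, 1.340 per
# diagonal step along the 8-connected outer boundary.
mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image((mask != 0) * 1))
  if (length(oc) == 0) return(0)
  total <- 0
  for (ct in oc) {
    if (nrow(ct) < 2) next
    d <- abs(ct - ct[c(2:nrow(ct), 1), , drop = FALSE])
    steps <- rowSums(d)
    total <- total + 0.948 * sum(steps == 1) + 1.340 * sum(steps == 2)
  }
  total
}

mask_solidity <- function(fg, area) {
  if (area <= 3) return(1)
  h <- grDevices::chull(fg[, 2], fg[, 1])
  hull <- cbind(x = fg[h, 2], y = fg[h, 1])
  if (nrow(hull) < 3) return(1)
  dimm <- c(max(fg[, 1]) + 1, max(fg[, 2]) + 1)
  conv <- rasterize_polygon(hull, dimm)
  conv[fg] <- 1L  # hull boundary pixels always count as convex area
  min(1, area / sum(conv))
}

#' GLCM texture features of a nucleus instance
#'
#' Intensities inside the instance bounding box are min-max quantized to
#' 32 gray levels; symmetric normalized co-occurrence matrices are
#' accumulated at offset distance 1 for angles 0, 45, 90 and 135 degrees.
#' Dissimilarity = sum P(i,j)|i-j|, homogeneity = sum P(i,j)/(1+(i-j)^2)
#' and ASM = sum P(i,j)^2 are averaged over the four angles; energy is
#' sqrt of the averaged ASM, so the identity energy^2 = ASM holds
#' exactly for the reported values.
#'
#' @param image grayscale matrix (any range; quantization is per-patch).
#' @param instance_mask binary matrix, same size, selecting the instance.
#' @param levels number of gray levels (default 32).
#' @return named numeric vector `(dissimilarity, homogeneity, asm, energy)`.
#' @export
texture_features <- function(image, instance_mask, levels = 32L) {
  fg <- which(instance_mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("texture_features: empty mask")
  r <- range(fg[, 1]); cc <- range(fg[, 2])
  if (diff(r) < 1 || diff(cc) < 1) stop("texture_features: bounding box < 2x2")
  patch <- image[r[1]:r[2], cc[1]:cc[2]]
  q <- quantize_levels(patch, levels)
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  feats <- sapply(offs, function(o) glcm_features(q, o, levels))
  out <- rowMeans(feats)[1:3]
  out <- c(out, sqrt(out[[3]]))
  names(out) <- c("dissimilarity", "homogeneity", "asm", "energy")
  out
}

quantize_levels <- function(patch, levels) {
  rng <- range(patch)
  if (diff(rng) == 0) return(matrix(0L, nrow(patch), ncol(patch)))
  q <- floor((patch - rng[1]) / diff(rng) * levels)
  matrix(as.integer(pmin(q, levels - 1L)), nrow(patch), ncol(patch))
}

# Symmetric normalized GLCM at one offset; returns the 4 features.
glcm_features <- function(q, off, levels) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  i <- c(a, b); j <- c(b, a)  # symmetric accumulation
  p <- tabulate(i * levels + j + 1L, nbins = levels * levels)
  p <- p / sum(p)
  lev <- 0:(levels - 1L)
  dij <- abs(outer(lev, lev, "-"))
  asm <- sum(p^2)
  c(sum(p * dij), sum(p / (1 + dij^2)), asm, sqrt(asm))
}

#' Deterministic descriptor of a 64 x 64 patch around a centroid
#'
#' Stands in the architecture's patch-embedding slot (a learned
#' self-supervised encoder in the original design) with a fixed, fully
#' deterministic summary: per-channel mean and standard deviation (6
#' values) plus two-level Haar-like grayscale contrasts (left-right,
#' top-bottom and diagonal differences of block means over the full patch
#' and over its central half; 6 values). Patches clipped by the tile
#' border are zero-padded.
#'
#' @param image H x W x 3 array (0..255 or 0..1).
#' @param centroid (row, col), 1-based.
#' @param size patch side in pixels (default 64).
#' @return numeric vector of length 12.
#' @export
patch_descriptor <- function(image, centroid, size = 64L) {
  stopifnot(length(dim(image)) == 3)
  half <- size %/% 2L
  r0 <- round(centroid[1]) - half; c0 <- round(centroid[2]) - half
  patch <- array(0, c(size, size, 3))
  rr <- max(1L, r0):min(nrow(image), r0 + size - 1L)
  cc <- max(1L, c0):min(ncol(image), c0 + size - 1L)
  if (length(rr) > 0 && length(cc) > 0 && rr[1] <= rr[length(rr)]) {
    patch[rr - r0 + 1L, cc - c0 + 1L, ] <- image[rr, cc, , drop = FALSE]
  }
  means <- apply(patch, 3, mean)
  sds <- apply(patch, 3, sd)
  gray <- 0.299 * patch[, , 1] + 0.587 * patch[, , 2] + 0.114 * patch[, , 3]
  haar <- function(g) {
    n <- nrow(g); h <- n %/% 2
    c(mean(g[, 1:h]) - mean(g[, (h + 1):n]),
      mean(g[1:h, ]) - mean(g[(h + 1):n, ]),
      mean(g[1:h, 1:h]) + mean(g[(h + 1):n, (h + 1):n]) -
        mean(g[1:h, (h + 1):n]) - mean(g[(h + 1):n, 1:h]))
  }
  ctr <- (size %/% 4 + 1):(size - size %/% 4)
  out <- c(means, sds, haar(gray), haar(gray[ctr, ctr]))
  names(out) <- c(paste0("patch_mean_", c("r", "g", "b")),
                  paste0("patch_sd_", c("r", "g", "b")),
                  paste0("patch_haar_", 1:6))
  out
}

#' Per-nucleus feature matrix for a labeled tile
#'
#' One row per instance label (row k corresponds to label k), columns =
#' 8 shape + 4 GLCM texture + patch descriptor (default 12; 24 total).
#' Instances whose bounding box is degenerate for the GLCM get zero
#' dissimilarity and unit homogeneity/ASM/energy (the constant-patch
#' limit).
#'
#' @param image H x W x 3 array (0..255).
#' @param instance_mask integer label matrix.
#' @param descriptor function(image, centroid) -> numeric vector; the
#'   patch-embedding slot. Defaults to [patch_descriptor()].
#' @return list with `features` (m x f matrix) and `centroids` (m x 2
#'   matrix of (row, col)).
#' @export
featurize_tile <- function(image, instance_mask,
                           descriptor = function(img, ctr)
                             patch_descriptor(img, ctr, 64L)) {
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  labs <- seq_len(max(0L, max(instance_mask)))
  probe <- descriptor(image, c(1, 1))
  fnames <- c("major_axis_length", "minor_axis_length", "orientation",
              "eccentricity", "roundness", "area", "solidity", "perimeter",
              "dissimilarity", "homogeneity", "asm", "energy",
              names(probe) %||% paste0("patch_", seq_along(probe)))
  if (length(labs) == 0) {
    return(list(features = matrix(numeric(0), 0, length(fnames),
                                  dimnames = list(NULL, fnames)),
                centroids = matrix(numeric(0), 0, 2)))
  }
  out <- matrix(0, length(labs), length(fnames),
                dimnames = list(NULL, fnames))
  cents <- matrix(0, length(labs), 2)
  # one pass over the label image, then per-instance bounding-box crops
  w <- which(instance_mask > 0L)
  lab_at <- instance_mask[w]
  nr <- nrow(instance_mask)
  prow <- split(((w - 1L) %% nr) + 1L, lab_at)
  pcol <- split(((w - 1L) %/% nr) + 1L, lab_at)
  for (k in labs) {
    rr <- prow[[as.character(k)]]
    cc <- pcol[[as.character(k)]]
    if (is.null(rr)) stop("featurize_tile: label ", k, " has no pixels")
    ctr <- c(mean(rr), mean(cc))
    cents[k, ] <- ctr
    r0 <- min(rr); c0 <- min(cc)
    sub <- instance_mask[r0:max(rr), c0:max(cc), drop = FALSE] == k
    gsub <- gray[r0:max(rr), c0:max(cc), drop = FALSE]
    tex <- if (nrow(sub) < 2 || ncol(sub) < 2) {
      c(dissimilarity = 0, homogeneity = 1, asm = 1, energy = 1)
    } else {
      texture_features(gsub, sub)
    }
    out[k, ] <- c(shape_features(sub), tex, descriptor(image, ctr))
  }
  list(features = out, centroids = cents)
}

#' Z-score normalization statistics for node features
#'
#' Statistics are fitted on the training split only and reused verbatim
#' everywhere else. Columns with zero spread get unit scale.
#'
#' @param X numeric matrix (rows = instances).
#' @return object of class `feature_norm` with `center` and `scale`.
#' @export
feature_norm_fit <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2, sd)
  sc[!is.finite(sc) | sc < 1e-12] <- 1
  structure(list(center = ctr, scale = sc, names = colnames(X)),
            class = "feature_norm")
}

#' @rdname feature_norm_fit
#' @param norm a `feature_norm`.
#' @export
feature_norm_apply <- function(X, norm) {
  sweep(sweep(X, 2, norm$center), 2, norm$scale, "/")
}

#' @rdname feature_norm_fit
#' @export
feature_norm_invert <- function(X, norm) {
  sweep(sweep(X, 2, norm$scale, "*"), 2, norm$center, "+")
}

#' @rdname feature_norm_fit
#' @param path JSON file path.
#' @export
feature_norm_save <- function(norm, path) {
  jsonlite::write_json(unclass(norm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname feature_norm_fit
#' @export
feature_norm_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = setNames(unlist(x$center), x$names),
                 scale = setNames(unlist(x$scale), x$names),
                 names = x$names), class = "feature_norm")
}
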