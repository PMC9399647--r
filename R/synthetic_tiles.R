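#' Specification of a synthetic labeled tile
#'
#' Describes one synthetic histology-like tile: elliptical "nuclei" whose
#' spatial arrangement follows a class-specific point process. The three
#' built-in classes are spatial stand-ins for architecturally distinct
#' growth patterns:
#' \describe{
#'   \item{gland}{centroids on one or more rings (radius 30-60 px) with
#'     angular jitter, mimicking gland-like lumina.}
#'   \item{sheet}{dense jittered hexagonal packing, mimicking solid sheets
#'     of tumor cells.}
#'   \item{scattered}{hard-core Poisson process (minimum inter-centroid
#'     distance 25 px), mimicking sparsely scattered cells.}
#' }
#'
#' @param tile_size side of the square tile in pixels (>= 64).
#' @param class_label one of `"gland"`, `"sheet"`, `"scattered"`.
#' @param n_nuclei number of nuclei to attempt to place; defaults per
#'   class (gland 36, sheet 60, scattered 20) match the density regime of
#'   each point process at 256 px.
#' @param nucleus_axes_range length-2 numeric, min/max ellipse semi-axis
#'   in pixels (>= 2).
#' @param intensity_params list with per-channel `bg_mean`, `nuc_mean`
#'   (length 3, 0..255) and scalar `bg_sd`, `nuc_sd`.
#' @param seed integer; fully determines the tile.
#' @return an object of class `tile_spec`.
#' @export
tile_spec <- function(tile_size = 256L,
                      class_label = c("gland", "sheet", "scattered"),
                      n_nuclei = NULL,
                      nucleus_axes_range = c(4, 8),
                      intensity_params = NULL,
                      seed = 1L) {
  class_label <- match.arg(class_label)
  if (is.null(n_nuclei)) {
    n_nuclei <- switch(class_label, gland = 36L, sheet = 60L, scattered = 20L)
  }
  if (is.null(intensity_params)) {
    intensity_params <- list(bg_mean = c(225, 205, 220), bg_sd = 8,
                             nuc_mean = c(110, 85, 150), nuc_sd = 10)
  }
  stopifnot(tile_size >= 64, n_nuclei >= 1,
            length(nucleus_axes_range) == 2,
            nucleus_axes_range[1] >= 2,
            nucleus_axes_range[2] >= nucleus_axes_range[1])
  structure(list(tile_size = as.integer(tile_size),
                 class_label = class_label,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_axes_range = as.numeric(nucleus_axes_range),
                 intensity_params = intensity_params,
                 seed = as.integer(seed)),
            class = "tile_spec")
}

# Rasterize an ellipse: 1-based (row, col) pixel centers inside the ellipse
# centered at (cr, cc) with semi-axes a >= b and orientation theta (angle of
# the a-axis from the +column axis). Returns a 2-column matrix.
ellipse_pixels <- function(cr, cc, a, b, theta, nrow_max, ncol_max) {
  rr <- max(1L, floor(cr - a)):min(nrow_max, ceiling(cr + a))
  cz <- max(1L, floor(cc - a)):min(ncol_max, ceiling(cc + a))
  g <- expand.grid(row = rr, col = cz)
  dx <- g$col - cc
  dy <- g$row - cr
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  as.matrix(g[u^2 + v^2 <= 1, , drop = FALSE])
}

# Stateful centroid proposal streams, one per class process.
make_proposer <- function(spec) {
  ts <- spec$tile_size
  margin <- spec$nucleus_axes_range[2] + 1
  lo <- margin
  hi <- ts - margin
  if (spec$class_label == "gland") {
    queue <- matrix(numeric(0), 0, 2)
    function() {
      while (nrow(queue) == 0) {
        rad <- runif(1, 30, 60)
        ctr <- runif(2, lo, hi)  # ring center; off-tile points are filtered
        n_on <- max(3L, floor(2 * pi * rad / 22))
        ang <- 2 * pi * (seq_len(n_on) - 1) / n_on + rnorm(n_on, 0, 0.08)
        pts <- cbind(ctr[1] + (rad + rnorm(n_on, 0, 1.5)) * sin(ang),
                     ctr[2] + (rad + rnorm(n_on, 0, 1.5)) * cos(ang))
        ok <- pts[, 1] >= lo & pts[, 1] <= hi & pts[, 2] >= lo & pts[, 2] <= hi
        queue <<- pts[ok, , drop = FALSE]
      }
      p <- queue[1, ]
      queue <<- queue[-1, , drop = FALSE]
      p
    }
  } else if (spec$class_label == "sheet") {
    # dense hexagonal patch centered in the tile, sized to hold ~n_nuclei;
    # filled in row-major order so the packing stays contiguous and dense
    s <- 15
    side <- min(hi - lo, sqrt(spec$n_nuclei * s^2 * sqrt(3) / 2) * 1.1)
    p0 <- (lo + hi) / 2 - side / 2
    queue <- matrix(numeric(0), 0, 2)
    function() {
      while (nrow(queue) == 0) {
        rows <- seq(p0, p0 + side, by = s * sqrt(3) / 2)
        pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
          xs <- seq(p0 + (i %% 2) * s / 2, p0 + side, by = s)
          cbind(rows[i] + rnorm(length(xs), 0, 1.5),
                xs + rnorm(length(xs), 0, 1.5))
        }))
        ok <- pts[, 1] >= lo & pts[, 1] <= hi & pts[, 2] >= lo & pts[, 2] <= hi
        queue <<- pts[ok, , drop = FALSE]
      }
      p <- queue[1, ]
      queue <<- queue[-1, , drop = FALSE]
      p
    }
  } else { # scattered: hard-core thinning against already accepted centroids
    accepted <- NULL
    function() {
      repeat {
        p <- runif(2, lo, hi)
        if (is.null(accepted) ||
            min(sqrt(rowSums((accepted - rep(p, each = nrow(accepted)))^2))) >= 25) {
          accepted <<- rbind(accepted, p)
          return(p)
        }
      }
    }
  }
}

#' Generate one synthetic tile
#'
#' Places elliptical nuclei by the class-specific point process of the
#' spec, with rejection sampling so that instances never overlap (a 1 px
#' separation is enforced, so each label is a 4-connected region). The
#' image is rendered as Gaussian background noise with darker nucleus
#' interiors. A bounded number of rejections (1000 per instance) prevents
#' infinite loops: on exhaustion the remaining instances are dropped.
#'
#' @param spec a [tile_spec()].
#' @return a list of class `synthetic_tile` with elements `image`
#'   (H x W x 3 integer array, 0..255), `instance_mask` (H x W integer
#'   matrix, labels 1..n with no gaps), `label` and `spec`.
#' @export
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "tile_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  ts <- spec$tile_size
  mask <- matrix(0L, ts, ts)
  occupied <- matrix(FALSE, ts + 2, ts + 2)  # padded for the 1 px margin test
  propose <- make_proposer(spec)
  ax <- spec$nucleus_axes_range
  placed <- 0L
  inst <- list()
  for (k in seq_len(spec$n_nuclei)) {
    done <- FALSE
    for (attempt in seq_len(1000L)) {
      ctr <- propose()
      semi <- sort(runif(2, ax[1], ax[2]), decreasing = TRUE)
      theta <- runif(1, -pi / 2, pi / 2)
      px <- ellipse_pixels(ctr[1], ctr[2], semi[1], semi[2], theta, ts, ts)
      if (nrow(px) < 4) next
      # reject if the ellipse or its 1 px neighborhood touches an instance
      idx <- cbind(px[, 1] + 1L, px[, 2] + 1L)
      hit <- occupied[idx] |
        occupied[cbind(idx[, 1] + 1L, idx[, 2])] |
        occupied[cbind(idx[, 1] - 1L, idx[, 2])] |
        occupied[cbind(idx[, 1], idx[, 2] + 1L)] |
        occupied[cbind(idx[, 1], idx[, 2] - 1L)]
      if (any(hit)) next
      placed <- placed + 1L
      mask[px] <- placed
      occupied[idx] <- TRUE
      inst[[placed]] <- data.frame(instance = placed, row = ctr[1],
                                   col = ctr[2], a = semi[1], b = semi[2],
                                   theta = theta)
      done <- TRUE
      break
    }
    if (!done) break  # bounded rejections: drop remaining instances
  }
  if (placed == 0L) stop("no instances could be placed for this tile_spec")

  ip <- spec$intensity_params
  img <- array(0L, c(ts, ts, 3))
  fg <- mask > 0
  for (ch in 1:3) {
    plane <- matrix(rnorm(ts * ts, ip$bg_mean[ch], ip$bg_sd), ts, ts)
    plane[fg] <- rnorm(sum(fg), ip$nuc_mean[ch], ip$nuc_sd)
    img[, , ch] <- as.integer(clamp(round(plane), 0, 255))
  }
  structure(list(image = img, instance_mask = mask,
                 label = spec$class_label, spec = spec,
                 instances = do.call(rbind, inst)),
            class = "synthetic_tile")
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_per_class` tiles for each class as 8-bit RGB PNG, 16-bit
#' TIFF instance masks, and a CSV manifest with header
#' `tile,mask,label,seed`. Tile seeds are `base_seed + index` with a
#' globally increasing index, so seeds are disjoint across classes and
#' each tile is reproducible in isolation.
#'
#' @param n_per_class tiles per class (>= 1).
#' @param base_seed integer base seed.
#' @param out_dir output directory (created if needed).
#' @param classes character vector of class labels to generate.
#' @param ... further arguments passed to [tile_spec()] (e.g. `tile_size`).
#' @return the manifest as a data.frame (paths relative to `out_dir`),
#'   invisibly also written to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n_per_class, base_seed, out_dir,
                             classes = c("gland", "sheet", "scattered"),
                             ...) {
  stopifnot(n_per_class >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  idx <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      seed <- as.integer(base_seed + idx)
      tl <- generate_tile(tile_spec(class_label = cl, seed = seed, ...))
      tile_file <- sprintf("tile_%s_%03d.png", cl, i)
      mask_file <- sprintf("mask_%s_%03d.tif", cl, i)
      write_tile(tl$image, file.path(out_dir, tile_file))
      write_mask(tl$instance_mask, file.path(out_dir, mask_file))
      rows[[idx]] <- data.frame(tile = tile_file, mask = mask_file,
                                label = cl, seed = seed)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest
#'
#' @param path path to a `manifest.csv` written by [generate_dataset()];
#'   relative tile/mask paths are resolved against the manifest directory.
#' @return data.frame with absolute `tile` and `mask` paths.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tile", "mask", "label", "seed") %in% names(m)))
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", m$tile)
  m$tile[rel] <- file.path(base, m$tile[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", m$mask)
  m$mask[rel] <- file.path(base, m$mask[rel])
  m
}
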