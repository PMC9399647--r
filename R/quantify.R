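#' Tile a slide region under a tumor mask
#'
#' Lays a regular grid of `tile`-sized windows (stride `stride`,
#' defaulting to non-overlapping) over the image and keeps every window
#' whose footprint lies at least `min_coverage` inside the tumor mask.
#' Reported coordinates are 0-based (row0, col0) with half-open extents,
#' matching common image tooling.
#'
#' @param image large H x W x 3 array (or any object with dim H, W in
#'   the first two slots).
#' @param tumor_mask binary H x W matrix (nonzero = tumor).
#' @param tile window side in pixels.
#' @param stride grid step in pixels (default `tile`).
#' @param min_coverage minimum fraction of the window inside the mask
#'   (default 0.5).
#' @return data.frame with `row0`, `col0` (0-based) for each kept tile;
#'   zero rows when the mask is empty.
#' @export
tile_region <- function(image, tumor_mask, tile, stride = tile,
                        min_coverage = 0.5) {
  dm <- dim(image)
  stopifnot(all(dim(tumor_mask) == dm[1:2]), tile >= 1, stride >= 1)
  if (dm[1] < tile || dm[2] < tile) {
    return(data.frame(row0 = integer(0), col0 = integer(0)))
  }
  r0s <- seq(0L, dm[1] - tile, by = stride)
  c0s <- seq(0L, dm[2] - tile, by = stride)
  grid <- expand.grid(row0 = r0s, col0 = c0s)
  cov <- vapply(seq_len(nrow(grid)), function(i) {
    mean(tumor_mask[grid$row0[i] + seq_len(tile),
                    grid$col0[i] + seq_len(tile)] != 0)
  }, numeric(1))
  out <- grid[cov >= min_coverage, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$row0, out$col0), , drop = FALSE]
}

#' Round class proportions to 5% increments (largest remainder)
#'
#' Each proportion is expressed in units of 5%; integer parts are kept
#' and the remaining units are assigned in decreasing order of
#' fractional remainder (ties broken by lower class index), so the
#' rounded percentages always sum to exactly 100.
#'
#' @param counts non-negative class counts (sum > 0).
#' @return numeric vector of percentages, each a multiple of 5, summing
#'   to 100.
#' @export
round_percent_5 <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  units <- counts / sum(counts) * 20  # 20 units of 5%
  base <- floor(units)
  left <- 20L - sum(base)
  if (left > 0) {
    rem <- units - base
    ord <- order(-rem, seq_along(counts))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  base * 5
}

#' Quantify growth-pattern proportions over a slide region
#'
#' Tiles the masked region, classifies each tile, and reports per-class
#' tile counts, raw proportions, proportions rounded to the nearest 5%
#' by largest remainder (summing to exactly 100%), the dominant pattern,
#' and a class map painting each tile with its predicted class.
#'
#' @param image H x W x 3 array.
#' @param tumor_mask binary H x W matrix.
#' @param classifier either a `pg_checkpoint` (tiles are featurized and
#'   classified by the trained model) or a function
#'   `function(tile_image) -> class label or index` (e.g. a ground-truth
#'   oracle).
#' @param tile window side in pixels (default 256).
#' @param stride grid step (default `tile`).
#' @param classes class labels; taken from the checkpoint when one is
#'   supplied.
#' @param ... passed to [prepare_dataset()]-style featurization when a
#'   checkpoint is used (`K`, `d`, `descriptor`).
#' @return object of class `quant_report`: list with `tiles`
#'   (data.frame row0, col0, pred), `counts`, `raw` (proportions summing
#'   to 1 over classified tiles), `rounded` (percent, multiples of 5),
#'   `dominant`, and `class_map` (H x W x 3 array).
#' @export
quantify_slide <- function(image, tumor_mask, classifier, tile = 256L,
                           stride = tile, classes = NULL, ...) {
  grid <- tile_region(image, tumor_mask, tile, stride)
  if (nrow(grid) == 0) stop("quantify_slide: no tiles under the mask")
  is_ckpt <- inherits(classifier, "pg_checkpoint")
  if (is_ckpt) classes <- classifier$classes
  preds <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sub <- image[grid$row0[i] + seq_len(tile),
                 grid$col0[i] + seq_len(tile), , drop = FALSE]
    if (is_ckpt) {
      preds[i] <- classify_tile(sub, classifier, ...)
    } else {
      p <- classifier(sub)
      preds[i] <- if (is.numeric(p) && !is.null(classes)) classes[p]
        else as.character(p)
    }
  }
  if (is.null(classes)) classes <- sort(unique(preds))
  counts <- setNames(vapply(classes, function(cl) sum(preds == cl),
                            numeric(1)), classes)
  raw <- counts / sum(counts)
  rounded <- setNames(round_percent_5(counts), classes)
  dominant <- classes[which.max(counts)]
  structure(list(tiles = cbind(grid, pred = preds), counts = counts,
                 raw = raw, rounded = rounded, dominant = dominant,
                 class_map = render_class_map(dim(image), grid, preds,
                                              classes, tile)),
            class = "quant_report")
}

#' Classify one tile with a trained checkpoint
#'
#' Runs the checkpoint's pipeline on a single tile: nuclei from the mask
#' are not available at slide level, so the fallback segmenter provides
#' the instance mask for the cell-graph branch.
#'
#' @param tile_image tile-sized H x W x 3 array.
#' @param ckpt a `pg_checkpoint`.
#' @param segmenter function(image) -> instance label mask; default
#'   [fallback_segment()].
#' @param K,d cell-graph parameters (default the dataset defaults).
#' @return predicted class label (character).
#' @export
classify_tile <- function(tile_image, ckpt, segmenter = fallback_segment,
                          K = 5L, d = 50) {
  mask <- segmenter(tile_image)
  ft <- featurize_tile(tile_image, mask)
  graph <- if (nrow(ft$centroids) > 0) {
    build_graph(ft$centroids, K = K, d = d)
  } else NULL
  sample <- list(
    graph = graph,
    features = feature_norm_apply(ft$features, ckpt$feature_norm),
    image = resize_tile(tile_image, ckpt$cnn_config$input_size))
  ckpt$classes[which.max(model_forward(sample, ckpt)$probabilities)]
}

# Paint each classified tile with its class color over a dimmed copy of
# the slide. Legend order: red, green, yellow, blue, cyan, then a
# recycled rainbow for further classes.
render_class_map <- function(dm, grid, preds, classes, tile) {
  pal <- c("red", "green", "yellow", "blue", "cyan")
  if (length(classes) > length(pal)) {
    pal <- c(pal, grDevices::rainbow(length(classes) - length(pal)))
  }
  rgb <- grDevices::col2rgb(pal[seq_along(classes)])
  map <- array(255L, c(dm[1], dm[2], 3))
  for (i in seq_len(nrow(grid))) {
    ci <- match(preds[i], classes)
    for (ch in 1:3) {
      map[grid$row0[i] + seq_len(tile), grid$col0[i] + seq_len(tile), ch] <-
        as.integer(rgb[ch, ci])
    }
  }
  map
}

#' Write a quantification report to disk
#'
#' JSON report (counts, raw and rounded proportions, dominant pattern),
#' PNG class map, and CSV of per-tile predictions with 0-based
#' coordinates.
#'
#' @param report a `quant_report`.
#' @param dir output directory.
#' @param prefix file name prefix (default `"quant"`).
#' @export
write_quant_report <- function(report, dir, prefix = "quant") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(counts = as.list(report$counts), raw = as.list(report$raw),
         rounded_pct = as.list(report$rounded),
         dominant = report$dominant),
    file.path(dir, paste0(prefix, "_report.json")),
    auto_unbox = TRUE, digits = NA)
  write_tile(report$class_map, file.path(dir, paste0(prefix, "_map.png")))
  write.csv(report$tiles, file.path(dir, paste0(prefix, "_tiles.csv")),
            row.names = FALSE)
  invisible(dir)
}

#' @export
print.quant_report <- function(x, ...) {
  cat("Tiles classified:", nrow(x$tiles), "\n")
  for (cl in names(x$counts)) {
    cat(sprintf("  %-10s %4d tiles  raw %6.2f%%  rounded %3d%%\n", cl,
                x$counts[[cl]], 100 * x$raw[[cl]], x$rounded[[cl]]))
  }
  cat("Dominant pattern:", x$dominant, "\n")
  invisible(x)
}
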