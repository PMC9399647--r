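# Shared fixtures and independent oracles used across the test files.

# Filled disk mask of radius r with a small empty border.
disk_mask <- function(r, pad = 3) {
  d <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  m <- matrix(0L, d, d)
  g <- as.matrix(expand.grid(row = 1:d, col = 1:d))
  m[g[(g[, 1] - ctr)^2 + (g[, 2] - ctr)^2 <= r^2, , drop = FALSE]] <- 1L
  m
}

# Rasterized ellipse mask (semi-axes a >= b, orientation theta).
ellipse_mask <- function(a, b, theta = 0, pad = 4) {
  d <- ceiling(2 * a) + 2 * pad + 1
  ctr <- (d + 1) / 2
  px <- pathograph:::ellipse_pixels(ctr, ctr, a, b, theta, d, d)
  m <- matrix(0L, d, d)
  m[px] <- 1L
  m
}

iou <- function(a, b) sum(a > 0 & b > 0) / sum(a > 0 | b > 0)

# Independent O(m^2) brute-force KNN + distance-threshold oracle: directed
# edge (i, j) iff j is among i's K nearest (ties by lower index) and
# D(i, j) < d.
brute_force_edges <- function(cent, K, d) {
  m <- nrow(cent)
  edges <- matrix(integer(0), 0, 2)
  if (m < 2) return(edges)
  for (i in seq_len(m)) {
    dists <- rep(Inf, m)
    for (j in seq_len(m)) {
      if (j != i) dists[j] <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    }
    ord <- order(dists, seq_len(m))
    nb <- ord[seq_len(min(K, m - 1))]
    for (j in nb) if (dists[j] < d) edges <- rbind(edges, c(i, j))
  }
  edges
}

edge_set_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(edges[, 1], edges[, 2]))
}

# Central-difference numeric gradient over a flat named parameter list.
num_grad_params <- function(fn, params, eps = 1e-5) {
  g <- lapply(params, function(p) p * 0)
  for (k in names(params)) {
    for (i in seq_along(params[[k]])) {
      p1 <- params; p1[[k]][i] <- p1[[k]][i] + eps
      p2 <- params; p2[[k]][i] <- p2[[k]][i] - eps
      g[[k]][i] <- (fn(p1) - fn(p2)) / (2 * eps)
    }
  }
  g
}

grad_rel_err <- function(a, b) {
  num <- sqrt(sum(unlist(Map(function(x, y) sum((x - y)^2), a, b))))
  den <- sqrt(sum(unlist(lapply(a, function(x) sum(x^2)))))
  num / max(den, 1e-12)
}

# Small in-memory tile set, memoized across test files.
.fixture_env <- new.env(parent = emptyenv())

small_tiles <- function(n_per_class = 10, base_seed = 7000) {
  key <- sprintf("tiles_%d_%d", n_per_class, base_seed)
  if (is.null(.fixture_env[[key]])) {
    tiles <- list()
    i <- 0
    for (cl in c("gland", "sheet", "scattered")) {
      for (s in seq_len(n_per_class)) {
        i <- i + 1
        tiles[[i]] <- generate_tile(tile_spec(class_label = cl,
                                              seed = base_seed + i))
      }
    }
    .fixture_env[[key]] <- tiles
  }
  .fixture_env[[key]]
}

small_dataset <- function(n_per_class = 10, base_seed = 7000) {
  key <- sprintf("ds_%d_%d", n_per_class, base_seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- prepare_dataset(small_tiles(n_per_class,
                                                       base_seed))
  }
  .fixture_env[[key]]
}
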