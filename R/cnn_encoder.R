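#' Configuration of the VGG-style semantic encoder
#'
#' A stack of 3x3 convolution + ReLU stages, each followed by 2x2 max
#' pooling that halves the spatial size, then one fully connected layer
#' producing the semantic embedding h_s of the whole tile.
#'
#' Two variants are provided: `vgg16` (the classical 13-conv/5-pool
#' layout, h_s of length 1024) and `vgg_small`, a desk-scale encoder
#' with one conv per pooling stage (8, 16, 32, 32 channels) and h_s of
#' length 64, trainable on a CPU.
#'
#' @param variant `"vgg_small"` (default) or `"vgg16"`.
#' @param out_dim length of h_s; defaults 64 (vgg_small) / 1024 (vgg16).
#' @param input_size input tile side in pixels; must be divisible by
#'   2^(number of pool stages). Defaults 64 (vgg_small) / 224 (vgg16).
#' @param seed integer seed for Glorot-uniform initialization.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(variant = c("vgg_small", "vgg16"), out_dim = NULL,
                       input_size = NULL, seed = 1L) {
  variant <- match.arg(variant)
  stages <- if (variant == "vgg16") {
    list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
         c(512L, 512L, 512L), c(512L, 512L, 512L))
  } else {
    list(8L, 16L, 32L, 32L)
  }
  out_dim <- as.integer(out_dim %||% if (variant == "vgg16") 1024L else 64L)
  input_size <- as.integer(input_size %||%
                             if (variant == "vgg16") 224L else 64L)
  stopifnot(out_dim >= 1, input_size %% (2^length(stages)) == 0)
  structure(list(variant = variant, stages = stages, out_dim = out_dim,
                 input_size = input_size, seed = as.integer(seed)),
            class = "cnn_config")
}

#' @rdname cnn_config
#' @param config a `cnn_config`.
#' @return `cnn_init` returns the parameter list (per-conv `W`/`b` and
#'   the fully connected `Wfc`/`bfc`).
#' @export
cnn_init <- function(config) {
  set.seed(config$seed)
  params <- list()
  cin <- 3L
  for (s in seq_along(config$stages)) {
    for (j in seq_along(config$stages[[s]])) {
      f <- config$stages[[s]][j]
      params[[sprintf("W%d_%d", s, j)]] <- glorot_uniform(9L * cin, f)
      params[[sprintf("b%d_%d", s, j)]] <- numeric(f)
      cin <- f
    }
  }
  side <- config$input_size / 2^length(config$stages)
  params$Wfc <- glorot_uniform(side^2 * cin, config$out_dim)
  params$bfc <- numeric(config$out_dim)
  params
}

# 3x3 same-padding im2col: H x W x C array -> (H*W) x (9C) patch matrix.
# The gather indices into the zero-padded array depend only on the shape,
# so they are computed once per (H, W, C) and cached.
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(H, W, C) {
  key <- sprintf("%d_%d_%d", H, W, C)
  idx <- .im2col_cache[[key]]
  if (is.null(idx)) {
    Hp <- H + 2L
    base <- outer(2:(H + 1), (2:(W + 1) - 1L) * Hp, "+")  # center cells
    idx <- matrix(0L, H * W, 9L * C)
    k <- 0L
    for (di in -1:1) for (dj in -1:1) {
      k <- k + 1L
      off <- as.integer(base + di + dj * Hp)
      for (ch in seq_len(C)) {
        idx[, (k - 1L) * C + ch] <- off + (ch - 1L) * Hp * (W + 2L)
      }
    }
    .im2col_cache[[key]] <- idx
  }
  idx
}

conv_im2col <- function(x) {
  dm <- dim(x)
  H <- dm[1]; W <- dm[2]; C <- dm[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  P <- xp[im2col_indices(H, W, C)]
  dim(P) <- c(H * W, 9L * C)
  P
}

conv_col2im <- function(dP, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    k <- k + 1L
    blk <- dP[, ((k - 1L) * C + 1L):(k * C)]
    dim(blk) <- c(H, W, C)
    dxp[(1:H) + di, (1:W) + dj, ] <-
      dxp[(1:H) + di, (1:W) + dj, , drop = FALSE] + blk
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

maxpool2_forward <- function(x, want_masks = TRUE) {
  dm <- dim(x)
  stopifnot(dm[1] %% 2 == 0, dm[2] %% 2 == 0)
  ro <- seq(1, dm[1], 2); co <- seq(1, dm[2], 2)
  a <- x[ro, co, , drop = FALSE]; b <- x[ro, co + 1, , drop = FALSE]
  cc <- x[ro + 1, co, , drop = FALSE]; d <- x[ro + 1, co + 1, , drop = FALSE]
  y <- pmax(a, b, cc, d)
  if (!want_masks) return(list(y = y))
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !m1 & !m2
  m4 <- (d == y) & !m1 & !m2 & !m3
  list(y = y, masks = list(m1, m2, m3, m4))
}

maxpool2_backward <- function(dy, masks, H, W) {
  C <- dim(dy)[3]
  dx <- array(0, c(H, W, C))
  ro <- seq(1, H, 2); co <- seq(1, W, 2)
  dx[ro, co, ] <- dy * masks[[1]]
  dx[ro, co + 1, ] <- dy * masks[[2]]
  dx[ro + 1, co, ] <- dy * masks[[3]]
  dx[ro + 1, co + 1, ] <- dy * masks[[4]]
  dx
}

# Forward pass; with train = TRUE the caches needed for backprop are kept.
cnn_forward <- function(x, config, params, train = FALSE) {
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3,
            dim(x)[1] == config$input_size, dim(x)[2] == config$input_size)
  cache <- list(P = list(), act = list(), masks = list(), hw = list())
  li <- 0L
  for (s in seq_along(config$stages)) {
    for (j in seq_along(config$stages[[s]])) {
      li <- li + 1L
      dm <- dim(x)
      P <- conv_im2col(x)
      Y <- P %*% params[[sprintf("W%d_%d", s, j)]]
      Y <- sweep(Y, 2, params[[sprintf("b%d_%d", s, j)]], "+")
      act <- Y > 0
      Y[!act] <- 0
      dim(Y) <- c(dm[1], dm[2], ncol(act))
      x <- Y
      if (train) {
        cache$P[[li]] <- P
        cache$act[[li]] <- act  # ReLU derivative mask, (H*W) x F
        cache$hw[[li]] <- dm
      }
    }
    dm_in <- dim(x)
    mp <- maxpool2_forward(x, want_masks = train)
    # bookkeeping: every pooling stage halves the spatial size
    stopifnot(all(dim(mp$y)[1:2] == dm_in[1:2] / 2))
    x <- mp$y
    if (train) cache$masks[[s]] <- mp$masks
  }
  v <- as.vector(x)
  h_s <- as.numeric(v %*% params$Wfc + params$bfc)
  if (train) {
    cache$v <- v
    cache$feat_dim <- dim(x)
  }
  list(h_s = h_s, cache = if (train) cache else NULL)
}

cnn_backward <- function(dh_s, cache, config, params) {
  grads <- zeros_like(params)
  grads$Wfc <- outer(cache$v, dh_s)
  grads$bfc <- dh_s
  dx <- array(as.numeric(params$Wfc %*% dh_s), cache$feat_dim)
  li <- sum(lengths(config$stages))
  for (s in rev(seq_along(config$stages))) {
    last_hw <- cache$hw[[li]]
    dx <- maxpool2_backward(dx, cache$masks[[s]], last_hw[1], last_hw[2])
    for (j in rev(seq_along(config$stages[[s]]))) {
      dm <- cache$hw[[li]]
      dYm <- dx
      dim(dYm) <- dim(cache$act[[li]])
      dYm <- dYm * cache$act[[li]]
      grads[[sprintf("W%d_%d", s, j)]] <- crossprod(cache$P[[li]], dYm)
      grads[[sprintf("b%d_%d", s, j)]] <- colSums(dYm)
      if (li > 1L) {
        dP <- dYm %*% t(params[[sprintf("W%d_%d", s, j)]])
        dx <- conv_col2im(dP, dm[1], dm[2], dm[3])
      }
      li <- li - 1L
    }
  }
  grads
}

#' Embed a tile with the semantic CNN branch
#'
#' @param tile H x W x 3 numeric array; integers 0..255 are rescaled to
#'   0..1, then the optional per-channel normalization statistics
#'   (fitted on the training split) are applied. H and W must equal
#'   `config$input_size`.
#' @param config a [cnn_config()].
#' @param params parameters from [cnn_init()].
#' @param input_norm optional list with per-channel `mean` and `sd`.
#' @return numeric vector `h_s` of length `config$out_dim`.
#' @export
encode_image <- function(tile, config, params, input_norm = NULL) {
  x <- prep_cnn_input(tile, input_norm)
  cnn_forward(x, config, params)$h_s
}

prep_cnn_input <- function(tile, input_norm = NULL) {
  x <- tile
  if (max(x) > 1.5) x <- x / 255
  if (!is.null(input_norm)) {
    for (ch in 1:3) {
      x[, , ch] <- (x[, , ch] - input_norm$mean[ch]) / input_norm$sd[ch]
    }
  }
  x
}

#' Resize a tile to the CNN input size
#'
#' Bilinear resizing of an RGB tile (values preserved in 0..255).
#'
#' @param image H x W x 3 array.
#' @param size target side in pixels.
#' @return size x size x 3 numeric array.
#' @export
resize_tile <- function(image, size) {
  if (dim(image)[1] == size && dim(image)[2] == size) return(image * 1)
  wh <- EBImage::Image(aperm(image / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(wh, w = size, h = size)
  aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
}
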