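#' Configuration of the graph-convolutional encoder
#'
#' The encoder stacks spectral-normalized graph convolutions
#' `H^(l+1) = sigma(A_norm H^(l) W^(l))`, applies a permutation-invariant
#' readout over nodes, and maps the pooled vector linearly to the graph
#' embedding h_c.
#'
#' @param layer_widths channel counts along the layer chain; the first
#'   entry is the node-feature width, each following entry a layer output
#'   width (default c(24, 32, 32): 24 input features, two hidden layers).
#' @param activation `"relu"` or `"identity"`.
#' @param readout `"mean"`, `"max"` or `"sum"` (default mean).
#' @param embed_dim width of h_c (default 32).
#' @param seed integer seed for Glorot-uniform initialization.
#' @return object of class `gcn_config`.
#' @export
gcn_config <- function(layer_widths = c(24L, 32L, 32L),
                       activation = c("relu", "identity"),
                       readout = c("mean", "max", "sum"),
                       embed_dim = 32L, seed = 1L) {
  stopifnot(length(layer_widths) >= 2, all(layer_widths >= 1), embed_dim >= 1)
  structure(list(layer_widths = as.integer(layer_widths),
                 activation = match.arg(activation),
                 readout = match.arg(readout),
                 embed_dim = as.integer(embed_dim),
                 seed = as.integer(seed)),
            class = "gcn_config")
}

#' @rdname gcn_config
#' @param config a `gcn_config`.
#' @return `gcn_init` returns the parameter list (layer weights `W1..Wl`,
#'   readout projection `Wout`, `bout`).
#' @export
gcn_init <- function(config) {
  set.seed(config$seed)
  w <- config$layer_widths
  params <- list()
  for (l in seq_len(length(w) - 1)) {
    params[[paste0("W", l)]] <- glorot_uniform(w[l], w[l + 1])
  }
  params$Wout <- glorot_uniform(w[length(w)], config$embed_dim)
  params$bout <- numeric(config$embed_dim)
  params
}

#' One graph-convolution layer
#'
#' Computes exactly `sigma(A_norm %*% H %*% W)`.
#'
#' @param H m x k node feature matrix.
#' @param A_norm m x m normalized propagation matrix (see
#'   [normalize_adjacency()]).
#' @param W k x k' weight matrix.
#' @param sigma activation function (default [relu]).
#' @return m x k' matrix.
#' @export
gcn_layer <- function(H, A_norm, W, sigma = relu) {
  stopifnot(nrow(H) == nrow(A_norm), ncol(A_norm) == nrow(H),
            ncol(H) == nrow(W))
  sigma(A_norm %*% H %*% W)
}

# Forward pass with cache for backprop. Empty graphs (m = 0) produce the
# zero embedding so nucleus-free tiles do not crash the pipeline.
gcn_forward <- function(graph, config, params) {
  H <- graph$node_features
  m <- nrow(graph$centroids)
  if (m == 0 || is.null(H) || nrow(H) == 0) {
    return(list(h_c = numeric(config$embed_dim), empty = TRUE))
  }
  act <- if (config$activation == "relu") relu else identity
  An <- graph$A_norm
  nl <- length(config$layer_widths) - 1
  pre <- vector("list", nl)
  Hs <- vector("list", nl + 1)
  Hs[[1]] <- H
  for (l in seq_len(nl)) {
    pre[[l]] <- An %*% Hs[[l]] %*% params[[paste0("W", l)]]
    Hs[[l + 1]] <- act(pre[[l]])
  }
  HL <- Hs[[nl + 1]]
  r <- switch(config$readout,
              mean = colMeans(HL),
              sum = colSums(HL),
              max = apply(HL, 2, max))
  h_c <- as.numeric(r %*% params$Wout + params$bout)
  list(h_c = h_c, empty = FALSE, Hs = Hs, pre = pre, r = r, An = An, m = m)
}

# Backward pass: dh_c (length embed_dim) -> parameter gradients.
gcn_backward <- function(dh_c, cache, config, params) {
  grads <- zeros_like(params)
  if (isTRUE(cache$empty)) return(grads)
  grads$Wout <- outer(cache$r, dh_c)
  grads$bout <- dh_c
  dr <- as.numeric(params$Wout %*% dh_c)
  HL <- cache$Hs[[length(cache$Hs)]]
  m <- cache$m
  dHL <- switch(config$readout,
                mean = matrix(dr / m, m, length(dr), byrow = TRUE),
                sum = matrix(dr, m, length(dr), byrow = TRUE),
                max = {
                  dH <- matrix(0, m, length(dr))
                  for (j in seq_along(dr)) {
                    i <- which.max(HL[, j])
                    dH[i, j] <- dr[j]
                  }
                  dH
                })
  act_grad <- if (config$activation == "relu") drelu else function(x) 1
  dH <- dHL
  nl <- length(config$layer_widths) - 1
  for (l in rev(seq_len(nl))) {
    dpre <- dH * act_grad(cache$pre[[l]])
    AH <- cache$An %*% cache$Hs[[l]]
    grads[[paste0("W", l)]] <- crossprod(AH, dpre)
    if (l > 1) dH <- t(cache$An) %*% dpre %*% t(params[[paste0("W", l)]])
  }
  grads
}

#' Embed a cell graph
#'
#' Applies the configured stack of graph convolutions, the readout and
#' the output projection. An empty graph (no nuclei) returns the zero
#' embedding with a message rather than an error.
#'
#' @param graph a `cell_graph` whose `node_features` width matches
#'   `config$layer_widths[1]`.
#' @param config a [gcn_config()].
#' @param params parameters from [gcn_init()].
#' @return numeric vector `h_c` of length `config$embed_dim`.
#' @export
encode_graph <- function(graph, config, params) {
  fw <- gcn_forward(graph, config, params)
  if (isTRUE(fw$empty)) message("encode_graph: empty graph, zero embedding")
  fw$h_c
}
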