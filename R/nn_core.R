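# Small neural-network primitives shared by the GCN, CNN and fusion
# modules. Parameters are flat named lists of numeric matrices/vectors;
# gradients mirror that structure, which lets one Adam implementation
# serve every component.

relu <- function(x) pmax(x, 0)
drelu <- function(x) (x > 0) * 1
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(logits) {
  # rows = samples
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

glorot_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  Map(`+`, acc, g)
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

#' @noRd
adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# One Adam step; lr may be a scalar or a named vector keyed by parameter
# name prefix groups (see lr_for). Returns list(params, state).
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    lrk <- if (length(lr) == 1) lr else lr[[k]]
    params[[k]] <- params[[k]] - lrk * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Flatten a nested list of parameter blocks into one named list with
# "<block>." prefixes, and restore it.
flatten_params <- function(blocks) {
  out <- list()
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    for (pn in names(b)) out[[paste0(bn, ".", pn)]] <- b[[pn]]
  }
  out
}

unflatten_params <- function(flat) {
  out <- list()
  for (k in names(flat)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    out[[parts[1]]][[parts[2]]] <- flat[[k]]
  }
  out
}
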