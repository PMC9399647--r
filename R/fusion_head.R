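#' Configuration of the gated Kronecker-product fusion head
#'
#' Each branch embedding is linearly projected (with ReLU) to
#' `proj_dim`, scaled elementwise by a sigmoid gate computed from the
#' concatenation of both projected embeddings, fused by the outer
#' (Kronecker) product of the two gated vectors, and classified by one
#' fully connected layer with softmax.
#'
#' @param proj_dim projection width per branch before fusion (default
#'   32, so the fused tensor has 32 x 32 = 1024 entries).
#' @param n_classes number of classes.
#' @param append_one if TRUE, a constant 1 is appended to each gated
#'   vector before the outer product so unimodal terms survive in the
#'   fused tensor (off by default: the plain outer product).
#' @param seed integer seed for initialization.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(proj_dim = 32L, n_classes = 3L,
                          append_one = FALSE, seed = 1L) {
  stopifnot(proj_dim >= 1, n_classes >= 2)
  structure(list(proj_dim = as.integer(proj_dim),
                 n_classes = as.integer(n_classes),
                 append_one = isTRUE(append_one),
                 seed = as.integer(seed)),
            class = "fusion_config")
}

#' @rdname fusion_config
#' @param config a `fusion_config`.
#' @param dc,ds widths of the incoming h_c and h_s.
#' @return `fusion_init` returns the parameter list.
#' @export
fusion_init <- function(config, dc, ds) {
  set.seed(config$seed)
  p <- config$proj_dim
  fl <- if (config$append_one) (p + 1L)^2 else p^2
  list(Wc = glorot_uniform(dc, p), bc = numeric(p),
       Ws = glorot_uniform(ds, p), bs = numeric(p),
       Wzc = glorot_uniform(dc + ds, p), bzc = numeric(p),
       Wzs = glorot_uniform(dc + ds, p), bzs = numeric(p),
       Wcls = glorot_uniform(fl, config$n_classes),
       bcls = numeric(config$n_classes))
}

#' Gated attention over the two branch embeddings
#'
#' For each modality m in {c, s}: `h_m <- ReLU(W_m h_m + b_m)` projects
#' to `proj_dim`; the per-feature importance score
#' `z_m = sigmoid(W_cs->m [h_c; h_s] + b)` is computed from the
#' concatenation of the two incoming branch embeddings; the gated
#' representation is the elementwise product `z_m * h_m`.
#'
#' @param h_c,h_s branch embedding vectors.
#' @param params parameters from [fusion_init()].
#' @return list with `h_c_gated`, `h_s_gated`, the gates `z_c`, `z_s`
#'   and the projected vectors.
#' @export
gate <- function(h_c, h_s, params) {
  pc_pre <- as.numeric(h_c %*% params$Wc + params$bc)
  ps_pre <- as.numeric(h_s %*% params$Ws + params$bs)
  pc <- relu(pc_pre)
  ps <- relu(ps_pre)
  cat2 <- c(h_c, h_s)
  zc_pre <- as.numeric(cat2 %*% params$Wzc + params$bzc)
  zs_pre <- as.numeric(cat2 %*% params$Wzs + params$bzs)
  z_c <- sigmoid(zc_pre)
  z_s <- sigmoid(zs_pre)
  list(h_c_gated = z_c * pc, h_s_gated = z_s * ps,
       z_c = z_c, z_s = z_s, pc = pc, ps = ps,
       pc_pre = pc_pre, ps_pre = ps_pre, zc_pre = zc_pre, zs_pre = zs_pre)
}

#' Kronecker (outer-product) fusion of two gated embeddings
#'
#' `h_fusion[(i-1)*q + j] = a[i] * b[j]`: the outer product flattened
#' row-major, capturing every pairwise multiplicative interaction
#' between the two modalities.
#'
#' @param a,b numeric vectors of lengths p and q.
#' @return numeric vector of length p*q.
#' @export
kronecker_fuse <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  as.vector(t(outer(a, b)))
}

#' Linear classifier over the fused tensor
#'
#' @param h_fusion fused vector.
#' @param params parameters holding `Wcls`, `bcls`.
#' @return list with `logits` and softmax `probabilities`.
#' @export
classify <- function(h_fusion, params) {
  logits <- as.numeric(h_fusion %*% params$Wcls + params$bcls)
  p <- exp(logits - max(logits))
  list(logits = logits, probabilities = p / sum(p))
}

#' Mean cross-entropy loss
#'
#' `-mean(log q_b[true class])` over the batch, with the predicted
#' probability clamped at 1e-12.
#'
#' @param batch_probs B x C matrix of predicted class probabilities.
#' @param batch_labels integer class labels in 1..C (or a B x C one-hot
#'   matrix).
#' @return scalar loss.
#' @export
cross_entropy <- function(batch_probs, batch_labels) {
  batch_probs <- rbind(batch_probs)
  if (is.matrix(batch_labels)) {
    batch_labels <- max.col(batch_labels, ties.method = "first")
  }
  stopifnot(all(batch_labels >= 1), all(batch_labels <= ncol(batch_probs)))
  q <- batch_probs[cbind(seq_len(nrow(batch_probs)), batch_labels)]
  mean(-log(pmax(q, 1e-12)))
}

# Full fusion-head forward with cache.
fusion_forward <- function(h_c, h_s, config, params) {
  g <- gate(h_c, h_s, params)
  a <- g$h_c_gated; b <- g$h_s_gated
  if (config$append_one) { a <- c(a, 1); b <- c(b, 1) }
  fused <- kronecker_fuse(a, b)
  cl <- classify(fused, params)
  c(list(logits = cl$logits, probabilities = cl$probabilities,
         fused = fused, a = a, b = b, h_c = h_c, h_s = h_s), g)
}

# Backward from dlogits; returns parameter grads plus dh_c, dh_s.
fusion_backward <- function(dlogits, cache, config, params) {
  grads <- zeros_like(params)
  grads$Wcls <- outer(cache$fused, dlogits)
  grads$bcls <- dlogits
  dfused <- as.numeric(params$Wcls %*% dlogits)
  q <- length(cache$b)
  M <- matrix(dfused, q, length(cache$a))  # column i = dfused block of a_i
  da <- as.numeric(crossprod(M, cache$b))
  db <- as.numeric(M %*% cache$a)
  p <- config$proj_dim
  if (config$append_one) { da <- da[seq_len(p)]; db <- db[seq_len(p)] }
  # gated = z * proj
  dz_c <- da * cache$pc
  dpc <- da * cache$z_c
  dz_s <- db * cache$ps
  dps <- db * cache$z_s
  dzc_pre <- dz_c * cache$z_c * (1 - cache$z_c)
  dzs_pre <- dz_s * cache$z_s * (1 - cache$z_s)
  cat2 <- c(cache$h_c, cache$h_s)
  grads$Wzc <- outer(cat2, dzc_pre)
  grads$bzc <- dzc_pre
  grads$Wzs <- outer(cat2, dzs_pre)
  grads$bzs <- dzs_pre
  dcat <- as.numeric(params$Wzc %*% dzc_pre) +
    as.numeric(params$Wzs %*% dzs_pre)
  dc <- length(cache$h_c)
  dpc_pre <- dpc * drelu(cache$pc_pre)
  dps_pre <- dps * drelu(cache$ps_pre)
  grads$Wc <- outer(cache$h_c, dpc_pre)
  grads$bc <- dpc_pre
  grads$Ws <- outer(cache$h_s, dps_pre)
  grads$bs <- dps_pre
  list(grads = grads,
       dh_c = as.numeric(params$Wc %*% dpc_pre) + dcat[seq_len(dc)],
       dh_s = as.numeric(params$Ws %*% dps_pre) + dcat[dc + seq_along(cache$h_s)])
}
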