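test_that("kronecker fusion enumerates pairwise products row-major", {
  expect_equal(kronecker_fuse(c(1, 2), c(3, 4)), c(3, 4, 6, 8))
  expect_equal(kronecker_fuse(c(2, -1, 3), numeric(2) * 0), numeric(6))
  expect_length(kronecker_fuse(rnorm(32), rnorm(32)), 1024)
  # bilinearity: scaling one side scales the output exactly
  set.seed(41)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(kronecker_fuse(2.5 * a, b), 2.5 * kronecker_fuse(a, b))
  expect_equal(kronecker_fuse(a, -3 * b), -3 * kronecker_fuse(a, b))
})

test_that("gates open and close the branch embeddings as designed", {
  cfg <- fusion_config(proj_dim = 4, n_classes = 3, seed = 42)
  params <- fusion_init(cfg, 6, 8)
  set.seed(43)
  h_c <- rnorm(6); h_s <- rnorm(8)
  # force open gates: zero gate weights, large positive bias
  po <- params
  po$Wzc[] <- 0; po$bzc[] <- 50
  po$Wzs[] <- 0; po$bzs[] <- 50
  go <- gate(h_c, h_s, po)
  expect_equal(go$h_c_gated, go$pc, tolerance = 1e-12)
  expect_equal(go$h_s_gated, go$ps, tolerance = 1e-12)
  # force closed gates
  pc <- params
  pc$Wzc[] <- 0; pc$bzc[] <- -50
  pc$Wzs[] <- 0; pc$bzs[] <- -50
  gc <- gate(h_c, h_s, pc)
  expect_equal(gc$h_c_gated, numeric(4), tolerance = 1e-12)
  # finite inputs give gates strictly inside (0,1): contraction
  g <- gate(h_c, h_s, params)
  expect_true(all(g$z_c > 0 & g$z_c < 1))
  if (sum(g$pc^2) > 0) {
    expect_lt(sqrt(sum(g$h_c_gated^2)), sqrt(sum(g$pc^2)))
  }
})

test_that("the classifier head behaves like a softmax linear model", {
  params <- list(Wcls = matrix(0, 10, 4), bcls = numeric(4))
  cl <- classify(rnorm(10), params)
  expect_equal(cl$probabilities, rep(0.25, 4))
  # shift invariance of softmax
  set.seed(44)
  params$Wcls <- matrix(rnorm(40), 10, 4)
  h <- rnorm(10)
  p1 <- classify(h, params)$probabilities
  params$bcls <- params$bcls + 7
  p2 <- classify(h, params)$probabilities
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
})

test_that("cross-entropy matches its closed forms and is monotone", {
  expect_equal(cross_entropy(matrix(c(1, 0, 0), 1), 1L), 0)
  expect_equal(cross_entropy(matrix(rep(0.2, 5), 1), 3L), log(5),
               tolerance = 1e-12)
  l1 <- cross_entropy(matrix(c(0.5, 0.3, 0.2), 1), 1L)
  l2 <- cross_entropy(matrix(c(0.7, 0.2, 0.1), 1), 1L)
  expect_lt(l2, l1)
  expect_error(cross_entropy(matrix(c(0.5, 0.5), 1), 3L))
  # batch mean over rows, one-hot labels accepted
  probs <- rbind(c(0.6, 0.4), c(0.1, 0.9))
  expect_equal(cross_entropy(probs, c(1L, 2L)),
               mean(-log(c(0.6, 0.9))))
  expect_equal(cross_entropy(probs, rbind(c(1, 0), c(0, 1))),
               cross_entropy(probs, c(1L, 2L)))
})

test_that("zeroing one branch projection isolates the bias path", {
  cfg <- fusion_config(proj_dim = 3, n_classes = 3, seed = 45)
  params <- fusion_init(cfg, 5, 5)
  params$Wc[] <- 0
  params$bc[] <- 0
  set.seed(46)
  l1 <- pathograph:::fusion_forward(rnorm(5), rnorm(5), cfg, params)$logits
  l2 <- pathograph:::fusion_forward(rnorm(5), rnorm(5), cfg, params)$logits
  expect_equal(l1, params$bcls, tolerance = 1e-12)
  expect_equal(l2, params$bcls, tolerance = 1e-12)
})

test_that("analytic fusion gradients match numeric differentiation on a batch", {
  cfg <- fusion_config(proj_dim = 3, n_classes = 3, seed = 47)
  params <- fusion_init(cfg, 4, 5)
  set.seed(48)
  batch <- list(list(h_c = rnorm(4), h_s = rnorm(5), y = 1L),
                list(h_c = rnorm(4), h_s = rnorm(5), y = 3L))
  loss <- function(p) {
    probs <- t(vapply(batch, function(s)
      pathograph:::fusion_forward(s$h_c, s$h_s, cfg, p)$probabilities,
      numeric(3)))
    cross_entropy(probs, vapply(batch, `[[`, integer(1), "y"))
  }
  analytic <- NULL
  for (s in batch) {
    fw <- pathograph:::fusion_forward(s$h_c, s$h_s, cfg, params)
    dlogits <- fw$probabilities
    dlogits[s$y] <- dlogits[s$y] - 1
    fb <- pathograph:::fusion_backward(dlogits / length(batch), fw, cfg,
                                       params)
    analytic <- if (is.null(analytic)) fb$grads
      else Map(`+`, analytic, fb$grads)
  }
  numeric <- num_grad_params(loss, params)
  expect_lt(grad_rel_err(analytic, numeric), 1e-4)
})

test_that("append-one fusion preserves unimodal terms", {
  cfg <- fusion_config(proj_dim = 3, n_classes = 2, append_one = TRUE,
                       seed = 49)
  params <- fusion_init(cfg, 4, 4)
  expect_identical(nrow(params$Wcls), 16L)
  fw <- pathograph:::fusion_forward(rnorm(4), rnorm(4), cfg, params)
  expect_length(fw$fused, 16)
  expect_equal(fw$fused[16], 1)  # the 1 x 1 constant cell
})
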