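#' Training configuration
#'
#' Defaults follow a two-stage protocol: each branch is trained alone
#' with Adam at `lr` (0.001), then the joint fused model is fine-tuned,
#' with the pretrained branch weights moving at `lr_finetune` (0.00001)
#' while the freshly initialised fusion head trains at `lr`. Desk-scale
#' defaults (batch 16, 30 epochs) keep a CPU run short; batch 64 /
#' 100 fine-tuning epochs reproduce the original regime.
#'
#' @param mode `"gcn"`, `"cnn"` or `"fused"`.
#' @param lr Adam learning rate for branch training and for the fusion
#'   head (default 0.001).
#' @param lr_finetune learning rate applied to pretrained branch weights
#'   during fused fine-tuning (default 1e-5).
#' @param batch_size minibatch size (default 16).
#' @param epochs training epochs (default 30).
#' @param seed seed controlling split, initialization and batch order.
#' @param split train/val/test fractions, summing to 1.
#' @return object of class `train_config`.
#' @export
train_config <- function(mode = c("gcn", "cnn", "fused"), lr = 0.001,
                         lr_finetune = 0.00001, batch_size = 16L,
                         epochs = 30L, seed = 1L,
                         split = c(train = 0.7, val = 0.15, test = 0.15)) {
  mode <- match.arg(mode)
  stopifnot(lr > 0, lr_finetune > 0, batch_size >= 1, epochs >= 1,
            abs(sum(split) - 1) < 1e-8, all(split >= 0))
  structure(list(mode = mode, lr = lr, lr_finetune = lr_finetune,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 split = split),
            class = "train_config")
}

#' Prepare a dataset for training and evaluation
#'
#' For each tile: nucleus features and centroids are computed with
#' [featurize_tile()], the cell graph is built with [build_graph()], and
#' the image is resized to the CNN input size. Raw (un-normalized)
#' features are kept; normalization statistics are fitted later on the
#' training split only.
#'
#' @param tiles either a manifest data.frame (columns `tile`, `mask`,
#'   `label`; see [read_manifest()]) or a list of `synthetic_tile`
#'   objects.
#' @param input_size CNN input side (tiles are resized to it).
#' @param K,d cell-graph parameters (see [build_graph()]).
#' @param descriptor patch-descriptor function (see [featurize_tile()]).
#' @return object of class `pg_dataset`: list of samples (`graph`,
#'   `features_raw`, `image`, `label`) plus `classes` and `input_size`.
#' @export
prepare_dataset <- function(tiles, input_size = 64L, K = 5L, d = 50,
                            descriptor = function(img, ctr)
                              patch_descriptor(img, ctr, 64L)) {
  if (is.data.frame(tiles)) {
    labels <- tiles$label
    loader <- function(i) list(image = read_tile(tiles$tile[i]),
                               mask = read_mask(tiles$mask[i]))
    n <- nrow(tiles)
    ids <- basename(tiles$tile)
  } else {
    labels <- vapply(tiles, function(t) t$label, character(1))
    loader <- function(i) list(image = tiles[[i]]$image,
                               mask = tiles[[i]]$instance_mask)
    n <- length(tiles)
    ids <- sprintf("tile_%04d", seq_len(n))
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("prepare_dataset: need at least 2 classes")
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- loader(i)
    ft <- featurize_tile(tm$image, tm$mask, descriptor = descriptor)
    graph <- if (nrow(ft$centroids) > 0) {
      build_graph(ft$centroids, node_features = NULL, K = K, d = d)
    } else NULL
    samples[[i]] <- list(graph = graph, features_raw = ft$features,
                         image = resize_tile(tm$image, input_size),
                         label = match(labels[i], classes))
  }
  structure(list(samples = samples, classes = classes, ids = ids,
                 input_size = as.integer(input_size), K = K, d = d),
            class = "pg_dataset")
}

# Stratified split indices by class, deterministic in seed.
split_dataset <- function(labels, split, seed) {
  set.seed(seed)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in unique(labels)) {
    cl_idx <- sample(which(labels == cl))
    n <- length(cl_idx)
    n_tr <- round(split[["train"]] * n)
    n_va <- round(split[["val"]] * n)
    idx$train <- c(idx$train, cl_idx[seq_len(n_tr)])
    idx$val <- c(idx$val, cl_idx[n_tr + seq_len(min(n_va, n - n_tr))])
    idx$test <- c(idx$test, cl_idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  lapply(idx, sort)
}

# Forward one sample under a mode; returns probabilities and caches.
model_forward <- function(sample, ckpt, train = FALSE) {
  mode <- ckpt$mode
  out <- list()
  if (mode %in% c("gcn", "fused")) {
    g <- sample$graph
    if (!is.null(g)) g$node_features <- sample[["features"]]
    out$gf <- gcn_forward(g %||% list(centroids = matrix(numeric(0), 0, 2)),
                          ckpt$gcn_config, ckpt$params$gcn)
  }
  if (mode %in% c("cnn", "fused")) {
    x <- sample[["x"]] %||% prep_cnn_input(sample$image, ckpt$input_norm)
    out$cf <- cnn_forward(x, ckpt$cnn_config, ckpt$params$cnn, train = train)
  }
  if (mode == "fused") {
    out$ff <- fusion_forward(out$gf$h_c, out$cf$h_s, ckpt$fusion_config,
                             ckpt$params$fusion)
    out$probabilities <- out$ff$probabilities
  } else {
    h <- if (mode == "gcn") out$gf$h_c else out$cf$h_s
    cl <- classify(h, list(Wcls = ckpt$params$head$W,
                           bcls = ckpt$params$head$b))
    out$h <- h
    out$probabilities <- cl$probabilities
  }
  out
}

# Backward one sample; dlogits already divided by batch size.
model_backward <- function(sample, fw, dlogits, ckpt) {
  mode <- ckpt$mode
  grads <- list()
  if (mode == "fused") {
    fb <- fusion_backward(dlogits, fw$ff, ckpt$fusion_config,
                          ckpt$params$fusion)
    grads$fusion <- fb$grads
    grads$gcn <- gcn_backward(fb$dh_c, fw$gf, ckpt$gcn_config,
                              ckpt$params$gcn)
    grads$cnn <- cnn_backward(fb$dh_s, fw$cf$cache, ckpt$cnn_config,
                              ckpt$params$cnn)
  } else {
    grads$head <- list(W = outer(fw$h, dlogits), b = dlogits)
    dh <- as.numeric(ckpt$params$head$W %*% dlogits)
    if (mode == "gcn") {
      grads$gcn <- gcn_backward(dh, fw$gf, ckpt$gcn_config, ckpt$params$gcn)
    } else {
      grads$cnn <- cnn_backward(dh, fw$cf$cache, ckpt$cnn_config,
                                ckpt$params$cnn)
    }
  }
  grads
}

ckpt_accuracy <- function(ckpt, data, idx) {
  if (length(idx) == 0) return(NA_real_)
  pred <- predict_samples(ckpt, data, idx)$pred
  mean(pred == vapply(data$samples[idx], `[[`, integer(1), "label"))
}

#' Train a model on a prepared dataset or manifest
#'
#' Trains one branch (`mode = "gcn"` or `"cnn"`: encoder plus a linear
#' softmax head) or the fused model (`mode = "fused"`: both encoders plus
#' the gated Kronecker fusion head, typically warm-started from the
#' branch checkpoints via `init_from`). All randomness (split, weight
#' init, batch order) is controlled by `config$seed`. The training log
#' records the full-training-set loss before the first update (epoch 0)
#' and per-epoch mean minibatch loss and validation accuracy; a
#' non-finite loss aborts with a diagnostic.
#'
#' @param data a `pg_dataset` from [prepare_dataset()], a manifest
#'   data.frame, or a manifest CSV path.
#' @param config a [train_config()].
#' @param gcn_cfg,cnn_cfg,fusion_cfg component configurations
#'   (defaults match the component constructors; seeds are derived from
#'   `config$seed`).
#' @param init_from for `mode = "fused"`: list with elements `gcn` and
#'   `cnn`, the pretrained branch checkpoints to warm-start from.
#' @param log_path optional CSV path for the training log.
#' @return a checkpoint: list with `params`, the component configs, the
#'   feature/image normalization statistics, `classes`, `split_idx` and
#'   the training `log` (data.frame epoch, loss, val_acc).
#' @export
train_model <- function(data, config = train_config(),
                        gcn_cfg = NULL, cnn_cfg = NULL,
                        fusion_cfg = NULL, init_from = NULL,
                        log_path = NULL) {
  if (is.character(data)) data <- read_manifest(data)
  if (is.data.frame(data)) data <- prepare_dataset(data)
  stopifnot(inherits(data, "pg_dataset"))
  if (length(data$classes) < 2) stop("train_model: need >= 2 classes")
  mode <- config$mode
  n_classes <- length(data$classes)
  labels <- vapply(data$samples, `[[`, integer(1), "label")
  split_idx <- split_dataset(labels, config$split, config$seed)

  # normalization statistics from the training split only
  feat_tr <- do.call(rbind, lapply(data$samples[split_idx$train],
                                   `[[`, "features_raw"))
  feature_norm <- feature_norm_fit(feat_tr)
  imgs_tr <- lapply(data$samples[split_idx$train], `[[`, "image")
  input_norm <- list(
    mean = sapply(1:3, function(ch)
      mean(vapply(imgs_tr, function(im) mean(im[, , ch] / 255), numeric(1)))),
    sd = sapply(1:3, function(ch) {
      s <- sd(unlist(lapply(imgs_tr[seq_len(min(32, length(imgs_tr)))],
                            function(im) as.numeric(im[, , ch] / 255))))
      if (!is.finite(s) || s < 1e-6) 1 else s
    }))
  for (i in seq_along(data$samples)) {
    data$samples[[i]]$features <-
      feature_norm_apply(data$samples[[i]]$features_raw, feature_norm)
  }
  precompute_inputs <- function() {
    for (i in seq_along(data$samples)) {
      data$samples[[i]]$x <<- prep_cnn_input(data$samples[[i]]$image,
                                             input_norm)
    }
  }

  feat_dim <- ncol(feat_tr)
  gcfg <- gcn_cfg %||% gcn_config_default(feat_dim, config$seed)
  ccfg <- cnn_cfg %||% cnn_config(input_size = data$input_size,
                                  seed = config$seed + 1L)
  fcfg <- fusion_cfg %||% fusion_config(n_classes = n_classes,
                                        seed = config$seed + 2L)
  if (gcfg$layer_widths[1] != feat_dim)
    stop("gcn layer_widths[1] must equal the feature width ", feat_dim)
  stopifnot(ccfg$input_size == data$input_size)

  params <- list()
  lr_groups <- list()
  if (mode %in% c("gcn", "fused")) {
    params$gcn <- if (!is.null(init_from$gcn)) init_from$gcn$params$gcn
      else gcn_init(gcfg)
    lr_groups$gcn <- if (mode == "fused" && !is.null(init_from$gcn))
      config$lr_finetune else config$lr
  }
  if (mode %in% c("cnn", "fused")) {
    params$cnn <- if (!is.null(init_from$cnn)) init_from$cnn$params$cnn
      else cnn_init(ccfg)
    lr_groups$cnn <- if (mode == "fused" && !is.null(init_from$cnn))
      config$lr_finetune else config$lr
    if (!is.null(init_from$cnn)) input_norm <- init_from$cnn$input_norm
  }
  if (mode == "fused") {
    params$fusion <- fusion_init(fcfg, gcfg$embed_dim, ccfg$out_dim)
    lr_groups$fusion <- config$lr
  } else {
    set.seed(config$seed + 3L)
    in_dim <- if (mode == "gcn") gcfg$embed_dim else ccfg$out_dim
    params$head <- list(W = glorot_uniform(in_dim, n_classes),
                        b = numeric(n_classes))
    lr_groups$head <- config$lr
  }

  if (mode %in% c("cnn", "fused")) precompute_inputs()

  ckpt <- structure(list(mode = mode, params = params,
                         gcn_config = gcfg, cnn_config = ccfg,
                         fusion_config = fcfg,
                         feature_norm = feature_norm,
                         input_norm = input_norm,
                         classes = data$classes, split_idx = split_idx,
                         train_config = config),
                    class = "pg_checkpoint")

  flat <- flatten_params(params)
  lr_vec <- setNames(
    unlist(lapply(names(params), function(bn)
      rep(lr_groups[[bn]], length(params[[bn]])))),
    names(flat))
  state <- adam_init(flat)

  tr <- split_idx$train
  ytr <- labels[tr]
  batch_loss <- function(idx) {
    probs <- t(vapply(idx, function(i)
      model_forward(data$samples[[i]], ckpt)$probabilities,
      numeric(n_classes)))
    cross_entropy(probs, labels[idx])
  }
  log <- data.frame(epoch = 0L, loss = batch_loss(tr),
                    val_acc = ckpt_accuracy(ckpt, data, split_idx$val))

  set.seed(config$seed + 10L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr)
    ep_losses <- c()
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      B <- length(bidx)
      acc <- NULL
      losses <- numeric(B)
      for (bi in seq_len(B)) {
        i <- bidx[bi]
        fw <- model_forward(data$samples[[i]], ckpt, train = TRUE)
        y <- labels[i]
        losses[bi] <- -log(max(fw$probabilities[y], 1e-12))
        dlogits <- fw$probabilities
        dlogits[y] <- dlogits[y] - 1
        g <- model_backward(data$samples[[i]], fw, dlogits / B, ckpt)
        acc <- add_grads(acc, flatten_params(g))
      }
      loss <- mean(losses)
      if (!is.finite(loss)) {
        stop(sprintf("NaN/Inf loss at epoch %d (batch starting %d); %s",
                     epoch, b0,
                     "check feature scaling and learning rate"))
      }
      upd <- adam_step(flat, acc, state, lr_vec)
      flat <- upd$params
      state <- upd$state
      ckpt$params <- unflatten_params(flat)
      ep_losses <- c(ep_losses, loss)
    }
    log <- rbind(log, data.frame(
      epoch = epoch, loss = mean(ep_losses),
      val_acc = ckpt_accuracy(ckpt, data, split_idx$val)))
  }
  ckpt$log <- log
  if (!is.null(log_path)) write.csv(log, log_path, row.names = FALSE)
  ckpt
}

# default GCN config sized to the feature width
gcn_config_default <- function(feat_dim, seed) {
  gcn_config(layer_widths = c(feat_dim, 32L, 32L), seed = seed)
}

#' Predict class probabilities for dataset samples
#'
#' @param ckpt a `pg_checkpoint`.
#' @param data a `pg_dataset` (features are normalized with the
#'   checkpoint's statistics).
#' @param idx sample indices (default all).
#' @return list with `probs` (n x C matrix) and `pred` (integer labels).
#' @export
predict_samples <- function(ckpt, data, idx = seq_along(data$samples)) {
  n_classes <- length(ckpt$classes)
  probs <- matrix(0, length(idx), n_classes)
  for (k in seq_along(idx)) {
    s <- data$samples[[idx[k]]]
    if (is.null(s[["features"]]) && !is.null(s$features_raw)) {
      s$features <- feature_norm_apply(s$features_raw, ckpt$feature_norm)
    }
    probs[k, ] <- model_forward(s, ckpt)$probabilities
  }
  list(probs = probs, pred = max.col(probs, ties.method = "first"))
}

#' Evaluate a checkpoint on a dataset split
#'
#' @param ckpt a `pg_checkpoint`.
#' @param data a `pg_dataset`.
#' @param split `"test"`, `"val"`, `"train"` (uses the checkpoint's
#'   stored split indices) or an integer index vector.
#' @param predictions_path optional CSV path
#'   (`tile,true,pred,prob_1..prob_C`).
#' @return list with `metrics` (a `metrics_report`) and `predictions`
#'   (data.frame).
#' @export
evaluate_model <- function(ckpt, data, split = "test",
                           predictions_path = NULL) {
  idx <- if (is.character(split)) ckpt$split_idx[[split]] else split
  if (length(idx) == 0) stop("evaluate_model: empty split")
  y <- vapply(data$samples[idx], `[[`, integer(1), "label")
  pr <- predict_samples(ckpt, data, idx)
  metrics <- compute_metrics(y, pr$pred, length(ckpt$classes))
  tile_ids <- if (is.null(data$ids)) as.character(idx) else data$ids[idx]
  preds <- data.frame(tile = tile_ids,
                      true = ckpt$classes[y],
                      pred = ckpt$classes[pr$pred])
  colnames(pr$probs) <- paste0("prob_", ckpt$classes)
  preds <- cbind(preds, pr$probs)
  if (!is.null(predictions_path))
    write.csv(preds, predictions_path, row.names = FALSE)
  list(metrics = metrics, predictions = preds)
}

#' Two-stage training pipeline
#'
#' Trains the GCN branch and the CNN branch separately at `config$lr`,
#' then fine-tunes the fused model warm-started from both (branch
#' weights at `config$lr_finetune`, fusion head at `config$lr`).
#'
#' @param data a `pg_dataset` (or manifest).
#' @param config a [train_config()]; `mode` is overridden per stage.
#' @param ... passed through to [train_model()].
#' @return list of checkpoints `gcn`, `cnn`, `fused`.
#' @export
train_two_stage <- function(data, config = train_config(), ...) {
  cfg_g <- config; cfg_g$mode <- "gcn"
  cfg_c <- config; cfg_c$mode <- "cnn"
  cfg_f <- config; cfg_f$mode <- "fused"
  ck_g <- train_model(data, cfg_g, ...)
  ck_c <- train_model(data, cfg_c, ...)
  ck_f <- train_model(data, cfg_f, init_from = list(gcn = ck_g, cnn = ck_c),
                      ...)
  list(gcn = ck_g, cnn = ck_c, fused = ck_f)
}

#' Save / load a checkpoint
#'
#' Single-file RDS containing all parameters, configurations and
#' normalization statistics.
#'
#' @param ckpt a `pg_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "pg_checkpoint"))
  ckpt
}
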