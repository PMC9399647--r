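test_that("one-vs-rest metrics follow their defining formulas", {
  # class 1: TP=3, FP=1, FN=2 by construction
  y_true <- c(1, 1, 1, 1, 1, 2, 2, 2)
  y_pred <- c(1, 1, 1, 2, 2, 1, 2, 2)
  mr <- compute_metrics(y_true, y_pred, 2)
  expect_identical(mr$per_class$TP[1], 3L)
  expect_identical(mr$per_class$FP[1], 1L)
  expect_identical(mr$per_class$FN[1], 2L)
  expect_equal(mr$per_class$P[1], 75)
  expect_equal(mr$per_class$R[1], 60)
  expect_equal(mr$per_class$F1S[1], 100 * 2 * 3 / (2 * 3 + 1 + 2),
               tolerance = 1e-12)

  perfect <- compute_metrics(c(1, 2, 3), c(1, 2, 3), 3)
  expect_true(all(perfect$per_class$P == 100))
  expect_true(all(perfect$per_class$F1S == 100))
  expect_equal(perfect$accuracy, 100)

  # a class never predicted and never present: degenerate denominators
  m0 <- suppressWarnings(compute_metrics(c(1, 1), c(1, 1), 2))
  expect_equal(m0$per_class$P[2], 0)
  expect_warning(compute_metrics(c(1, 1, 2), c(1, 1, 1), 2), "denominator")
})

test_that("accuracy and F1 identities hold on random label vectors", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    k <- sample(2:5, 1)
    yt <- sample(k, n, replace = TRUE)
    yp <- sample(k, n, replace = TRUE)
    mr <- suppressWarnings(compute_metrics(yt, yp, k))
    expect_equal(mr$accuracy,
                 100 * sum(diag(mr$confusion)) / sum(mr$confusion),
                 tolerance = 1e-12)
    for (cl in seq_len(k)) {
      p <- mr$per_class$P[cl]
      r <- mr$per_class$R[cl]
      if (p + r > 0) {
        expect_equal(mr$per_class$F1S[cl], 2 * p * r / (p + r),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("training starts near the uniform-prediction loss and is reproducible", {
  ds <- small_dataset()
  cfg <- train_config(mode = "gcn", epochs = 2, seed = 5)
  ck1 <- train_model(ds, cfg)
  expect_lt(abs(ck1$log$loss[1] - log(3)) / log(3), 0.2)
  ck2 <- train_model(ds, cfg)
  expect_identical(ck1$log, ck2$log)
  expect_identical(ck1$params, ck2$params)
  # losses must decrease over a longer run
  ck3 <- train_model(ds, train_config(mode = "gcn", epochs = 25, seed = 5))
  expect_lt(tail(ck3$log$loss, 1), ck1$log$loss[1])
})

test_that("the cell-graph branch is isolated from the CNN image stream", {
  ds <- small_dataset()
  ck <- train_model(ds, train_config(mode = "gcn", epochs = 5, seed = 9))
  pr1 <- predict_samples(ck, ds)
  noisy <- ds
  set.seed(99)
  for (i in seq_along(noisy$samples)) {
    noisy$samples[[i]]$image <-
      array(runif(length(noisy$samples[[i]]$image), 0, 255),
            dim(noisy$samples[[i]]$image))
  }
  pr2 <- predict_samples(ck, noisy)
  expect_identical(pr1$probs, pr2$probs)
})

test_that("a small model overfits its training split", {
  ds <- small_dataset()
  ck <- train_model(ds, train_config(mode = "cnn", epochs = 15, seed = 3))
  ev <- evaluate_model(ck, ds, split = "train")
  expect_gte(ev$metrics$accuracy, 95)
  expect_identical(nrow(ev$metrics$per_class), 3L)
  expect_identical(nrow(ev$predictions), length(ck$split_idx$train))
  expect_named(ev$predictions,
               c("tile", "true", "pred", paste0("prob_", ds$classes)))
})

test_that("checkpoints roundtrip through disk and logs are written", {
  ds <- small_dataset()
  lf <- withr::local_tempfile(fileext = ".csv")
  ck <- train_model(ds, train_config(mode = "gcn", epochs = 2, seed = 2),
                    log_path = lf)
  expect_true(file.exists(lf))
  expect_equal(nrow(read.csv(lf)), 3)  # epoch 0 + 2 epochs
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  expect_identical(ck2$params, ck$params)
  expect_identical(predict_samples(ck2, ds, 1:4)$probs,
                   predict_samples(ck, ds, 1:4)$probs)
})

test_that("degenerate inputs are rejected with diagnostics", {
  one_class <- small_tiles()[1:4]
  expect_error(prepare_dataset(one_class), "2 classes")
  ds <- small_dataset()
  expect_error(train_model(ds, train_config(mode = "gcn", epochs = 1),
                           gcn_cfg = gcn_config(layer_widths = c(7, 8))),
               "feature width")
})

test_that("fused training warm-starts from branch checkpoints", {
  ds <- small_dataset()
  cfg <- train_config(epochs = 4, seed = 13)
  cks <- train_two_stage(ds, cfg)
  expect_setequal(names(cks), c("gcn", "cnn", "fused"))
  # frozen-ish branches: fine-tuned weights stay near their warm start
  expect_lt(max(abs(cks$fused$params$gcn$W1 - cks$gcn$params$gcn$W1)),
            50 * cfg$lr_finetune * 4 * 3)
  # the fused head actually trained
  expect_gt(max(abs(cks$fused$params$fusion$Wcls)), 0)
  ev <- suppressWarnings(evaluate_model(cks$fused, ds, split = "val"))
  expect_identical(nrow(ev$predictions), length(cks$fused$split_idx$val))
})
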