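test_that("shape features match closed forms for disks and ellipses", {
  f <- shape_features(disk_mask(20))
  expect_gte(f[["roundness"]], 0.95)
  expect_gte(f[["solidity"]], 0.98)
  expect_lte(f[["eccentricity"]], 0.1)
  expect_lt(abs(f[["area"]] - pi * 400) / (pi * 400), 0.02)

  fe <- shape_features(ellipse_mask(10, 5, 0))
  expect_lt(abs(fe[["major_axis_length"]] / fe[["minor_axis_length"]] - 2) / 2,
            0.05)
  expect_lt(abs(fe[["eccentricity"]] - sqrt(1 - 25 / 100)), 0.05)
  expect_true(fe[["minor_axis_length"]] <= fe[["major_axis_length"]])

  f1 <- shape_features(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(f1[["area"]], 1)
  expect_equal(f1[["solidity"]], 1)
})

test_that("rotating a mask by 90 degrees preserves rotation-invariant features", {
  set.seed(51)
  for (i in 1:5) {
    a <- runif(1, 7, 15)
    m <- ellipse_mask(a, runif(1, 5, a), runif(1, -1.2, 1.2))
    r <- t(m)[, nrow(m):1]  # 90-degree rotation
    f0 <- shape_features(m)
    f9 <- shape_features(r)
    for (k in c("area", "solidity", "eccentricity", "roundness")) {
      expect_lt(abs(f9[[k]] - f0[[k]]) / max(f0[[k]], 1e-9), 0.02)
    }
    dth <- (f9[["orientation"]] - f0[["orientation"]]) %% pi
    expect_lt(min(abs(dth - pi / 2), abs(dth - pi / 2 - pi),
                  abs(dth + pi / 2)), 0.1)
    expect_lte(f0[["solidity"]], 1)
  }
})

test_that("GLCM features satisfy their defining identities", {
  img <- matrix(100, 10, 10)
  msk <- matrix(1L, 10, 10)
  tf <- texture_features(img, msk)
  expect_equal(unname(tf), c(0, 1, 1, 1))

  # energy^2 == ASM on arbitrary patches
  set.seed(52)
  for (i in 1:5) {
    patch <- matrix(round(runif(64, 0, 255)), 8, 8)
    tf <- texture_features(patch, matrix(1L, 8, 8))
    expect_equal(tf[["energy"]]^2, tf[["asm"]], tolerance = 1e-12)
    # per-patch quantization makes features shift-invariant
    tf2 <- texture_features(patch + 37, matrix(1L, 8, 8))
    expect_equal(tf, tf2, tolerance = 1e-12)
  }

  # 2x2 checkerboard of extreme levels: all horizontal co-occurrence
  # mass is off-diagonal at |i-j| = 31
  q <- matrix(c(0L, 31L, 31L, 0L), 2, 2)
  g0 <- pathograph:::glcm_features(q, c(0L, 1L), 32L)
  expect_equal(g0[[1]], 31)
  expect_equal(g0[[3]], 0.5)
})

test_that("the default patch descriptor is deterministic and border-safe", {
  img <- array(128, c(100, 100, 3))
  pd <- patch_descriptor(img, c(50, 50))
  expect_length(pd, 12)
  expect_equal(unname(pd[4:6]), c(0, 0, 0))  # constant input, zero sd
  expect_true(all(is.finite(patch_descriptor(img, c(1, 1)))))
  # identical content at different centroids gives identical descriptors
  set.seed(53)
  tile <- array(runif(200 * 200 * 3, 0, 255), c(200, 200, 3))
  tile[81:144, 21:84, ] <- tile[81:144, 121:184, ]
  expect_equal(patch_descriptor(tile, c(113, 53)),
               patch_descriptor(tile, c(113, 153)))
})

test_that("featurize_tile yields one ordered row per instance", {
  tl <- generate_tile(tile_spec(class_label = "scattered", n_nuclei = 12,
                                seed = 61))
  ft <- featurize_tile(tl$image, tl$instance_mask)
  expect_identical(dim(ft$features), c(12L, 24L))
  # row k corresponds to label k: centroids match the mask
  for (k in c(1, 7, 12)) {
    expect_equal(ft$centroids[k, ],
                 colMeans(which(tl$instance_mask == k, arr.ind = TRUE)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # zero instances: empty matrix with the full column set
  ft0 <- featurize_tile(tl$image, matrix(0L, 64, 64))
  expect_identical(dim(ft0$features), c(0L, 24L))
})

test_that("z-score normalization inverts exactly and persists", {
  set.seed(54)
  X <- matrix(rnorm(200, 5, 3), 20, 10)
  colnames(X) <- paste0("f", 1:10)
  norm <- feature_norm_fit(X)
  Z <- feature_norm_apply(X, norm)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(feature_norm_invert(Z, norm), X, tolerance = 1e-9)
  f <- withr::local_tempfile(fileext = ".json")
  feature_norm_save(norm, f)
  n2 <- feature_norm_load(f)
  expect_equal(n2$center, norm$center, tolerance = 1e-12)
  expect_equal(n2$scale, norm$scale, tolerance = 1e-12)
})
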