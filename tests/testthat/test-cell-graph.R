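test_that("hand-enumerable point sets produce the expected edges", {
  cent <- rbind(c(0, 0), c(1, 0), c(3, 0))
  g <- build_graph(cent, K = 1, d = 10)
  expect_identical(edge_set_key(g$directed_edges),
                   edge_set_key(rbind(c(1, 2), c(2, 1), c(3, 2))))
  expect_equal(g$A, rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))

  # tightening d to 1.5 drops the distance-2 edge (strict inequality)
  g2 <- build_graph(cent, K = 1, d = 1.5)
  expect_identical(edge_set_key(g2$directed_edges),
                   edge_set_key(rbind(c(1, 2), c(2, 1))))
  expect_equal(g2$A[2, 3], 0)

  # single node: edgeless, A_norm = 1 (self-loop only)
  g1 <- build_graph(matrix(c(5, 5), 1, 2))
  expect_equal(g1$A, matrix(0, 1, 1))
  expect_equal(g1$A_norm, matrix(1, 1, 1))
})

test_that("build_graph matches the brute-force oracle on random point sets", {
  set.seed(71)
  for (rep in 1:50) {
    m <- sample(2:50, 1)
    cent <- matrix(runif(2 * m, 0, 200), m, 2)
    K <- sample(1:8, 1)
    d <- runif(1, 10, 150)
    g <- build_graph(cent, K = K, d = d)
    expect_identical(edge_set_key(g$directed_edges),
                     edge_set_key(brute_force_edges(cent, K, d)))
    expect_true(all(g$A == t(g$A)))
    expect_true(all(diag(g$A) == 0))
    # out-degree of the directed KNN graph is capped at K; the
    # symmetrized degree also counts incoming choices by other nodes
    out_deg <- tabulate(g$directed_edges[, 1], nbins = m)
    expect_true(all(out_deg <= K))
    deg <- rowSums(g$A)
    expect_equal(diag(g$A_norm), 1 / (deg + 1), tolerance = 1e-12)
  }
})

test_that("edges grow monotonically with K and d", {
  set.seed(72)
  cent <- matrix(runif(60, 0, 100), 30, 2)
  und <- function(g) {
    e <- which(g$A == 1, arr.ind = TRUE)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  for (K in c(1, 3)) {
    for (d in c(20, 40)) {
      base <- und(build_graph(cent, K = K, d = d))
      expect_true(all(base %in% und(build_graph(cent, K = K + 2, d = d))))
      expect_true(all(base %in% und(build_graph(cent, K = K, d = d * 2))))
    }
  }
})

test_that("normalization follows the self-looped symmetric form", {
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2)),
               matrix(0.5, 2, 2))
  expect_equal(normalize_adjacency(matrix(0, 4, 4)), diag(4))
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(normalize_adjacency(K3), matrix(1 / 3, 3, 3))
  # leading eigenvalue is 1 for any graph
  set.seed(73)
  for (rep in 1:20) {
    m <- sample(2:25, 1)
    A <- matrix(rbinom(m * m, 1, 0.25), m, m)
    A <- 1 * ((A + t(A)) > 0)
    diag(A) <- 0
    ev <- eigen(normalize_adjacency(A), symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(max(ev), 1, tolerance = 1e-10)
  }
})

test_that("graphs roundtrip through JSON and export to MatrixMarket", {
  set.seed(74)
  g <- build_graph(matrix(runif(24, 0, 100), 12, 2),
                   node_features = matrix(rnorm(36), 12, 3), K = 3, d = 45)
  f <- withr::local_tempfile(fileext = ".json")
  write_cell_graph(g, f)
  g2 <- read_cell_graph(f)
  expect_equal(g2$centroids, g$centroids, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(g2$A, g$A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g2$A_norm, g$A_norm, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g2$node_features, g$node_features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(g2$K, g$K)

  # asymmetric adjacency is rejected on load
  bad <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad$A[1, 2] <- 1 - bad$A[2, 1]
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  expect_error(read_cell_graph(f2), "symmetric")

  # empty graph file loads as a valid empty cell graph
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(centroids = list(), K = 5L, d = 50),
                       f3, auto_unbox = TRUE)
  g0 <- read_cell_graph(f3)
  expect_s3_class(g0, "cell_graph")
  expect_identical(nrow(g0$centroids), 0L)

  fm <- withr::local_tempfile(fileext = ".mtx")
  write_adjacency_mtx(g, fm)
  M <- as.matrix(Matrix::readMM(fm))
  expect_equal(1 * M, g$A, ignore_attr = TRUE)
})
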