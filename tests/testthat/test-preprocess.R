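test_that("highly variable gene selection ranks by variance", {
  # 4 spots x 3 genes with raw per-gene variances 0.1, 4.0, 2.0
  counts <- cbind(g1 = c(1.0, 1.1, 1.2, 1.5),
                  g2 = c(0, 4, 2, 1),
                  g3 = c(0, 1, 3, 2))
  rownames(counts) <- paste0("s", 1:4)
  expect_equal(round(apply(counts, 2, var), 3),
               c(g1 = 0.047, g2 = 2.917, g3 = 1.667))
  kept <- select_hvg(counts, n_top = 2, normalize = FALSE)
  expect_identical(colnames(kept), c("g2", "g3"))
  # n_top beyond the gene count keeps everything
  expect_identical(ncol(select_hvg(counts, n_top = 5, normalize = FALSE)), 3L)
  # default size of the highly variable set
  expect_identical(formals(select_hvg)$n_top, 2000)
  expect_error(select_hvg(matrix(numeric(0), 0, 0)), class = "spotacc_invalid_input")
})

test_that("PCA embedding matches a brute-force eigendecomposition", {
  set.seed(42)
  X <- matrix(rexp(4 * 3), 4, 3)
  emb <- pca_embed(X, n_components = 2, normalize = FALSE, scale = FALSE)
  expect_identical(dim(emb), c(4L, 2L))
  # oracle: eigendecomposition of the covariance matrix
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  scores <- Xc %*% ev$vectors[, 1:2]
  # components defined up to sign
  for (k in 1:2) {
    expect_equal(abs(emb[, k]), abs(scores[, k]), tolerance = 1e-10)
  }
  # explained variance ordering
  sdev <- attr(emb, "sdev")
  expect_true(all(diff(sdev) <= 1e-12))
})

test_that("rank-1 data is fully explained by one component", {
  t_par <- 1:6
  X <- cbind(2 * t_par, -1 * t_par) + 10
  emb <- pca_embed(X, n_components = 1, normalize = FALSE, scale = FALSE)
  sdev <- attr(emb, "sdev")
  expect_equal(sdev[1]^2 / sum(sdev^2), 1, tolerance = 1e-10)
  expect_error(pca_embed(X, n_components = 3, normalize = FALSE),
               class = "spotacc_invalid_input")
})

test_that("default neighborhood size is the closest odd integer to sqrt(N)", {
  expect_identical(default_neighbors(9), 3L)
  expect_identical(default_neighbors(2696), 51L)   # sqrt = 51.92
  expect_identical(default_neighbors(2500), 49L)   # tie at sqrt = 50 -> down
  expect_identical(default_neighbors(100), 9L)     # tie at sqrt = 10 -> down
  expect_error(default_neighbors(1), class = "spotacc_invalid_input")
  # property: odd, positive, and closest among odd integers
  Ns <- c(2:50, 1234, 99999, 10^6)
  for (N in Ns) {
    R <- default_neighbors(N)
    expect_identical(R %% 2L, 1L)
    odd <- seq(1L, as.integer(2 * ceiling(sqrt(N))) + 3L, by = 2L)
    expect_equal(abs(R - sqrt(N)), min(abs(odd - sqrt(N))), tolerance = 1e-12)
  }
  # monotone non-decreasing in N
  Rs <- vapply(2:2000, default_neighbors, integer(1))
  expect_true(all(diff(Rs) >= 0))
})

test_that("knn graph connects nearest neighbors with union symmetrization", {
  A <- knn_graph(matrix(c(0, 1, 3, 7), 4, 1), R = 1)
  expected <- matrix(0L, 4, 4)
  expected[1, 2] <- expected[2, 1] <- 1L
  expected[2, 3] <- expected[3, 2] <- 1L
  expected[3, 4] <- expected[4, 3] <- 1L
  expect_identical(unname(A), expected)
  expect_identical(rowSums(A), c(1, 2, 2, 1))
  expect_error(knn_graph(matrix(0, 3, 1), R = 3), class = "spotacc_invalid_input")
})

test_that("knn distance ties resolve to the lowest index and stay symmetric", {
  # exactly equidistant configuration: node 2 ties between nodes 1 and 3
  pts <- matrix(c(0, 1, 2), 3, 1)
  A <- knn_graph(pts, R = 1)
  # node 2's tie resolves to node 1; union symmetrization keeps {2,3}
  # because node 3's nearest neighbor is node 2
  expect_identical(A, t(A))
  expect_identical(A[1, 2], 1L)
  expect_identical(A[2, 3], 1L)
  expect_identical(A[1, 3], 0L)
  # with duplicate points the tie rule still applies
  dup <- matrix(c(0, 0, 5), 3, 1)
  Ad <- knn_graph(dup, R = 1)
  expect_identical(Ad[1, 2], 1L)
  expect_identical(Ad[3, 1], 1L)  # node 3 ties toward the lowest index
})

test_that("knn graphs are symmetric binary and rigid-motion invariant", {
  set.seed(7)
  for (rep in 1:5) {
    pts <- matrix(rnorm(30 * 2), 30, 2)
    A <- knn_graph(pts, R = 4)
    expect_true(all(A %in% c(0L, 1L)))
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_true(all(rowSums(A) >= 4))
    ang <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    shifted <- pts %*% rot + matrix(rnorm(2), 30, 2, byrow = TRUE)
    expect_identical(knn_graph(shifted, R = 4), A)
  }
})

test_that("build_multilayer composes the pipeline deterministically", {
  set.seed(11)
  n <- 100
  counts <- matrix(rpois(n * 40, 5), n, 40,
                   dimnames = list(paste0("s", 1:n), paste0("g", 1:40)))
  coords <- cbind(x = runif(n), y = runif(n))
  rownames(coords) <- paste0("s", 1:n)
  g <- build_multilayer(counts, coords, n_pcs = 10)
  expect_s3_class(g, "multilayer_graph")
  expect_identical(g$N, 100L)
  expect_identical(g$L, 2L)
  # R defaults to the sqrt heuristic: sqrt(100) = 10, tie -> 9
  for (l in 1:2) {
    A <- as_adjacency(g, l)
    expect_identical(A, t(A))
    expect_true(all(rowSums(A) >= 9))
  }
  # determinism: same inputs give bit-identical graphs
  g2 <- build_multilayer(counts, coords, n_pcs = 10)
  expect_identical(g$edges, g2$edges)
  # spatial layer equals direct knn on the coordinates at the same R
  expect_identical(as_adjacency(g, "spatial"), knn_graph(coords, 9))
  # misaligned spot ids are reported
  bad <- coords
  rownames(bad)[1:2] <- c("zz1", "zz2")
  expect_error(build_multilayer(counts, bad, n_pcs = 10),
               regexp = "zz1", class = "spotacc_invalid_input")
})

test_that("multilayer_graph validates its layers", {
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- 1L
  expect_silent(multilayer_graph(list(A, A)))
  bad_diag <- A
  diag(bad_diag) <- 1L
  expect_error(multilayer_graph(list(bad_diag)), class = "spotacc_invalid_input")
  bad_sym <- A
  bad_sym[1, 3] <- 1L
  expect_error(multilayer_graph(list(bad_sym)), class = "spotacc_invalid_input")
  expect_error(multilayer_graph(list(A * 2L)), class = "spotacc_invalid_input")
})
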