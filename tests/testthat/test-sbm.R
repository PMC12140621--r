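# fixture: N=4, L=2, z=(1,1,2,2); layer 1 edges {1,2},{3,4},{1,3};
# layer 2 edges {1,2},{3,4}. Hand-enumerated pair counts:
# E[1,1]=2 (P=2), E[1,2]=1 (P=8), E[2,2]=2 (P=2).
toy_graph <- function() {
  A1 <- matrix(0L, 4, 4)
  A1[1, 2] <- A1[2, 1] <- 1L
  A1[3, 4] <- A1[4, 3] <- 1L
  A1[1, 3] <- A1[3, 1] <- 1L
  A2 <- matrix(0L, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 1L
  A2[3, 4] <- A2[4, 3] <- 1L
  multilayer_graph(list(A1, A2))
}

test_that("pair counts match hand enumeration on the two-layer toy", {
  cnt <- pair_counts(toy_graph(), c(1, 1, 2, 2), K = 2)
  expect_equal(cnt$edges, matrix(c(2, 1, 1, 2), 2, 2))
  expect_equal(cnt$possible, matrix(c(2, 8, 8, 2), 2, 2))
  expect_error(pair_counts(toy_graph(), c(1, 1, 2, 3), K = 2),
               class = "spotacc_invalid_input")
})

test_that("pair counts handle empty and saturated graphs", {
  empty <- multilayer_graph(list(matrix(0L, 4, 4), matrix(0L, 4, 4)))
  cnt <- pair_counts(empty, c(1, 1, 2, 2), K = 2)
  expect_true(all(cnt$edges == 0))
  expect_equal(cnt$possible, matrix(c(2, 8, 8, 2), 2, 2))
  full <- 1L - diag(1L, 4)
  cnt2 <- pair_counts(multilayer_graph(list(full, full)), c(1, 1, 2, 2), K = 2)
  expect_equal(cnt2$edges, cnt2$possible)
})

test_that("community weight draws follow the conjugate Dirichlet", {
  pr <- sbm_priors(2)
  set.seed(1)
  draws <- t(replicate(1e5, update_pi(c(1, 1, 2), pr)))
  expect_equal(rowSums(draws), rep(1, 1e5), tolerance = 1e-9)
  # Dirichlet(3, 2): mean (0.6, 0.4), var p(1-p)/(a0+1)
  se <- sqrt(0.6 * 0.4 / 6 / 1e5)
  expect_lt(abs(mean(draws[, 1]) - 0.6), 3 * se)
  # K = 1 degenerates to the point mass at 1
  expect_identical(update_pi(rep(1, 5), sbm_priors(1)), 1)
})

test_that("connectivity draws follow the conjugate Beta", {
  pr <- sbm_priors(2)
  cnt <- pair_counts(toy_graph(), c(1, 1, 2, 2), K = 2)
  set.seed(2)
  draws <- replicate(1e4, update_theta(cnt, pr))
  # entry (1,1): edges=2, possible=2 -> Beta(3,1), mean 0.75
  se11 <- sqrt(3 * 1 / (4^2 * 5) / 1e4)
  expect_lt(abs(mean(draws[1, 1, ]) - 0.75), 3 * se11)
  # entry (1,2): edges=1, possible=8 -> Beta(2,8), mean 0.2
  se12 <- sqrt(2 * 8 / (10^2 * 11) / 1e4)
  expect_lt(abs(mean(draws[1, 2, ]) - 0.2), 3 * se12)
  # symmetry and range of every draw
  expect_equal(draws[1, 2, ], draws[2, 1, ])
  expect_true(all(draws >= 0 & draws <= 1))
  # empty community pair falls back to the Beta(1,1) prior
  cnt0 <- pair_counts(toy_graph(), c(1, 1, 1, 1), K = 2)
  set.seed(3)
  d0 <- replicate(2e4, update_theta(cnt0, pr)[2, 2])
  expect_lt(abs(mean(d0) - 0.5), 3 * sqrt(1 / 12 / 2e4))
  # inconsistent counts are rejected
  cnt_bad <- cnt
  cnt_bad$edges[1, 1] <- 99
  expect_error(update_theta(cnt_bad, pr), class = "spotacc_invalid_input")
})

test_that("label sweep matches the exact full conditional", {
  # 3 nodes, K=2, z_{-1}=(.,1,2), edges A12=1, A13=0 in both layers
  A1 <- matrix(0L, 3, 3)
  A1[1, 2] <- A1[2, 1] <- 1L
  g <- multilayer_graph(list(A1, A1))
  theta <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  pi <- c(0.5, 0.5)
  z0 <- c(2L, 1L, 2L)
  p_exact <- naive_z_conditional(g, z0, 1, pi, theta)
  # rho ∝ (0.5*(0.9*0.9)^2, 0.5*(0.1*0.1)^2): P(z1 = 1) ≈ 0.99985
  expect_equal(p_exact[1], 0.6561 / (0.6561 + 1e-4), tolerance = 1e-10)
  set.seed(4)
  hits <- replicate(1e5, update_z(g, z0, pi, theta)[1] == 1L)
  se <- sqrt(p_exact[1] * (1 - p_exact[1]) / 1e5)
  expect_lt(abs(mean(hits) - p_exact[1]), 3 * se)
})

test_that("label sweep is uniform when theta carries no information", {
  g <- toy_graph()
  theta <- matrix(0.4, 3, 3)  # all rows identical
  pi <- rep(1 / 3, 3)
  set.seed(5)
  draws <- replicate(3e4, update_z(g, c(1L, 2L, 3L, 1L), pi, theta)[2])
  freq <- tabulate(draws, 3) / 3e4
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt(1 / 3 * 2 / 3 / 3e4)))
})

test_that("single-site transition frequencies match the closed form", {
  set.seed(6)
  g <- random_graph(6, L = 2, p = 0.4)
  theta <- matrix(c(0.5, 0.2, 0.2, 0.6), 2, 2)
  pi <- c(0.3, 0.7)
  z0 <- c(1L, 2L, 1L, 2L, 1L, 2L)
  p_exact <- naive_z_conditional(g, z0, 1, pi, theta)
  hits <- replicate(2e4, update_z(g, z0, pi, theta)[1] == 1L)
  se <- sqrt(max(p_exact[1] * (1 - p_exact[1]), 1e-6) / 2e4)
  expect_lt(abs(mean(hits) - p_exact[1]), 3 * se)
})

test_that("canonical relabeling orders first occurrences and is idempotent", {
  pi <- c(0.2, 0.5, 0.3)
  theta <- matrix(c(0.5, 0.1, 0.2,
                    0.1, 0.6, 0.3,
                    0.2, 0.3, 0.7), 3, 3)
  out <- canonical_relabel(c(2L, 2L, 1L, 3L), pi, theta)
  expect_identical(out$z, c(1L, 1L, 2L, 3L))
  expect_equal(out$pi, c(0.5, 0.2, 0.3))
  expect_equal(out$theta[1, 1], 0.6)
  expect_equal(out$theta[2, 2], 0.5)
  expect_equal(out$theta[1, 2], 0.1)
  expect_equal(out$theta[1, 3], 0.3)
  # idempotence
  out2 <- canonical_relabel(out$z, out$pi, out$theta)
  expect_identical(out2$z, out$z)
  expect_equal(out2$pi, out$pi)
  expect_equal(out2$theta, out$theta)
  # already-canonical input returned unchanged
  out3 <- canonical_relabel(c(1L, 2L, 1L, 3L), pi, theta)
  expect_identical(out3$z, c(1L, 2L, 1L, 3L))
  expect_equal(out3$theta, theta)
})

test_that("log posterior is invariant under canonical relabeling", {
  set.seed(7)
  pr <- sbm_priors(3, beta1 = 2, beta2 = 3)
  for (rep in 1:5) {
    g <- random_graph(8, L = 2, p = 0.3)
    z <- sample(1:3, 8, replace = TRUE)
    pi <- as.numeric(update_pi(z, pr))
    theta <- update_theta(pair_counts(g, z, 3), pr)
    before <- log_posterior(g, z, pi, theta, pr)
    out <- canonical_relabel(z, pi, theta)
    after <- log_posterior(g, out$z, out$pi, out$theta, pr)
    expect_equal(after, before, tolerance = 1e-12)
  }
})

test_that("log posterior matches the naive double-loop oracle", {
  set.seed(8)
  pr <- sbm_priors(3, alpha = c(1, 2, 0.5), beta1 = 1.5, beta2 = 2)
  for (rep in 1:5) {
    g <- random_graph(10, L = 2, p = 0.35)
    z <- sample(1:3, 10, replace = TRUE)
    pi <- as.numeric(update_pi(z, pr))
    theta <- update_theta(pair_counts(g, z, 3), pr)
    expect_equal(log_posterior(g, z, pi, theta, pr),
                 naive_log_posterior(g, z, pi, theta, pr),
                 tolerance = 1e-10)
  }
  # empty graph at theta = 0.5: likelihood term is -L*N(N-1)/2 * log 2
  empty <- multilayer_graph(list(matrix(0L, 5, 5), matrix(0L, 5, 5)))
  pr1 <- sbm_priors(1)
  lp <- log_posterior(empty, rep(1L, 5), 1, matrix(0.5, 1, 1), pr1)
  expect_equal(lp, -2 * 10 * log(2), tolerance = 1e-12)
})
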