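# Independent oracles used across the suite. These deliberately use naive
# dense double loops / exhaustive enumeration, not the package's own
# vectorized or C++ code paths.

# random small multilayer graph (dense Bernoulli layers)
random_graph <- function(n, L = 2, p = 0.3) {
  layers <- lapply(seq_len(L), function(l) {
    A <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        A[i, j] <- A[j, i] <- rbinom(1, 1, p)
      }
    }
    A
  })
  multilayer_graph(layers)
}

# joint log posterior by naive loops over all pairs, layers, and entries
naive_log_posterior <- function(A, z, pi, theta, priors) {
  n <- A$N
  K <- priors$K
  th <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
  ll <- 0
  for (l in seq_len(A$L)) {
    Ad <- as_adjacency(A, l)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        p <- th[z[i], z[j]]
        ll <- ll + if (Ad[i, j] == 1) log(p) else log(1 - p)
      }
    }
  }
  for (i in seq_len(n)) ll <- ll + log(max(pi[z[i]], 1e-300))
  ll <- ll + lgamma(sum(priors$alpha)) - sum(lgamma(priors$alpha))
  for (k in seq_len(K)) {
    if (priors$alpha[k] != 1)
      ll <- ll + (priors$alpha[k] - 1) * log(max(pi[k], 1e-300))
  }
  for (s in seq_len(K)) {
    for (r in seq_len(s)) {
      ll <- ll + (priors$beta1 - 1) * log(th[r, s]) +
        (priors$beta2 - 1) * log(1 - th[r, s]) -
        lbeta(priors$beta1, priors$beta2)
    }
  }
  ll
}

# exact single-site full conditional rho_i (formula evaluated by scalar
# loops), normalized over k
naive_z_conditional <- function(A, z, i, pi, theta) {
  K <- length(pi)
  th <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
  lp <- numeric(K)
  for (k in seq_len(K)) {
    s <- log(pi[k])
    for (l in seq_len(A$L)) {
      Ad <- as_adjacency(A, l)
      for (j in seq_len(A$N)) {
        if (j == i) next
        p <- th[k, z[j]]
        s <- s + if (Ad[i, j] == 1) log(p) else log(1 - p)
      }
    }
    lp[k] <- s
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

# collapsed posterior over all K^n label vectors by exhaustive enumeration
# with Dirichlet-multinomial and Beta-Bernoulli marginals; returns
# probabilities aggregated over canonical partition representatives
collapsed_posterior <- function(A, K, priors) {
  n <- A$N
  L <- A$L
  Ad <- lapply(seq_len(L), function(l) as_adjacency(A, l))
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  logp <- apply(grid, 1, function(z) {
    nk <- tabulate(z, K)
    lp <- lgamma(sum(priors$alpha)) - lgamma(sum(priors$alpha) + n) +
      sum(lgamma(priors$alpha + nk) - lgamma(priors$alpha))
    for (r in seq_len(K)) {
      for (s in seq(r, K)) {
        E <- 0
        P <- 0
        for (l in seq_len(L)) {
          for (i in seq_len(n - 1)) {
            for (j in seq(i + 1, n)) {
              pair <- sort(c(z[i], z[j]))
              if (pair[1] == r && pair[2] == s) {
                P <- P + 1
                E <- E + Ad[[l]][i, j]
              }
            }
          }
        }
        lp <- lp + lbeta(priors$beta1 + E, priors$beta2 + P - E) -
          lbeta(priors$beta1, priors$beta2)
      }
    }
    lp
  })
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  key <- apply(grid, 1, function(z)
    paste(canonical_relabel(z, pi = rep(1 / K, K))$z, collapse = "."))
  tapply(p, key, sum)
}

# adjusted Rand index via the contingency-table formula, scalar arithmetic
naive_ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(tab * (tab - 1) / 2)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  sa <- sum(ai * (ai - 1) / 2)
  sb <- sum(bj * (bj - 1) / 2)
  n <- length(a)
  tot <- n * (n - 1) / 2
  exp_idx <- sa * sb / tot
  max_idx <- (sa + sb) / 2
  if (max_idx == exp_idx) return(if (nij == max_idx) 1 else 0)
  (nij - exp_idx) / (max_idx - exp_idx)
}

# which true-community pairs end up merged under a fitted partition
# (majority fitted label per true community)
merged_pairs <- function(z_true, z_fit, K_true = max(z_true)) {
  maj <- vapply(seq_len(K_true), function(b) {
    tab <- table(z_fit[z_true == b])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  out <- NULL
  for (r in seq_len(K_true - 1)) {
    for (s in seq(r + 1, K_true)) {
      if (maj[r] == maj[s]) out <- rbind(out, c(r, s))
    }
  }
  out
}
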