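#' Conjugate priors for the multi-layer SBM
#'
#' Dirichlet prior on the community weights and a common Beta prior on every
#' connectivity entry. The defaults (`alpha = 1`, `beta1 = beta2 = 1`) are
#' weakly informative: uniform over the simplex and uniform over `[0, 1]`.
#'
#' @param K number of communities.
#' @param alpha Dirichlet concentration, scalar (recycled) or length-`K`.
#' @param beta1,beta2 Beta shape parameters for the connectivity entries.
#' @return an object of class `sbm_priors`.
#' @export
sbm_priors <- function(K, alpha = 1, beta1 = 1, beta2 = 1) {
  if (length(K) != 1L || is.na(K) || K < 1) stop_invalid("K must be >= 1")
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (length(alpha) != K) stop_invalid("alpha must be scalar or length K")
  if (any(alpha <= 0) || beta1 <= 0 || beta2 <= 0)
    stop_invalid("prior parameters must be strictly positive")
  structure(list(alpha = as.numeric(alpha), beta1 = as.numeric(beta1),
                 beta2 = as.numeric(beta2), K = as.integer(K)),
            class = "sbm_priors")
}

validate_labels <- function(z, N, K) {
  z <- as.integer(z)
  if (length(z) != N) stop_invalid("label vector length does not match graph")
  if (anyNA(z) || any(z < 1L) || any(z > K))
    stop_invalid(sprintf("labels must lie in 1..%d", K))
  z
}

#' Observed and possible edge counts per community pair
#'
#' For labels `z` and an `L`-layer graph, `edges[r, s]` counts the unordered
#' node pairs `{i, j}` with labels `{r, s}` that share an edge, summed over
#' layers (each unordered pair counted once per layer), and
#' `possible[r, s]` is `L * n_r * n_s` off the diagonal and
#' `L * n_r * (n_r - 1) / 2` on it.
#'
#' @param A a [multilayer_graph].
#' @param z integer labels in `1..K`.
#' @param K number of communities.
#' @return list with symmetric `K x K` matrices `edges` and `possible`,
#'   community sizes `n`, and layer count `L`.
#' @export
pair_counts <- function(A, z, K) {
  stopifnot(inherits(A, "multilayer_graph"))
  z <- validate_labels(z, A$N, K)
  Eu <- matrix(0, K, K)
  for (e in A$edges) {
    if (nrow(e) == 0L) next
    r <- z[e[, 1L]]
    s <- z[e[, 2L]]
    lo <- pmin(r, s)
    hi <- pmax(r, s)
    tab <- tabulate((hi - 1L) * K + lo, nbins = K * K)
    Eu <- Eu + matrix(tab, K, K)
  }
  E <- Eu + t(Eu)
  diag(E) <- diag(Eu)
  n <- tabulate(z, K)
  P <- A$L * outer(n, n)
  diag(P) <- A$L * n * (n - 1) / 2
  list(edges = E, possible = P, n = n, L = A$L)
}

#' Draw community weights from their full conditional
#'
#' One draw of `pi | z` from `Dirichlet(alpha_k + n_k)`, where `n_k` is the
#' number of spots with label `k` (zero for empty communities).
#'
#' @param z integer labels.
#' @param priors an [sbm_priors].
#' @return length-`K` probability vector.
#' @export
update_pi <- function(z, priors) {
  stopifnot(inherits(priors, "sbm_priors"))
  K <- priors$K
  z <- validate_labels(z, length(z), K)
  a <- priors$alpha + tabulate(z, K)
  g <- rgamma(K, shape = a, rate = 1)
  g / sum(g)
}

#' Draw the connectivity matrix from its full conditional
#'
#' Independent draws `theta_rs | z ~ Beta(beta1 + E_rs, beta2 + P_rs - E_rs)`
#' for `r <= s`, mirrored below the diagonal. A community pair with no
#' possible edges falls back to the prior.
#'
#' @param counts output of [pair_counts()].
#' @param priors an [sbm_priors].
#' @return symmetric `K x K` matrix with entries in `[0, 1]`.
#' @export
update_theta <- function(counts, priors) {
  stopifnot(inherits(priors, "sbm_priors"))
  E <- counts$edges
  P <- counts$possible
  if (any(E > P))
    stop_invalid("observed edge counts exceed possible edge counts")
  K <- nrow(E)
  ut <- which(upper.tri(E, diag = TRUE))  # column-major: s outer, r <= s
  draws <- rbeta(length(ut), priors$beta1 + E[ut], priors$beta2 + P[ut] - E[ut])
  th <- matrix(0, K, K)
  th[ut] <- draws
  th <- th + t(th)
  diag(th) <- diag(th) / 2
  th
}

#' One systematic sweep of the label full conditionals
#'
#' Visits spots in order `1..N` and redraws each label from its categorical
#' full conditional, with probabilities proportional to
#' `pi_k * prod_l prod_{j != i} theta[k, z_j]^A_ij^l (1 - theta[k, z_j])^(1 - A_ij^l)`,
#' each unordered pair entering once per layer. Computed in log space with
#' `theta` clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param A a [multilayer_graph].
#' @param z current labels.
#' @param pi community weights.
#' @param theta connectivity matrix.
#' @return updated integer label vector.
#' @export
update_z <- function(A, z, pi, theta) {
  stopifnot(inherits(A, "multilayer_graph"))
  K <- length(pi)
  z <- validate_labels(z, A$N, K)
  cpp_sweep_z(edges_zero_based(A), A$N, z, as.numeric(pi),
              matrix(as.numeric(theta), K, K))
}

#' Canonical relabeling of a community assignment
#'
#' Renames labels so that their first occurrences along `z` appear in
#' increasing order `1, 2, ...`, applying the same permutation to `pi` and
#' to the rows/columns of `theta`. Labels absent from `z` fill the remaining
#' slots in ascending original order. Idempotent, and the joint posterior is
#' invariant under it.
#'
#' @param z integer labels in `1..K`.
#' @param pi optional community weights to permute alongside.
#' @param theta optional connectivity matrix to permute alongside.
#' @return list with elements `z`, `pi`, `theta` (the latter two `NULL` if
#'   not supplied) and the applied permutation `map` (`map[old] = new`).
#' @export
canonical_relabel <- function(z, pi = NULL, theta = NULL) {
  z <- as.integer(z)
  K <- if (!is.null(pi)) length(pi) else max(z)
  if (any(z < 1L) || any(z > K)) stop_invalid("labels must lie in 1..K")
  seen <- unique(z)
  map <- integer(K)
  map[seen] <- seq_along(seen)
  absent <- setdiff(seq_len(K), seen)
  if (length(absent)) map[absent] <- length(seen) + seq_along(absent)
  inv <- order(map)  # old label for each new label
  list(z = map[z],
       pi = if (!is.null(pi)) pi[inv] else NULL,
       theta = if (!is.null(theta)) theta[inv, inv, drop = FALSE] else NULL,
       map = map)
}

#' Joint log posterior of the multi-layer SBM
#'
#' Bernoulli log likelihood over all unordered pairs and layers plus the
#' categorical, Dirichlet, and Beta log prior terms. `theta` is clamped to
#' `[1e-12, 1 - 1e-12]` so the value is always finite.
#'
#' @param A a [multilayer_graph].
#' @param z integer labels.
#' @param pi community weights.
#' @param theta connectivity matrix.
#' @param priors an [sbm_priors].
#' @return scalar log posterior (up to the model-constant normalizer).
#' @export
log_posterior <- function(A, z, pi, theta, priors) {
  stopifnot(inherits(priors, "sbm_priors"))
  K <- priors$K
  z <- validate_labels(z, A$N, K)
  cnt <- pair_counts(A, z, K)
  th <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
  logt <- log(th)
  log1mt <- log1p(-th)
  ut <- upper.tri(th, diag = TRUE)
  ll <- sum(cnt$edges[ut] * logt[ut] +
            (cnt$possible[ut] - cnt$edges[ut]) * log1mt[ut])
  lpi <- log(pmax(pi, 1e-300))
  lp <- ll + sum(cnt$n * lpi)
  lp <- lp + lgamma(sum(priors$alpha)) - sum(lgamma(priors$alpha))
  nz <- priors$alpha != 1
  if (any(nz)) lp <- lp + sum((priors$alpha[nz] - 1) * lpi[nz])
  lp + sum((priors$beta1 - 1) * logt[ut] + (priors$beta2 - 1) * log1mt[ut] -
           lbeta(priors$beta1, priors$beta2))
}
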