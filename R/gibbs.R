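#' Initialize community labels by modularity clustering
#'
#' Runs Louvain modularity clustering on the expression layer, then adjusts
#' the number of clusters to exactly `K`: extra clusters are merged pairwise
#' (choosing at each step the merge that least decreases modularity), and
#' missing clusters are created by 2-means splits of the largest cluster on
#' the leading eigenvectors of its adjacency submatrix. The result is
#' returned in canonical first-occurrence order.
#'
#' @param A1 binary symmetric adjacency matrix (expression layer) or a
#'   [multilayer_graph], in which case its first layer is used.
#' @param K target number of communities (`1 <= K <= N`).
#' @param seed integer seed; the procedure is deterministic given the seed.
#' @return integer label vector with exactly `K` non-empty groups.
#' @export
init_labels <- function(A1, K, seed) {
  if (inherits(A1, "multilayer_graph")) A1 <- as_adjacency(A1, 1L)
  N <- nrow(A1)
  if (length(K) != 1L || is.na(K) || K < 1) stop_invalid("K must be >= 1")
  if (K > N) stop_invalid(sprintf("K = %d exceeds the number of nodes %d", K, N))
  if (missing(seed)) stop_invalid("seed must be given explicitly")
  if (K == 1L) return(rep(1L, N))
  if (K == N) return(seq_len(N))
  set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(A1, mode = "undirected")
  memb <- as.integer(igraph::membership(igraph::cluster_louvain(g)))

  renumber <- function(m) match(m, sort(unique(m)))
  memb <- renumber(memb)

  while (max(memb) > K) {
    k <- max(memb)
    best <- NULL
    best_q <- -Inf
    for (a in seq_len(k - 1L)) {
      for (b in seq((a + 1L), k)) {
        cand <- memb
        cand[cand == b] <- a
        q <- igraph::modularity(g, renumber(cand))
        if (q > best_q) {
          best_q <- q
          best <- c(a, b)
        }
      }
    }
    memb[memb == best[2L]] <- best[1L]
    memb <- renumber(memb)
  }

  while (max(memb) < K) {
    sizes <- tabulate(memb)
    target <- which.max(sizes)  # ties: lowest label
    nodes <- which(memb == target)
    grp <- split_cluster(A1[nodes, nodes, drop = FALSE])
    memb[nodes[grp == 2L]] <- max(memb) + 1L
    memb <- renumber(memb)
  }
  canonical_relabel(memb)$z
}

# 2-means on the leading eigenvectors of an adjacency submatrix; falls back
# to an index-half split when the geometry is degenerate
split_cluster <- function(Asub) {
  m <- nrow(Asub)
  if (m < 2L) stop_invalid("cannot split a singleton cluster")
  half_split <- function() rep(c(1L, 2L), c(ceiling(m / 2), floor(m / 2)))
  if (m == 2L) return(c(1L, 2L))
  ev <- eigen(Asub, symmetric = TRUE)$vectors[, seq_len(min(2L, m)), drop = FALSE]
  grp <- tryCatch(kmeans(ev, centers = 2L, nstart = 10L)$cluster,
                  error = function(e) half_split())
  if (length(unique(grp)) < 2L) grp <- half_split()
  grp
}

#' Fit the multi-layer SBM by Gibbs sampling
#'
#' Initializes labels with [init_labels()], then iterates the conjugate
#' full-conditional updates of the community weights, the connectivity
#' matrix, and the labels, applying the canonical relabeling projection at
#' every iteration. Post-burn draws of `(z, pi, theta)` are stored together
#' with the joint log posterior of every iteration.
#'
#' @param A a [multilayer_graph]; layers are validated before sampling.
#' @param K number of communities.
#' @param priors an [sbm_priors]; defaults to `sbm_priors(K)`.
#' @param n_iter total number of iterations (default 2000).
#' @param burn number of burn-in iterations discarded from storage
#'   (default 1000, must be `< n_iter`).
#' @param seed integer seed, required explicitly; the full chain is
#'   reproducible given `(A, K, priors, n_iter, seed)`.
#' @param z_init optional starting labels (bypasses [init_labels()]).
#' @param verbose print iteration, log posterior, and occupied-community
#'   count every 100 sweeps.
#' @return an object of class `sbm_fit` with post-burn chains `z_chain`
#'   (iterations x N), `pi_chain` (iterations x K), `theta_chain`
#'   (iterations x K x K), per-iteration `log_post`, and the run
#'   configuration.
#' @export
run_gibbs <- function(A, K, priors = NULL, n_iter = 2000, burn = 1000, seed,
                      z_init = NULL, verbose = FALSE) {
  stopifnot(inherits(A, "multilayer_graph"))
  if (missing(seed)) stop_invalid("seed must be given explicitly")
  if (length(K) != 1L || is.na(K) || K < 1) stop_invalid("K must be >= 1")
  if (burn < 0 || burn >= n_iter) stop_invalid("burn must satisfy 0 <= burn < n_iter")
  if (is.null(priors)) priors <- sbm_priors(K)
  stopifnot(inherits(priors, "sbm_priors"))
  if (priors$K != K) stop_invalid("priors were built for a different K")
  for (l in seq_len(A$L)) validate_edge_list(A$edges[[l]], A$N)

  if (is.null(z_init)) {
    z_init <- init_labels(A, K, seed = seed)  # also seeds the chain RNG
  } else {
    set.seed(seed)
    z_init <- validate_labels(z_init, A$N, K)
  }

  res <- cpp_gibbs_chain(edges_zero_based(A), A$N, as.integer(K),
                         priors$alpha, priors$beta1, priors$beta2,
                         as.integer(n_iter), as.integer(burn),
                         z_init, isTRUE(verbose))
  n_keep <- n_iter - burn
  fit <- structure(
    list(z_chain = res$z_chain,
         pi_chain = res$pi_chain,
         theta_chain = array(res$theta_chain, dim = c(n_keep, K, K)),
         log_post = as.numeric(res$log_post),
         burn = as.integer(burn), n_iter = as.integer(n_iter),
         K = as.integer(K), N = A$N, L = A$L,
         priors = priors, seed = seed, spot_ids = A$spot_ids),
    class = "sbm_fit")
  fit
}

#' Maximum a posteriori community labels
#'
#' Returns the stored post-burn label vector from the iteration with the
#' highest joint log posterior (ties broken toward the earliest iteration).
#'
#' @param fit an `sbm_fit` from [run_gibbs()].
#' @return integer label vector with attribute `"iteration"` (index into the
#'   post-burn chain). A warning is issued if fewer than `K` labels occur.
#' @export
map_labels <- function(fit) {
  stopifnot(inherits(fit, "sbm_fit"))
  lp <- post_burn_log_post(fit)
  if (length(lp) == 0L) stop_invalid("no post-burn samples stored")
  idx <- which.max(lp)
  z <- as.integer(fit$z_chain[idx, ])
  k_used <- length(unique(z))
  if (k_used < fit$K)
    warning(sprintf("MAP labels use %d of %d communities", k_used, fit$K))
  attr(z, "iteration") <- idx
  z
}

post_burn_log_post <- function(fit) {
  fit$log_post[seq.int(fit$burn + 1L, fit$n_iter)]
}

#' @export
print.sbm_fit <- function(x, ...) {
  cat(sprintf("sbm_fit: N = %d spots, L = %d layers, K = %d communities\n",
              x$N, x$L, x$K))
  cat(sprintf("  %d iterations (%d burn-in), seed %s\n", x$n_iter, x$burn,
              format(x$seed)))
  lp <- post_burn_log_post(x)
  cat(sprintf("  post-burn log posterior: max %.2f at iteration %d\n",
              max(lp), which.max(lp)))
  invisible(x)
}
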