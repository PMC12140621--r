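#' Banded triangular-lattice tissue layout
#'
#' Places `n_spots` on a triangular lattice inside a near-square rectangle
#' (approximating the hexagonal spot geometry of array-based platforms) and
#' partitions them into `n_bands` spatially contiguous vertical bands of
#' near-equal size (sizes differ by at most 1). The band index is the
#' ground-truth community label.
#'
#' @param n_spots number of spots.
#' @param n_bands number of bands (`1 <= n_bands <= n_spots`).
#' @param jitter half-width of uniform positional noise added to both
#'   coordinates after band assignment (0 keeps the exact lattice).
#' @param seed integer RNG seed.
#' @return list with `coords` (`n_spots x 2` matrix, row names `spot1..`)
#'   and `z_true` (integer band labels).
#' @export
make_layout <- function(n_spots, n_bands = 5, jitter = 0, seed = 1) {
  if (length(n_bands) != 1L || is.na(n_bands) || n_bands < 1)
    stop_invalid("n_bands must be >= 1")
  if (n_bands > n_spots) stop_invalid("n_bands exceeds n_spots")
  set.seed(seed)
  h <- sqrt(3) / 2
  n_col <- max(2L, ceiling(sqrt(n_spots * h)))
  n_row <- ceiling(n_spots / n_col)
  row_id <- rep(seq_len(n_row), each = n_col)[seq_len(n_spots)]
  col_id <- rep(seq_len(n_col), times = n_row)[seq_len(n_spots)]
  x <- col_id + 0.5 * (row_id %% 2)
  y <- row_id * h
  # contiguous vertical bands of near-equal size by x-rank
  sizes <- rep(n_spots %/% n_bands, n_bands)
  extra <- n_spots %% n_bands
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(x, y)
  z_true <- integer(n_spots)
  z_true[ord] <- rep(seq_len(n_bands), times = sizes)
  if (jitter > 0) {
    x <- x + runif(n_spots, -jitter, jitter)
    y <- y + runif(n_spots, -jitter, jitter)
  }
  coords <- cbind(x = x, y = y)
  rownames(coords) <- paste0("spot", seq_len(n_spots))
  list(coords = coords, z_true = z_true)
}

#' Connectivity matrices for the simulation designs
#'
#' Base design: `K x K` matrix with within-community connectivity 0.3 on the
#' diagonal and between-community connectivity 0.1 elsewhere (SNR 3). The
#' named settings perturb the 5-community base:
#' \describe{
#'   \item{`default`}{the base matrix.}
#'   \item{`setting1`}{raises the between-community entries of the spatially
#'     disjoint pair (1,3) and the bordering pair (4,5) to `params$v`.}
#'   \item{`setting2`}{as `setting1` with `v` fixed at 0.2 (intended for
#'     under-specified `K = 4` fits).}
#'   \item{`setting3`}{lowers the within-community entries of communities
#'     1-3 to `params$v`.}
#' }
#'
#' @param setting one of `"default"`, `"setting1"`, `"setting2"`,
#'   `"setting3"`.
#' @param K number of communities (must be 5 for the named settings).
#' @param params list; `v` gives the perturbed value in `[0, 1]`, and
#'   `within` / `between` override the base values (default 0.3 / 0.1).
#' @return symmetric `K x K` connectivity matrix.
#' @export
setting_theta <- function(setting = c("default", "setting1", "setting2",
                                      "setting3"),
                          K = 5, params = list()) {
  setting <- match.arg(setting)
  within <- if (!is.null(params$within)) params$within else 0.3
  between <- if (!is.null(params$between)) params$between else 0.1
  if (any(c(within, between) < 0) || any(c(within, between) > 1))
    stop_invalid("connectivity values must lie in [0, 1]")
  theta <- matrix(between, K, K)
  diag(theta) <- within
  if (setting == "default") return(theta)
  if (K != 5L) stop_invalid("named settings are defined for K = 5")
  v <- params$v
  if (setting == "setting2") v <- if (is.null(v)) 0.2 else v
  if (is.null(v)) stop_invalid("params$v is required for this setting")
  if (v < 0 || v > 1) stop_invalid("params$v must lie in [0, 1]")
  if (setting %in% c("setting1", "setting2")) {
    theta[1, 3] <- theta[3, 1] <- v
    theta[4, 5] <- theta[5, 4] <- v
  } else {
    theta[1, 1] <- theta[2, 2] <- theta[3, 3] <- v
  }
  theta
}

#' Sample one SBM adjacency layer
#'
#' Independent `Bernoulli(theta[z_i, z_j])` draws for every unordered pair
#' `i < j`, mirrored to a symmetric zero-diagonal binary matrix.
#'
#' @param z integer community labels.
#' @param theta symmetric connectivity matrix with entries in `[0, 1]`.
#' @return binary adjacency matrix.
#' @export
sample_sbm_layer <- function(z, theta) {
  z <- as.integer(z)
  n <- length(z)
  theta <- as.matrix(theta)
  if (any(theta < 0) || any(theta > 1))
    stop_invalid("theta entries must lie in [0, 1]")
  if (max(z) > nrow(theta)) stop_invalid("labels exceed theta dimension")
  idx <- which(upper.tri(diag(n)))
  i <- (idx - 1L) %% n + 1L
  j <- (idx - 1L) %/% n + 1L
  a <- rbinom(length(idx), 1L, theta[cbind(z[i], z[j])])
  A <- matrix(0L, n, n)
  A[idx] <- a
  A <- A + t(A)
  A
}

#' Generate a full simulated experiment
#'
#' Builds a banded layout, samples the expression layer from the SBM with
#' the requested connectivity matrix, and constructs the spatial layer.
#' By default the spatial layer is the KNN graph of the lattice coordinates
#' (geometry-derived, which is what produces the spatial-proximity effects
#' of the banded designs); `spatial_layer = "sbm"` instead samples it from
#' the same connectivity matrix, giving a fully generative two-layer SBM
#' suitable for connectivity-calibration checks.
#'
#' @param setting design name passed to [setting_theta()].
#' @param n_spots number of spots (default 800).
#' @param params design parameters passed to [setting_theta()].
#' @param R spatial KNN neighborhood size; `NULL` for
#'   [default_neighbors()].
#' @param n_bands number of bands/communities (default 5).
#' @param jitter positional noise for [make_layout()].
#' @param seed integer RNG seed (required).
#' @param spatial_layer `"knn"` (geometry-derived) or `"sbm"` (sampled).
#' @return an object of class `sim_truth`: `coords`, `z_true`,
#'   `theta_true`, `graph` (a [multilayer_graph]), `snr`, `R`, `seed`,
#'   `setting`.
#' @export
simulate_experiment <- function(setting = "default", n_spots = 800,
                                params = list(), R = NULL, n_bands = 5,
                                jitter = 0, seed, spatial_layer = c("knn",
                                                                    "sbm")) {
  if (missing(seed)) stop_invalid("seed must be given explicitly")
  spatial_layer <- match.arg(spatial_layer)
  theta_true <- setting_theta(setting, K = n_bands, params = params)
  layout <- make_layout(n_spots, n_bands = n_bands, jitter = jitter,
                        seed = seed)
  if (is.null(R)) R <- default_neighbors(n_spots)
  A1 <- sample_sbm_layer(layout$z_true, theta_true)
  A2 <- if (spatial_layer == "knn") {
    knn_graph(layout$coords, R)
  } else {
    sample_sbm_layer(layout$z_true, theta_true)
  }
  rownames(A1) <- colnames(A1) <- rownames(layout$coords)
  rownames(A2) <- colnames(A2) <- rownames(layout$coords)
  graph <- multilayer_graph(list(expression = A1, spatial = A2))
  structure(list(coords = layout$coords, z_true = layout$z_true,
                 theta_true = theta_true, graph = graph,
                 snr = snr_estimate(theta_true), R = R, seed = seed,
                 setting = setting, spatial_layer = spatial_layer,
                 n_bands = as.integer(n_bands)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %s, %d spots, %d bands, R = %d, seed %s\n",
              x$setting, nrow(x$coords), x$n_bands, x$R, format(x$seed)))
  cat(sprintf("  spatial layer: %s; true SNR = %.2f\n", x$spatial_layer,
              x$snr))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors; 1 if and only if
#' the partitions are identical up to relabeling, about 0 for independent
#' partitions.
#'
#' @param z_a,z_b label vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
ari <- function(z_a, z_b) {
  if (length(z_a) != length(z_b)) stop_invalid("label vectors differ in length")
  tab <- table(z_a, z_b)
  n <- length(z_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == max_index) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}
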