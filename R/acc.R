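#' Summarize community connectivity from posterior samples
#'
#' Point estimates and equal-tailed credible intervals for every entry of
#' the connectivity matrix. The default point estimate is the `theta` draw
#' stored at the MAP iteration (self-consistent with [map_labels()]); the
#' elementwise posterior mean is available as an alternative. The diagonal
#' gives the within-community connectivity (WCC), the upper off-diagonal
#' entries the between-community connectivity (BCC).
#'
#' @param fit an `sbm_fit` from [run_gibbs()].
#' @param level credible level in `(0, 1)` (default 0.95).
#' @param estimate `"map"` (theta at the MAP iteration) or `"mean"`
#'   (elementwise posterior mean).
#' @return an object of class `acc_summary` with `theta_hat`, `wcc`,
#'   `bcc` (data frame `r`, `s`, `estimate`, `lower`, `upper`), `ci_lower`,
#'   `ci_upper` (`K x K`), `level`, `snr`, and `K`.
#' @export
connectivity_summary <- function(fit, level = 0.95,
                                 estimate = c("map", "mean")) {
  stopifnot(inherits(fit, "sbm_fit"))
  estimate <- match.arg(estimate)
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
    stop_invalid("level must lie strictly between 0 and 1")
  K <- fit$K
  if (dim(fit$theta_chain)[1L] == 0L) stop_invalid("no post-burn samples stored")
  theta_hat <- if (estimate == "map") {
    idx <- which.max(post_burn_log_post(fit))
    matrix(fit$theta_chain[idx, , ], K, K)
  } else {
    apply(fit$theta_chain, c(2, 3), mean)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci_lower <- apply(fit$theta_chain, c(2, 3), quantile, probs = probs[1L])
  ci_upper <- apply(fit$theta_chain, c(2, 3), quantile, probs = probs[2L])
  new_acc_summary(theta_hat, ci_lower, ci_upper, level,
                  source = paste0("posterior (", estimate, ")"))
}

new_acc_summary <- function(theta_hat, ci_lower, ci_upper, level,
                            source, theta_sd = NULL) {
  K <- nrow(theta_hat)
  wcc <- diag(theta_hat)
  bcc <- NULL
  if (K >= 2) {
    pr <- which(upper.tri(theta_hat), arr.ind = TRUE)
    pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
    bcc <- data.frame(r = pr[, 1L], s = pr[, 2L],
                      estimate = theta_hat[pr],
                      lower = ci_lower[pr], upper = ci_upper[pr])
  }
  snr <- if (K >= 2) snr_estimate(theta_hat) else NA_real_
  structure(list(theta_hat = theta_hat, wcc = wcc, bcc = bcc,
                 ci_lower = ci_lower, ci_upper = ci_upper, level = level,
                 snr = snr, K = K, source = source, theta_sd = theta_sd),
            class = "acc_summary")
}

#' @export
print.acc_summary <- function(x, digits = 3, ...) {
  cat(sprintf("acc_summary (%s): K = %d, level = %.2f\n", x$source, x$K,
              x$level))
  cat("within-community connectivity (WCC):\n")
  print(round(x$wcc, digits))
  if (!is.null(x$bcc)) {
    cat("between-community connectivity (BCC):\n")
    print(cbind(x$bcc[, c("r", "s")], round(x$bcc[, c("estimate", "lower",
                                                      "upper")], digits)),
          row.names = FALSE)
    cat(sprintf("estimated SNR (mean WCC / mean BCC): %.2f\n", x$snr))
  }
  invisible(x)
}

#' Signal-to-noise ratio of a connectivity matrix
#'
#' The mean of the diagonal (within-community connectivity) divided by the
#' mean of the off-diagonal entries (between-community connectivity). A
#' value of 1 indicates no community structure; the banded simulation
#' defaults (within 0.3, between 0.1) give 3.
#'
#' @param theta `K x K` connectivity matrix with `K >= 2`.
#' @return scalar ratio; `Inf` if the off-diagonal mean is zero.
#' @export
snr_estimate <- function(theta) {
  theta <- as.matrix(theta)
  if (nrow(theta) < 2L) stop_invalid("SNR requires K >= 2")
  within <- mean(diag(theta))
  between <- mean(theta[row(theta) != col(theta)])
  if (between == 0) return(Inf)
  within / between
}

#' Community connectivity from external labels
#'
#' Holding the community assignment fixed at externally supplied labels
#' (e.g., clusters from any other method), the connectivity posterior is
#' exactly `Beta(beta1 + E_rs, beta2 + P_rs - E_rs)` for each pair, so point
#' estimates (posterior means), posterior standard deviations, and
#' equal-tailed intervals are analytic Beta quantities.
#'
#' @param A a [multilayer_graph].
#' @param z_ext external labels aligned with `A`; arbitrary codes are
#'   mapped to `1..K'` in canonical first-occurrence order.
#' @param priors an [sbm_priors] for `K'` communities (default uniform).
#' @param level credible level in `(0, 1)`.
#' @param n_draws if positive, intervals are instead computed from this many
#'   Monte Carlo draws per entry (mainly for cross-checks).
#' @param seed RNG seed used only when `n_draws > 0`.
#' @return an `acc_summary`; `theta_sd` holds the analytic posterior
#'   standard deviations.
#' @export
external_labels_acc <- function(A, z_ext, priors = NULL, level = 0.95,
                                n_draws = 0, seed = NULL) {
  stopifnot(inherits(A, "multilayer_graph"))
  if (length(z_ext) != A$N) stop_invalid("labels not aligned with graph")
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
    stop_invalid("level must lie strictly between 0 and 1")
  z <- canonical_relabel(match(z_ext, unique(z_ext)))$z
  K <- max(z)
  if (is.null(priors)) priors <- sbm_priors(K)
  if (priors$K != K) stop_invalid("priors were built for a different K")
  cnt <- pair_counts(A, z, K)
  a <- priors$beta1 + cnt$edges
  b <- priors$beta2 + cnt$possible - cnt$edges
  theta_hat <- a / (a + b)
  theta_sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  lo <- (1 - level) / 2
  if (n_draws > 0) {
    if (!is.null(seed)) set.seed(seed)
    draws <- array(rbeta(n_draws * K * K, rep(a, each = n_draws),
                         rep(b, each = n_draws)), dim = c(n_draws, K, K))
    ci_lower <- apply(draws, c(2, 3), quantile, probs = lo)
    ci_upper <- apply(draws, c(2, 3), quantile, probs = 1 - lo)
  } else {
    ci_lower <- matrix(qbeta(lo, a, b), K, K)
    ci_upper <- matrix(qbeta(1 - lo, a, b), K, K)
  }
  new_acc_summary(theta_hat, ci_lower, ci_upper, level,
                  source = "external labels", theta_sd = theta_sd)
}
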