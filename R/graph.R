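#' Multi-layer binary graph
#'
#' Container for `L` binary, symmetric, zero-diagonal adjacency layers over
#' the same `N` spots (typically an expression-similarity layer and a
#' spatial-proximity layer). Layers are stored internally as `i < j` edge
#' lists (1-based).
#'
#' @param layers list of `N x N` binary symmetric adjacency matrices with
#'   zero diagonal, or of 2-column `i < j` edge-list matrices when `N` is
#'   given.
#' @param N number of nodes; required when `layers` are edge lists.
#' @param spot_ids optional character vector of node identifiers.
#' @return an object of class `multilayer_graph` with elements `edges`
#'   (list of 2-column integer matrices), `N`, `L`, `layer_names`,
#'   `spot_ids`.
#' @export
multilayer_graph <- function(layers, N = NULL, spot_ids = NULL) {
  if (!is.list(layers) || length(layers) == 0L)
    stop_invalid("layers must be a non-empty list")
  nm <- names(layers)
  if (is.null(nm)) nm <- paste0("layer", seq_along(layers))
  first <- layers[[1L]]
  if (is.matrix(first) && !is.null(N)) {
    edges <- lapply(layers, function(e) {
      e <- matrix(as.integer(e), ncol = 2)
      validate_edge_list(e, N)
      e
    })
  } else {
    if (!all(vapply(layers, is.matrix, logical(1))))
      stop_invalid("layers must be matrices")
    N <- nrow(first)
    edges <- lapply(seq_along(layers), function(l) {
      A <- layers[[l]]
      validate_adjacency(A, N, nm[l])
      adjacency_to_edges(A)
    })
    if (is.null(spot_ids)) spot_ids <- rownames(first)
  }
  names(edges) <- NULL
  structure(list(edges = edges, N = as.integer(N), L = length(edges),
                 layer_names = nm, spot_ids = spot_ids),
            class = "multilayer_graph")
}

validate_adjacency <- function(A, N, what = "layer") {
  if (nrow(A) != N || ncol(A) != N)
    stop_invalid(sprintf("%s must be %d x %d", what, N, N))
  if (anyNA(A) || !all(A %in% c(0, 1)))
    stop_invalid(sprintf("%s must be binary", what))
  if (any(diag(A) != 0)) stop_invalid(sprintf("%s has a non-zero diagonal", what))
  if (!isTRUE(all(A == t(A)))) stop_invalid(sprintf("%s is not symmetric", what))
  invisible(A)
}

validate_edge_list <- function(e, N) {
  if (ncol(e) != 2L) stop_invalid("edge list must have 2 columns")
  if (nrow(e) > 0L) {
    if (anyNA(e) || any(e < 1L) || any(e > N))
      stop_invalid("edge list indices out of range")
    if (any(e[, 1L] >= e[, 2L]))
      stop_invalid("edge list must satisfy i < j (no self loops)")
    if (anyDuplicated(e[, 1L] + as.numeric(N) * e[, 2L]))
      stop_invalid("edge list contains duplicate edges")
  }
  invisible(e)
}

adjacency_to_edges <- function(A) {
  idx <- which(upper.tri(A) & A != 0)
  n <- nrow(A)
  cbind(as.integer((idx - 1L) %% n + 1L),
        as.integer((idx - 1L) %/% n + 1L))
}

#' Extract one layer as a dense adjacency matrix
#'
#' @param g a [multilayer_graph].
#' @param layer layer index or name.
#' @return binary symmetric adjacency matrix.
#' @export
as_adjacency <- function(g, layer = 1L) {
  stopifnot(inherits(g, "multilayer_graph"))
  if (is.character(layer)) layer <- match(layer, g$layer_names)
  e <- g$edges[[layer]]
  A <- matrix(0L, g$N, g$N)
  if (nrow(e)) {
    A[e] <- 1L
    A[e[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  dimnames(A) <- list(g$spot_ids, g$spot_ids)
  A
}

#' @export
print.multilayer_graph <- function(x, ...) {
  cat(sprintf("multilayer_graph: %d nodes, %d layers\n", x$N, x$L))
  for (l in seq_len(x$L))
    cat(sprintf("  %s: %d edges (mean degree %.1f)\n", x$layer_names[l],
                nrow(x$edges[[l]]), 2 * nrow(x$edges[[l]]) / x$N))
  invisible(x)
}

edges_zero_based <- function(g) {
  lapply(g$edges, function(e) e - 1L)
}
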