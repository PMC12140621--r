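#' Normalize a spot-by-gene count matrix
#'
#' Standard single-cell style normalization used before highly variable gene
#' selection and PCA: library-size scaling to the median total count, a
#' `log1p` transform, and optional per-gene standardization. Each step can be
#' switched off independently.
#'
#' @param counts numeric matrix, spots in rows, genes in columns, no negative
#'   entries. Row names are spot identifiers, column names gene identifiers.
#' @param libsize scale each spot to the median total count.
#' @param log1p apply `log(1 + x)` after library-size scaling.
#' @param scale standardize each gene to zero mean and unit variance
#'   (genes with zero variance are centered only).
#' @return numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts, libsize = TRUE, log1p = TRUE,
                             scale = FALSE) {
  counts <- validate_expression(counts)
  x <- counts
  if (libsize) {
    tot <- rowSums(x)
    target <- median(tot)
    fac <- ifelse(tot > 0, target / tot, 0)
    x <- x * fac
  }
  if (log1p) x <- log1p(x)
  if (scale) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  }
  x
}

validate_expression <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (length(counts) == 0L || nrow(counts) == 0L || ncol(counts) == 0L)
    stop_invalid("expression matrix is empty")
  if (!is.numeric(counts)) stop_invalid("expression matrix must be numeric")
  if (anyNA(counts) || any(counts < 0))
    stop_invalid("expression matrix must be non-negative with no missing values")
  if (!is.null(rownames(counts)) && anyDuplicated(rownames(counts)))
    stop_invalid("duplicated spot identifiers in expression matrix")
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
    stop_invalid("duplicated gene identifiers in expression matrix")
  counts
}

validate_coords <- function(coords) {
  if (!is.matrix(coords)) coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop_invalid("coordinates must have exactly 2 columns")
  if (!all(is.finite(coords))) stop_invalid("coordinates must be finite")
  coords
}

#' Select highly variable genes
#'
#' Ranks genes by variance computed after library-size and `log1p`
#' normalization (per-gene standardization is never applied here, since it
#' would equalize all variances) and keeps the `n_top` most variable genes.
#'
#' @param counts spot-by-gene count matrix.
#' @param n_top number of genes to keep; the default mirrors common practice
#'   of retaining the top 2,000 variable genes. If `n_top` is at least the
#'   number of genes, all genes are returned (still ordered by variance).
#' @param normalize apply library-size + `log1p` normalization before
#'   computing variances; set `FALSE` to rank raw values.
#' @return the input matrix restricted to the selected genes, columns ordered
#'   by decreasing variance.
#' @export
select_hvg <- function(counts, n_top = 2000, normalize = TRUE) {
  counts <- validate_expression(counts)
  if (length(n_top) != 1L || is.na(n_top) || n_top < 1)
    stop_invalid("n_top must be a positive integer")
  x <- if (normalize) normalize_counts(counts, scale = FALSE) else counts
  v <- apply(x, 2, var)
  ord <- order(-v)  # ties resolved by ascending column index
  keep <- ord[seq_len(min(ncol(counts), floor(n_top)))]
  counts[, keep, drop = FALSE]
}

#' Embed spots by principal components analysis
#'
#' @param counts spot-by-gene matrix (typically the highly variable subset).
#' @param n_components number of components to retain; must not exceed the
#'   rank bound `min(nrow - 1, ncol)` of the centered matrix.
#' @param normalize apply library-size + `log1p` normalization first.
#' @param scale standardize genes before PCA.
#' @return spots-by-`n_components` score matrix, rows aligned with the input
#'   spot order, components in decreasing explained-variance order. The
#'   component standard deviations are attached as attribute `"sdev"`.
#' @export
pca_embed <- function(counts, n_components = 15, normalize = TRUE,
                      scale = TRUE) {
  counts <- validate_expression(counts)
  if (length(n_components) != 1L || is.na(n_components) || n_components < 1)
    stop_invalid("n_components must be a positive integer")
  x <- normalize_counts(counts, libsize = normalize, log1p = normalize,
                        scale = scale)
  rank_bound <- min(nrow(x) - 1L, ncol(x))
  if (n_components > rank_bound)
    stop_invalid(sprintf(
      "n_components = %d exceeds the rank bound min(N - 1, genes) = %d",
      n_components, rank_bound))
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  emb <- p$x[, seq_len(n_components), drop = FALSE]
  rownames(emb) <- rownames(counts)
  attr(emb, "sdev") <- p$sdev
  emb
}

#' Default neighborhood size for the KNN layers
#'
#' The closest odd integer to `sqrt(N)`, with exact ties broken downward.
#' For typical tissue sections of 2,000-3,000 spots this gives `R` around
#' 45-55 neighbors, i.e., third- to fourth-order neighborhoods on a
#' hexagonal spot lattice.
#'
#' @param N number of spots (at least 2).
#' @return an odd positive integer.
#' @export
default_neighbors <- function(N) {
  if (length(N) != 1L || is.na(N) || N < 2) stop_invalid("N must be at least 2")
  s <- sqrt(N)
  lo <- 2L * as.integer(floor((s - 1) / 2)) + 1L  # largest odd <= s
  if (lo < 1L) lo <- 1L
  hi <- lo + 2L
  if ((s - lo) <= (hi - s)) lo else hi
}

#' Build a symmetrized K-nearest-neighbor adjacency matrix
#'
#' Connects every point to its `R` nearest neighbors by Euclidean distance
#' (self excluded, distance ties broken by ascending index) and symmetrizes
#' the resulting digraph by union, so every node ends with degree at least
#' `R`.
#'
#' @param points numeric matrix of point coordinates (spots in rows); either
#'   a PCA embedding or 2-D spatial coordinates.
#' @param R number of nearest neighbors, `1 <= R < nrow(points)`.
#' @return binary symmetric adjacency matrix with zero diagonal.
#' @export
knn_graph <- function(points, R) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (!all(is.finite(points))) stop_invalid("points must be finite")
  n <- nrow(points)
  if (length(R) != 1L || is.na(R) || R < 1) stop_invalid("R must be positive")
  if (R >= n) stop_invalid(sprintf("R = %d must be smaller than N = %d", R, n))
  d <- as.matrix(dist(points))
  diag(d) <- Inf
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[seq_len(R)]  # stable: ties fall to lowest index
    A[i, nn] <- 1L
  }
  A <- (A | t(A)) * 1L
  diag(A) <- 0L
  dimnames(A) <- list(rownames(points), rownames(points))
  A
}

#' Combine expression and spatial layers into a multi-layer graph
#'
#' Layer 1 is the KNN graph of the PCA embedding of the highly variable
#' genes; layer 2 is the KNN graph of the spatial coordinates. Both layers
#' use the same `R`, which defaults to [default_neighbors()].
#'
#' @param counts spot-by-gene count matrix with spot row names.
#' @param coords spot coordinates, 2 columns, row names aligned with
#'   `counts` (order may differ; rows are matched by name).
#' @param R neighborhood size; `NULL` for the default heuristic.
#' @param n_hvg number of highly variable genes.
#' @param n_pcs number of principal components (capped at the rank bound).
#' @param normalize,scale normalization switches passed to the
#'   preprocessing steps.
#' @return a [multilayer_graph] with layers `expression` and `spatial`.
#' @export
build_multilayer <- function(counts, coords, R = NULL, n_hvg = 2000,
                             n_pcs = 15, normalize = TRUE, scale = TRUE) {
  counts <- validate_expression(counts)
  coords <- validate_coords(coords)
  if (!is.null(rownames(counts)) && !is.null(rownames(coords))) {
    missing_expr <- setdiff(rownames(counts), rownames(coords))
    missing_coord <- setdiff(rownames(coords), rownames(counts))
    if (length(missing_expr) || length(missing_coord)) {
      bad <- utils::head(c(missing_expr, missing_coord), 10)
      stop_invalid(paste0("spot identifiers do not align; offending ids: ",
                          paste(bad, collapse = ", ")))
    }
    coords <- coords[rownames(counts), , drop = FALSE]
  } else if (nrow(counts) != nrow(coords)) {
    stop_invalid("counts and coords have different numbers of spots")
  }
  n <- nrow(counts)
  if (is.null(R)) R <- default_neighbors(n)
  hvg <- select_hvg(counts, n_top = n_hvg, normalize = normalize)
  d <- min(n_pcs, nrow(hvg) - 1L, ncol(hvg))
  emb <- pca_embed(hvg, n_components = d, normalize = normalize, scale = scale)
  multilayer_graph(list(expression = knn_graph(emb, R),
                        spatial = knn_graph(coords, R)))
}
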