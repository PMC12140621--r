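#' Read a spot-by-gene expression matrix
#'
#' Supports MatrixMarket input (`.mtx`, genes in rows and spots in columns
#' as written by common platform pipelines, transposed on read) with
#' barcode/feature companion files, and dense CSV/TSV (spots in rows, a
#' header row, first column = spot identifier).
#'
#' @param path path to the `.mtx` or delimited file.
#' @param barcodes,features companion files for MTX input (one id per line,
#'   features may be multi-column TSV with ids in column 1). Default to
#'   `barcodes.tsv` / `features.tsv` next to the matrix.
#' @return numeric matrix, spots in rows with identifiers as row names.
#' @export
read_expression <- function(path, barcodes = NULL, features = NULL) {
  if (!file.exists(path)) stop_io(paste0("expression file not found: ", path))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(barcodes)) barcodes <- file.path(dirname(path), "barcodes.tsv")
    if (is.null(features)) features <- file.path(dirname(path), "features.tsv")
    for (f in c(barcodes, features))
      if (!file.exists(f)) stop_io(paste0("companion file not found: ", f))
    m <- as.matrix(Matrix::readMM(path))
    bc <- readLines(barcodes)
    ft <- read.delim(features, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (ncol(m) != length(bc) || nrow(m) != length(ft))
      stop_io(sprintf(
        "MTX dimensions %d x %d do not match %d features / %d barcodes",
        nrow(m), ncol(m), length(ft), length(bc)))
    m <- t(m)
    dimnames(m) <- list(bc, ft)
  } else {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop_io(paste0("expression table needs id + gene columns: ", path))
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop_io(paste0("non-numeric expression values in ", path))
    rownames(m) <- ids
  }
  validate_expression(m)
}

#' Read spot spatial coordinates
#'
#' Supports the Visium `tissue_positions` CSV dialect (columns `barcode`,
#' `in_tissue`, `array_row`, `array_col`, `pxl_row_in_fullres`,
#' `pxl_col_in_fullres`; rows with `in_tissue == 0` are dropped and the
#' pixel columns are used as `y`/`x`), and a generic 3-column CSV
#' (`id`, `x`, `y`).
#'
#' @param path path to the CSV.
#' @return `N x 2` matrix with columns `x`, `y` and spot ids as row names.
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop_io(paste0("coordinates file not found: ", path))
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                 check.names = FALSE)
  nms <- tolower(names(df))
  if (all(c("barcode", "in_tissue", "pxl_row_in_fullres",
            "pxl_col_in_fullres") %in% nms)) {
    names(df) <- nms
    df <- df[df$in_tissue == 1, , drop = FALSE]
    out <- cbind(x = as.numeric(df$pxl_col_in_fullres),
                 y = as.numeric(df$pxl_row_in_fullres))
    rownames(out) <- as.character(df$barcode)
  } else if (ncol(df) >= 3L) {
    out <- cbind(x = as.numeric(df[[2L]]), y = as.numeric(df[[3L]]))
    rownames(out) <- as.character(df[[1L]])
  } else {
    stop_io(paste0("unrecognized coordinates dialect in ", path))
  }
  validate_coords(out)
}

#' Write a multi-layer graph as edge-list TSVs
#'
#' One TSV per layer with columns `node_i`, `node_j`, `layer`; node indices
#' are 0-based with `node_i < node_j`.
#'
#' @param g a [multilayer_graph].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_graph <- function(g, dir) {
  stopifnot(inherits(g, "multilayer_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(g$L)
  for (l in seq_len(g$L)) {
    e <- g$edges[[l]]
    df <- data.frame(node_i = e[, 1L] - 1L, node_j = e[, 2L] - 1L, layer = l)
    paths[l] <- file.path(dir, paste0("edges_", g$layer_names[l], ".tsv"))
    con <- file(paths[l], "w")
    writeLines("# node indices 0-based, node_i < node_j; labels 1-based", con)
    write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read edge-list TSVs into a multi-layer graph
#'
#' Rejects self loops, reversed (`i >= j`) rows, duplicate edges, and
#' out-of-range indices rather than silently repairing them.
#'
#' @param paths edge-list TSV files, one per layer (ordered).
#' @param n_nodes number of nodes `N`.
#' @param layer_names optional layer names (defaults to file stems).
#' @param spot_ids optional node identifiers.
#' @return a [multilayer_graph].
#' @export
read_graph <- function(paths, n_nodes, layer_names = NULL, spot_ids = NULL) {
  edges <- lapply(paths, function(p) {
    if (!file.exists(p)) stop_io(paste0("edge list not found: ", p))
    df <- read.delim(p, sep = "\t", header = TRUE, comment.char = "#")
    if (!all(c("node_i", "node_j") %in% names(df)))
      stop_io(paste0("edge list must have node_i/node_j columns: ", p))
    e <- cbind(as.integer(df$node_i) + 1L, as.integer(df$node_j) + 1L)
    tryCatch(validate_edge_list(e, n_nodes),
             spotacc_invalid_input = function(c)
               stop_io(paste0(conditionMessage(c), " in ", p)))
    e
  })
  if (is.null(layer_names))
    layer_names <- sub("^edges_", "", sub("\\.tsv$", "", basename(paths)))
  names(edges) <- layer_names
  multilayer_graph(edges, N = n_nodes, spot_ids = spot_ids)
}

#' Write community labels to CSV
#'
#' @param z integer labels (1-based).
#' @param spot_ids spot identifiers (defaults to `spot1..`).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_labels <- function(z, spot_ids = NULL, path) {
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_along(z))
  write.csv(data.frame(spot_id = spot_ids, map_label = as.integer(z)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read community labels from CSV
#'
#' @param path CSV with columns `spot_id`, `map_label` (or any 2-column
#'   id/label file).
#' @return named integer vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_io(paste0("labels file not found: ", path))
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_io(paste0("labels file needs id + label columns: ", path))
  stats::setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

#' Export a connectivity summary
#'
#' Writes a JSON document (`theta_hat`, `wcc`, `bcc`, intervals, `snr`,
#' `level`) and a tidy CSV with one row per community pair
#' (`r`, `s`, `estimate`, `lower`, `upper`, `kind` in `WCC`/`BCC`).
#'
#' @param s an `acc_summary`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
write_acc_summary <- function(s, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(s, "acc_summary"))
  K <- s$K
  tidy <- data.frame(r = seq_len(K), s = seq_len(K), estimate = s$wcc,
                     lower = diag(s$ci_lower), upper = diag(s$ci_upper),
                     kind = "WCC")
  if (!is.null(s$bcc))
    tidy <- rbind(tidy, cbind(s$bcc, kind = "BCC"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(K = K, level = s$level, snr = s$snr, source = s$source,
           theta_hat = s$theta_hat, wcc = s$wcc,
           bcc = if (is.null(s$bcc)) list() else s$bcc,
           ci_lower = s$ci_lower, ci_upper = s$ci_upper),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    write.csv(tidy, csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(json_path, csv_path))
}

#' Export a simulated experiment bundle
#'
#' Writes coordinates, true labels, the true connectivity matrix, per-layer
#' edge lists, and a JSON configuration, in formats round-trippable through
#' the package readers.
#'
#' @param sim a `sim_truth` from [simulate_experiment()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
export_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(id = rownames(sim$coords), x = sim$coords[, 1L],
                       y = sim$coords[, 2L]),
            file.path(dir, "coords.csv"), row.names = FALSE, quote = FALSE)
  write_labels(sim$z_true, rownames(sim$coords),
               file.path(dir, "true_labels.csv"))
  write.csv(sim$theta_true, file.path(dir, "theta_true.csv"),
            row.names = FALSE)
  write_graph(sim$graph, dir)
  jsonlite::write_json(
    list(setting = sim$setting, n_spots = nrow(sim$coords),
         n_bands = sim$n_bands, R = sim$R, seed = sim$seed,
         spatial_layer = sim$spatial_layer, snr = sim$snr,
         layer_names = sim$graph$layer_names),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a simulated experiment bundle
#'
#' @param dir directory written by [export_simulation()].
#' @return a `sim_truth`.
#' @export
read_simulation <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop_io(paste0("config not found: ", cfg_path))
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  coords <- read_coords(file.path(dir, "coords.csv"))
  z_true <- unname(read_labels(file.path(dir, "true_labels.csv")))
  theta_true <- as.matrix(read.csv(file.path(dir, "theta_true.csv")))
  dimnames(theta_true) <- NULL
  paths <- file.path(dir, paste0("edges_", cfg$layer_names, ".tsv"))
  graph <- read_graph(paths, n_nodes = nrow(coords),
                      layer_names = cfg$layer_names,
                      spot_ids = rownames(coords))
  structure(list(coords = coords, z_true = z_true, theta_true = theta_true,
                 graph = graph, snr = cfg$snr, R = cfg$R, seed = cfg$seed,
                 setting = cfg$setting, spatial_layer = cfg$spatial_layer,
                 n_bands = as.integer(cfg$n_bands)),
            class = "sim_truth")
}
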