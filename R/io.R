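# Readers/writers for the delimited-text and MatrixMarket formats, plus the
# end-to-end pipeline driver.

#' Read a dataset bundle (counts + optional coordinates and labels)
#'
#' Counts come either from a delimited file (header row of gene names, first
#' column of cell ids) or a MatrixMarket triplet `<stem>.mtx` with
#' `<stem>_genes.tsv` / `<stem>_barcodes.tsv` sidecars. Coordinates are a
#' CSV with columns `cell_id,x,y[,z]`; labels a CSV with `cell_id,label`.
#' Cells x genes is the canonical orientation; when the row count does not
#' match the coordinate table but the column count does, the matrix is
#' transposed (set `orientation` to silence the auto-detection).
#'
#' @param counts path to the count matrix (.csv/.tsv or .mtx).
#' @param coords optional coordinates CSV path.
#' @param labels optional labels CSV path.
#' @param orientation `"auto"`, `"cells_by_genes"` or `"genes_by_cells"`.
#' @return list of class `dataset_bundle`: `expression` (cells x genes),
#'   `coordinates`, `labels`, `provenance` (paths and md5 checksums).
#' @export
read_bundle <- function(counts, coords = NULL, labels = NULL,
                        orientation = c("auto", "cells_by_genes",
                                        "genes_by_cells")) {
  orientation <- match.arg(orientation)
  paths <- c(counts = counts, coords = coords, labels = labels)
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)
  ext <- tolower(tools::file_ext(counts))
  if (ext == "mtx") {
    stem <- sub("\\.mtx$", "", counts)
    gf <- paste0(stem, "_genes.tsv"); bf <- paste0(stem, "_barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("MTX sidecars missing: expected ", gf, " and ", bf)
    M <- as.matrix(Matrix::readMM(counts))
    genes <- readLines(gf); cells <- readLines(bf)
    if (nrow(M) == length(cells) && ncol(M) == length(genes)) {
      dimnames(M) <- list(cells, genes)
    } else if (nrow(M) == length(genes) && ncol(M) == length(cells)) {
      M <- t(M); dimnames(M) <- list(cells, genes)
    } else stop("MTX dimensions do not match sidecar name files")
    X <- M
    paths <- c(paths, genes = gf, barcodes = bf)
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    df <- utils::read.table(counts, header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE)
    X <- as.matrix(df)
  }
  if (anyDuplicated(colnames(X))) stop("duplicate gene names in ", counts)
  if (anyDuplicated(rownames(X))) stop("duplicate cell ids in ", counts)

  coord_mat <- NULL
  if (!is.null(coords)) {
    cd <- utils::read.csv(coords)
    if (!all(c("cell_id", "x", "y") %in% names(cd)))
      stop("coordinates need columns cell_id,x,y[,z]")
    if (orientation == "auto" && nrow(X) != nrow(cd) && ncol(X) == nrow(cd))
      X <- t(X)
    if (orientation == "genes_by_cells") X <- t(X)
    if (nrow(cd) != nrow(X))
      stop("coordinate rows (", nrow(cd), ") do not match cells (", nrow(X), ")")
    m <- match(rownames(X), cd$cell_id)
    if (anyNA(m)) stop("coordinate cell ids do not cover all cells")
    cols <- intersect(c("x", "y", "z"), names(cd))
    coord_mat <- as.matrix(cd[m, cols, drop = FALSE])
    rownames(coord_mat) <- rownames(X)
  } else if (orientation == "genes_by_cells") {
    X <- t(X)
  }
  lab <- NULL
  if (!is.null(labels)) {
    ld <- utils::read.csv(labels)
    if (!all(c("cell_id", "label") %in% names(ld)))
      stop("labels need columns cell_id,label")
    m <- match(rownames(X), ld$cell_id)
    if (anyNA(m)) stop("label cell ids do not cover all cells")
    lab <- stats::setNames(as.character(ld$label[m]), rownames(X))
  }
  structure(list(expression = X, coordinates = coord_mat, labels = lab,
                 provenance = list(paths = paths,
                                   md5 = tools::md5sum(unname(paths)))),
            class = "dataset_bundle")
}

#' Write a dataset bundle to disk
#'
#' @param expr cells x genes matrix.
#' @param dir output directory (created if needed).
#' @param coords optional coordinate matrix (columns x, y[, z]).
#' @param labels optional per-cell label vector.
#' @param format `"tsv"`, `"csv"` or `"mtx"` for the count matrix.
#' @param stem file stem (default `"counts"`).
#' @return invisibly, the paths written.
#' @export
write_bundle <- function(expr, dir, coords = NULL, labels = NULL,
                         format = c("tsv", "csv", "mtx"), stem = "counts") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) rownames(expr) <- paste0("cell", seq_len(nrow(expr)))
  paths <- character(0)
  if (format == "mtx") {
    f <- file.path(dir, paste0(stem, ".mtx"))
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), f)
    writeLines(colnames(expr), file.path(dir, paste0(stem, "_genes.tsv")))
    writeLines(rownames(expr), file.path(dir, paste0(stem, "_barcodes.tsv")))
    paths <- c(paths, f)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    f <- file.path(dir, paste0(stem, ".", format))
    utils::write.table(data.frame(cell_id = rownames(expr), expr,
                                  check.names = FALSE),
                       f, sep = sep, quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(coords)) {
    f <- file.path(dir, "coordinates.csv")
    utils::write.csv(data.frame(cell_id = rownames(expr), coords,
                                check.names = FALSE), f, row.names = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(labels)) {
    f <- file.path(dir, "labels.csv")
    utils::write.csv(data.frame(cell_id = rownames(expr), label = labels),
                     f, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Run the end-to-end pipeline from a configuration file
#'
#' Stages: read (or simulate) the paired datasets, compute spatial COVET,
#' train ENVI, impute the full transcriptome for spatial cells, infer COVET
#' for dissociated cells, and write evaluation tables. Every artifact is
#' listed in a JSON manifest that records the configuration file's md5
#' hash, the package version, the seed and all parameters.
#'
#' The configuration is YAML with keys:
#' `out_dir`; either `synthetic: {preset, seed}` or `spatial: {counts,
#' coords}` plus `single_cell: {counts}`; optional `covet: {k, log1p}` and
#' `envi:` (any [envi_config()] argument).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  need <- function(key) {
    if (is.null(config[[key]]))
      stop("pipeline config is missing required key '", key, "'")
    config[[key]]
  }
  out_dir <- need("out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    tissue <- stage("simulate", synthetic_preset(
      preset = if (is.null(syn$preset)) "small" else syn$preset,
      seed = if (is.null(syn$seed)) 1 else syn$seed))
    sc <- stage("simulate", dissociate(
      tissue, seed = if (is.null(syn$seed)) 1 else syn$seed))
    st_counts <- tissue$counts_full[, tissue$panel]
    st_coords <- tissue$coords
    sc_counts <- sc$counts
    stage("write-input", write_bundle(st_counts, file.path(out_dir, "spatial"),
                                      coords = st_coords,
                                      labels = tissue$zone))
  } else {
    sp <- need("spatial"); sc_cfg <- need("single_cell")
    b_st <- stage("read", read_bundle(sp$counts, coords = sp$coords,
                                      labels = sp$labels))
    b_sc <- stage("read", read_bundle(sc_cfg$counts))
    st_counts <- b_st$expression; st_coords <- b_st$coordinates
    sc_counts <- b_sc$expression
  }
  cv <- config$covet
  k <- if (is.null(cv$k)) 8 else cv$k
  covet <- stage("covet", compute_covet(
    st_counts, st_coords, k = k,
    log1p = !is.null(cv$log1p) && isTRUE(cv$log1p)))
  utils::write.csv(pairwise_aot(covet),
                   file.path(out_dir, "aot_distances.csv"))

  envi_args <- if (is.null(config$envi)) list() else config$envi
  cfg <- do.call(envi_config, envi_args)
  model <- stage("train", envi_train(sc_counts, st_counts, st_coords,
                                     config = cfg, k = k))
  imputed <- stage("impute", envi_impute(model))
  inferred <- stage("infer-covet", envi_infer_covet(model))
  utils::write.table(data.frame(cell_id = rownames(imputed), imputed,
                                check.names = FALSE),
                     file.path(out_dir, "imputed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(t(apply(inferred, 3, as.numeric)),
                   file.path(out_dir, "inferred_covet_sqrt_flat.csv"),
                   row.names = FALSE)
  eval_tab <- stage("evaluate", evaluate_imputation(
    st_counts, imputed[, colnames(st_counts), drop = FALSE], st_coords, k = k))
  utils::write.csv(eval_tab, file.path(out_dir, "imputation_eval.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("covetenvi")),
    config = config,
    config_md5 = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path)) else NA,
    artifacts = c("aot_distances.csv", "imputed.tsv",
                  "inferred_covet_sqrt_flat.csv", "imputation_eval.csv"),
    final_loss = model$loss[length(model$loss)])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
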