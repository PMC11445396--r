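# Paired synthetic tissue + dissociated sample generator. The tissue plants
# exactly the statistical structures the niche methods exploit: a spatially
# smooth gradient gene block, a ligand block with cell-to-cell variability,
# and a receiver ("niche coupling") block whose expression follows the mean
# ligand signal of the 8 spatial neighbours with a zone-dependent strength,
# creating genuine cross-cell covariance that differs between zones.

#' Simulate a spatial tissue with niche-coupled expression
#'
#' Cells sit on a jittered square grid. Zones are horizontal bands (along
#' the y axis); a smooth expression gradient runs along the x axis so it is
#' orthogonal to zone identity. Cell types are assigned uniformly at random.
#' Gene log-means combine a baseline, per-type marker effects, noisy ligand
#' genes (each zone enriched for its own ligand subset, scaled by the
#' coupling), gradient genes with staggered sigmoidal domains along x (the
#' shape of axial patterning series, so each position has a distinct
#' signature), and a receiver block shifted by `coupling_strength *
#' zone_coefficient * (standardized mean ligand signal of the cell's k = 8
#' spatial neighbours)`. Zone coefficients run from 0 (uncoupled) to 1
#' (fully coupled), so with `coupling_strength = 0` the zones are
#' statistically identical and niche-based classifiers operate at chance,
#' while strong coupling makes zone niches separable through both their
#' ligand programs and their ligand-receiver covariance. Spatial counts are
#' Poisson draws from the log-means.
#'
#' @param n_cells number of cells (at least 64).
#' @param n_types number of cell types.
#' @param n_zones number of spatial zones.
#' @param g_full total number of genes (the dissociated modality sees all).
#' @param g_panel imaged panel size (first `g_panel` genes; must hold the
#'   marker, ligand, receiver and gradient blocks: `n_types + 12` genes).
#' @param coupling_strength niche coupling amplitude (log scale).
#' @param gradient_amp amplitude of the gradient block (log scale).
#' @param noise per-cell log-normal noise SD.
#' @param seed RNG seed.
#' @return object of class `synthetic_tissue`: `coords`, `zone`,
#'   `cell_type`, `gradient` (in [0,1]), `counts_full`, `panel` (gene
#'   names), `log_mean` (ground-truth log-means) and `blocks` (gene roles).
#' @export
simulate_tissue <- function(n_cells = 512, n_types = 3, n_zones = 2,
                            g_full = 30, g_panel = 20,
                            coupling_strength = 1.5, gradient_amp = 1.5,
                            noise = 0.5, seed = 1) {
  if (n_cells < 64) stop("n_cells must be at least 64")
  if (g_panel > g_full) stop("g_panel cannot exceed g_full")
  if (g_panel < n_types + 12)
    stop("g_panel must be at least n_types + 12 to hold all gene blocks")
  set.seed(seed)
  side <- ceiling(sqrt(n_cells))
  grid <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n_cells), ]
  coords <- as.matrix(grid) + matrix(stats::runif(2 * n_cells, -0.3, 0.3),
                                     n_cells, 2)
  colnames(coords) <- c("x", "y")
  gradient <- (coords[, "x"] - min(coords[, "x"])) /
    (max(coords[, "x"]) - min(coords[, "x"]))
  zone <- as.integer(cut(coords[, "y"], breaks = n_zones, labels = FALSE))
  cell_type <- sample.int(n_types, n_cells, replace = TRUE)

  genes <- c(paste0("mk", seq_len(n_types)),
             paste0("lig", 1:4), paste0("rec", 1:4), paste0("grd", 1:4),
             paste0("hk", seq_len(g_panel - n_types - 12)))
  if (g_full > g_panel) genes <- c(genes, paste0("ext", seq_len(g_full - g_panel)))
  blocks <- list(marker = paste0("mk", seq_len(n_types)),
                 ligand = paste0("lig", 1:4), receiver = paste0("rec", 1:4),
                 gradient = paste0("grd", 1:4))

  logmu <- matrix(log(2), n_cells, g_full, dimnames = list(NULL, genes))
  for (t in seq_len(n_types))
    logmu[cell_type == t, blocks$marker[t]] <-
      logmu[cell_type == t, blocks$marker[t]] + 2
  # ligand genes: noisy and cell-type-tilted; each zone is enriched for its
  # own subset of ligands with strength proportional to the coupling, so
  # zones are distinct niche programs of equal magnitude (and with
  # coupling_strength = 0 all zones are statistically identical)
  zone_coef <- if (n_zones == 1) 1 else (zone - 1) / (n_zones - 1)
  lig_zone <- rep_len(seq_len(n_zones), length(blocks$ligand))
  for (j in seq_along(blocks$ligand)) {
    tilt <- 0.5 * (cell_type == (j - 1) %% n_types + 1)
    logmu[, blocks$ligand[j]] <- logmu[, blocks$ligand[j]] + tilt +
      0.5 * coupling_strength * (zone == lig_zone[j]) +
      stats::rnorm(n_cells, 0, 0.8)
  }
  # gradient genes: staggered sigmoidal domains along x (nested axial
  # domains, as for Hox-like series) so niches at different positions have
  # distinct expression signatures rather than mirror-symmetric deviations
  centers <- seq(0.15, 0.85, length.out = length(blocks$gradient))
  for (j in seq_along(blocks$gradient))
    logmu[, blocks$gradient[j]] <- logmu[, blocks$gradient[j]] +
      gradient_amp / (1 + exp(-(gradient - centers[j]) / 0.2))
  # receiver genes: coupled to the neighbour-mean ligand signal, with a
  # zone-dependent coefficient in [0, 1]
  niche <- build_niche_index(coords, k = 8)
  lig_signal <- rowMeans(logmu[, blocks$ligand, drop = FALSE])
  nb_signal <- vapply(niche$neighbors, function(nb) mean(lig_signal[nb]),
                      numeric(1))
  nb_signal <- as.numeric(scale(nb_signal))
  for (j in seq_along(blocks$receiver))
    logmu[, blocks$receiver[j]] <- logmu[, blocks$receiver[j]] +
      coupling_strength * zone_coef * nb_signal
  logmu <- logmu + matrix(stats::rnorm(n_cells * g_full, 0, noise),
                          n_cells, g_full)
  counts <- matrix(stats::rpois(n_cells * g_full, exp(logmu)),
                   n_cells, g_full, dimnames = list(NULL, genes))
  rownames(counts) <- rownames(logmu) <- paste0("cell", seq_len(n_cells))
  rownames(coords) <- rownames(counts)
  structure(list(coords = coords, zone = zone, cell_type = cell_type,
                 gradient = gradient, counts_full = counts,
                 panel = genes[seq_len(g_panel)], log_mean = logmu,
                 blocks = blocks, seed = seed),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat("synthetic tissue:", nrow(x$counts_full), "cells,",
      ncol(x$counts_full), "genes (", length(x$panel), "imaged ),",
      length(unique(x$zone)), "zones\n")
  invisible(x)
}

#' Preset synthetic tissues
#'
#' * `small`: a compact tissue for smoke tests.
#' * `gradient`: a strong expression gradient along x with mild coupling,
#'   for recovering the planted axis from COVET diffusion components.
#' * `archetypes`: two zones, one uncoupled and one strongly niche-coupled,
#'   giving two well-separated niche archetypes for AOT classification.
#'
#' @param preset one of `"small"`, `"gradient"`, `"archetypes"`.
#' @param seed RNG seed.
#' @return a [simulate_tissue()] result.
#' @export
synthetic_preset <- function(preset = c("small", "gradient", "archetypes"),
                             seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    small = simulate_tissue(n_cells = 256, g_full = 30, g_panel = 20,
                            seed = seed),
    gradient = simulate_tissue(n_cells = 576, n_types = 1, g_full = 30,
                               g_panel = 20, coupling_strength = 0,
                               gradient_amp = 4, noise = 0.4, seed = seed),
    archetypes = simulate_tissue(n_cells = 512, n_zones = 2, g_full = 30,
                                 g_panel = 20, coupling_strength = 2.5,
                                 gradient_amp = 0.5, noise = 0.4, seed = seed))
}

#' Dissociate a synthetic tissue into a single-cell sample
#'
#' Resamples counts for every gene (the full transcriptome) from the
#' tissue's ground-truth log-means with negative binomial noise, per-cell
#' library-size variation and optional dropout, emulating the dissociated
#' modality's overdispersion and sparsity. Coordinates are discarded;
#' ground-truth labels ride along in a sidecar for evaluation only.
#'
#' @param tissue a [simulate_tissue()] result.
#' @param dropout_rate probability of zeroing any entry, in [0, 1).
#' @param dispersion negative binomial size parameter (`Inf` = Poisson).
#' @param library_scale SD of the log-normal per-cell library factor.
#' @param seed RNG seed.
#' @return list with `counts` (cells x `g_full`) and `meta` (tibble of
#'   zone, cell type and gradient ground truth).
#' @export
dissociate <- function(tissue, dropout_rate = 0.1, dispersion = 2,
                       library_scale = 0.3, seed = 1) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate in [0, 1)")
  set.seed(seed)
  mu <- exp(tissue$log_mean)
  n <- nrow(mu); g <- ncol(mu)
  lib <- exp(stats::rnorm(n, 0, library_scale))
  mu <- mu * lib
  counts <- if (is.infinite(dispersion))
    matrix(stats::rpois(n * g, mu), n, g)
  else
    matrix(stats::rnbinom(n * g, size = dispersion, mu = mu), n, g)
  if (dropout_rate > 0) {
    drop <- matrix(stats::runif(n * g) < dropout_rate, n, g)
    counts[drop] <- 0L
  }
  dimnames(counts) <- dimnames(tissue$counts_full)
  rownames(counts) <- paste0("sc_", rownames(counts))
  list(counts = counts,
       meta = tibble::tibble(cell_id = rownames(counts),
                             zone = tissue$zone,
                             cell_type = tissue$cell_type,
                             gradient = tissue$gradient))
}

#' Assign imaged-panel genes to cross-validation folds
#'
#' @param tissue a [simulate_tissue()] result (or any object with a `panel`
#'   character vector).
#' @param folds number of folds (default 5).
#' @param seed RNG seed.
#' @return named integer vector: fold of every panel gene; folds partition
#'   the panel.
#' @export
make_imputation_task <- function(tissue, folds = 5, seed = 1) {
  panel <- if (is.list(tissue)) tissue$panel else tissue
  if (folds > length(panel)) stop("more folds than panel genes")
  set.seed(seed)
  f <- sample(rep(seq_len(folds), length.out = length(panel)))
  names(f) <- panel
  f
}

#' Evaluate imputed expression against ground truth
#'
#' Per-gene Pearson correlation of `log(x + 0.1)`-transformed profiles and
#' the spatially aware [mssi()] between truth and prediction.
#'
#' @param truth,pred cells x genes nonnegative matrices with matching
#'   column names.
#' @param coords spatial coordinates (ignored if `pyramid` given).
#' @param k graph neighbourhood size for MSSI.
#' @param pyramid optional precomputed [build_pyramid()].
#' @return tibble with columns `gene`, `pearson`, `mssi`.
#' @export
evaluate_imputation <- function(truth, pred, coords = NULL, k = 8,
                                pyramid = NULL) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  genes <- intersect(colnames(truth), colnames(pred))
  if (length(genes) == 0) stop("no shared genes to evaluate")
  if (is.null(pyramid)) pyramid <- build_pyramid(coords, k = k)
  pe <- vapply(genes, function(g)
    stats::cor(log(truth[, g] + 0.1), log(pred[, g] + 0.1)), numeric(1))
  ms <- vapply(genes, function(g)
    mssi(truth[, g], pred[, g], pyramid = pyramid), numeric(1))
  tibble::tibble(gene = genes, pearson = unname(pe), mssi = unname(ms))
}
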