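# Downstream procedures on COVET space: diffusion components, AOT k-NN
# label transfer, niche composition regression, expression-vs-environment
# concordance and batch-silhouette integration scoring.

flatten_sqrt <- function(x) {
  if (inherits(x, "covet_tensor")) x <- x$sigma_sqrt[, , !x$empty, drop = FALSE]
  if (is.array(x) && length(dim(x)) == 3) t(apply(x, 3, as.numeric))
  else as.matrix(x)
}

#' Diffusion components of a feature matrix
#'
#' Builds a k-nearest-neighbour graph on the rows of `features`, converts it
#' to an affinity matrix with an adaptive Gaussian kernel (per-point
#' bandwidth = distance to the `adaptive_k`-th neighbour, scaled by `width`),
#' symmetrizes by averaging with the transpose, and computes the eigenvectors
#' of the degree-normalized operator `D^-1 A`, ordered by eigenvalue
#' magnitude. The trivial constant eigenvector (eigenvalue 1) is dropped, so
#' component 1 is the leading non-trivial direction. Signs are fixed so each
#' component correlates non-negatively with the first input feature column
#' (falling back to a positive first loading).
#'
#' Flattened COVET square roots are the intended input: squared Euclidean
#' distance on them equals the AOT distance, so these are diffusion
#' components of COVET space.
#'
#' @param features n x d numeric matrix (e.g. flattened COVET square roots),
#'   or a `covet_tensor` (flattened automatically).
#' @param n_components number of components to return.
#' @param knn graph neighbourhood size (default 30).
#' @param adaptive_k neighbour index used for the adaptive bandwidth
#'   (default 10).
#' @param width multiplicative bandwidth scale (default 1).
#' @return object of class `diffusion_result`: list with `components`
#'   (n x m; rows outside the largest connected component are `NA` with a
#'   warning) and `eigenvalues`.
#' @export
diffusion_components <- function(features, n_components = 10, knn = 30,
                                 adaptive_k = 10, width = 1) {
  X <- flatten_sqrt(features)
  n <- nrow(X)
  if (n <= n_components) stop("need more observations than components")
  knn <- min(knn, n - 1)
  adaptive_k <- min(adaptive_k, knn)
  D <- as.matrix(stats::dist(X))
  sigma <- apply(D, 1, function(row) sort(row[-which.min(row)])[adaptive_k])
  sigma <- pmax(sigma * width, 1e-12)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    nb <- ord[ord != i][seq_len(knn)]
    A[i, nb] <- exp(-(D[i, nb] / sigma[i])^2)
  }
  A <- (A + t(A)) / 2
  comp <- graph_components(A > 0)
  keep <- comp == which.max(tabulate(comp))
  if (!all(keep))
    warning("graph is disconnected; components computed on the largest ",
            "connected component (", sum(keep), "/", n, " cells)")
  Ak <- A[keep, keep, drop = FALSE]
  deg <- rowSums(Ak)
  di <- 1 / sqrt(deg)
  S <- di * t(di * Ak)                     # D^-1/2 A D^-1/2, similar to D^-1 A
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- di * e$vectors[, ord, drop = FALSE]   # right eigenvectors of D^-1 A
  # drop the trivial stationary direction (eigenvalue 1, constant vector)
  vals <- vals[-1]
  vecs <- vecs[, -1, drop = FALSE]
  m <- min(n_components, ncol(vecs))
  out <- matrix(NA_real_, n, m)
  ref <- X[keep, 1]
  for (j in seq_len(m)) {
    v <- vecs[, j]
    cr <- suppressWarnings(stats::cor(v, ref))
    flip <- if (is.finite(cr) && cr != 0) cr < 0 else v[which.max(abs(v))] < 0
    out[keep, j] <- if (flip) -v else v
  }
  structure(list(components = out, eigenvalues = vals[seq_len(m)]),
            class = "diffusion_result")
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' AOT k-nearest-neighbour label transfer
#'
#' Classifies each query niche by majority vote among the `k` AOT-nearest
#' training niches (squared Euclidean distance between flattened COVET
#' square roots). Ties are broken in favour of the tied class with the
#' smallest summed distance, then alphabetically, so the result is
#' deterministic.
#'
#' @param train_sqrt training COVET square roots (`covet_tensor`, g x g x n
#'   array, or pre-flattened n x g^2 matrix).
#' @param labels training labels (length n).
#' @param test_sqrt query square roots in the same format.
#' @param k number of neighbours (default 5).
#' @return character vector of predicted labels.
#' @export
aot_knn_label_transfer <- function(train_sqrt, labels, test_sqrt, k = 5) {
  Xtr <- flatten_sqrt(train_sqrt)
  Xte <- flatten_sqrt(test_sqrt)
  labels <- as.character(labels)
  if (length(labels) != nrow(Xtr)) stop("labels must match training rows")
  if (k > nrow(Xtr)) stop("k exceeds the training set size")
  # squared Euclidean cross-distances
  cross <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  apply(cross, 1, function(drow) {
    ord <- order(drow, seq_along(drow))[seq_len(k)]
    votes <- labels[ord]
    tab <- table(votes)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) {
      sums <- vapply(best, function(b) sum(drow[ord][votes == b]), numeric(1))
      best <- best[order(sums, best)][1]
    }
    best
  })
}

#' Niche cell-type composition and its k-NN regression from COVET space
#'
#' Counts the cell types among each spatial cell's niche neighbours (so each
#' composition vector sums to the niche size, 8 under defaults), then
#' predicts the composition of query niches as the average composition of
#' their `k_reg` AOT-nearest spatial cells.
#'
#' @param st_labels cell-type labels for all spatial cells.
#' @param niche a [build_niche_index()] result for the spatial cells
#'   (k = 8 default construction).
#' @param covet_sqrt_st spatial COVET square roots (any format accepted by
#'   [aot_knn_label_transfer()]).
#' @param covet_sqrt_query query square roots; defaults to the spatial set.
#' @param k_reg regression neighbourhood (default 5).
#' @param normalize return fractions summing to 1 instead of counts.
#' @return matrix, queries x cell types.
#' @export
niche_composition <- function(st_labels, niche, covet_sqrt_st,
                              covet_sqrt_query = NULL, k_reg = 5,
                              normalize = FALSE) {
  st_labels <- as.character(st_labels)
  if (anyNA(st_labels)) stop("all spatial cells must be labeled")
  types <- sort(unique(st_labels))
  M <- matrix(unlist(lapply(niche$neighbors, function(nb)
    as.numeric(table(factor(st_labels[nb], levels = types))))),
    ncol = length(types), byrow = TRUE, dimnames = list(NULL, types))
  if (is.null(covet_sqrt_query)) return(if (normalize) M / rowSums(M) else M)
  Xtr <- flatten_sqrt(covet_sqrt_st)
  Xte <- flatten_sqrt(covet_sqrt_query)
  if (nrow(Xtr) != nrow(M)) stop("COVET set and label set disagree in size")
  cross <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  out <- t(apply(cross, 1, function(drow) {
    ord <- order(drow, seq_along(drow))[seq_len(k_reg)]
    colMeans(M[ord, , drop = FALSE])
  }))
  colnames(out) <- types
  if (normalize) out / rowSums(out) else out
}

#' Expression-vs-environment concordance (mean adjusted Rand index)
#'
#' Clusters cells by log expression and, independently, by flattened COVET
#' square roots, with k-means restarted `restarts` times on each side
#' (seeds `seed .. seed + restarts - 1`), and returns the mean adjusted Rand
#' index over all `restarts^2` pairings of an expression clustering with an
#' environment clustering.
#'
#' @param expr cells x genes nonnegative expression (log1p applied
#'   internally).
#' @param covet_sqrt COVET square roots for the same cells.
#' @param n_clusters k-means k (default 5).
#' @param restarts restarts per side (default 10, i.e. 100 ARIs).
#' @param seed base RNG seed.
#' @return list with `mean_ari` and the full `ari` matrix.
#' @export
expression_environment_concordance <- function(expr, covet_sqrt,
                                               n_clusters = 5, restarts = 10,
                                               seed = 1) {
  X1 <- log1p(as.matrix(expr))
  X2 <- flatten_sqrt(covet_sqrt)
  if (nrow(X1) < n_clusters) stop("fewer cells than clusters")
  run <- function(X, s) {
    set.seed(s)
    stats::kmeans(X, centers = n_clusters, nstart = 1, iter.max = 50)$cluster
  }
  cl1 <- lapply(seq_len(restarts), function(r) run(X1, seed + r - 1))
  cl2 <- lapply(seq_len(restarts), function(r) run(X2, seed + r - 1))
  ari <- matrix(0, restarts, restarts)
  for (a in seq_len(restarts))
    for (b in seq_len(restarts))
      ari[a, b] <- mclust::adjustedRandIndex(cl1[[a]], cl2[[b]])
  list(mean_ari = mean(ari), ari = ari)
}

#' Batch average silhouette width of a latent embedding
#'
#' Integration score in [0, 1]: the latent is compressed to its top 10
#' principal components; within each cell type present in at least two
#' modalities, the silhouette coefficient of the modality labels is computed
#' and each cell contributes `1 - |s_i|`; per-type means are averaged. A
#' score near 1 means modalities are perfectly interleaved within cell
#' types; near 0 means they separate.
#'
#' @param latent n x d latent matrix (rows = cells from both modalities).
#' @param modality per-cell modality (batch) labels.
#' @param cell_type per-cell type labels.
#' @param n_pcs principal components to keep (default 10).
#' @return list with `score` and per-type scores `by_type`.
#' @export
batch_asw <- function(latent, modality, cell_type, n_pcs = 10) {
  latent <- as.matrix(latent)
  modality <- as.character(modality); cell_type <- as.character(cell_type)
  if (length(unique(modality)) < 2) stop("need at least two modalities")
  n_pcs <- min(n_pcs, ncol(latent), nrow(latent) - 1)
  pcs <- stats::prcomp(latent, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  by_type <- c()
  for (ct in sort(unique(cell_type))) {
    idx <- which(cell_type == ct)
    mods <- modality[idx]
    if (length(unique(mods)) < 2) {
      warning("cell type '", ct, "' present in a single modality; excluded")
      next
    }
    sil <- cluster::silhouette(as.integer(factor(mods)),
                               stats::dist(pcs[idx, , drop = FALSE]))
    by_type[ct] <- mean(1 - abs(sil[, "sil_width"]))
  }
  if (length(by_type) == 0) stop("no cell type spans two modalities")
  list(score = mean(by_type), by_type = by_type)
}
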