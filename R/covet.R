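#' Build a spatial niche index
#'
#' Identifies, for every cell, the set of cells forming its niche: either the
#' `k` spatially nearest cells (excluding the cell itself) or all cells within
#' a fixed `radius`. Distances are Euclidean in coordinate space; ties at equal
#' distance are broken by ascending cell index so results are reproducible
#' across platforms.
#'
#' @param coords numeric matrix of cell coordinates, cells x d (d = 2 or 3).
#' @param k niche size for `mode = "knn"` (default 8).
#' @param mode `"knn"` for a fixed number of neighbours, `"radius"` to take
#'   all cells within `radius`.
#' @param radius positive radius for `mode = "radius"`.
#' @return an object of class `niche_index`: a list with `neighbors` (per-cell
#'   integer vectors), `mode`, `k_or_radius` and `empty` (logical flag per
#'   cell, only ever `TRUE` in radius mode).
#' @export
build_niche_index <- function(coords, k = 8, mode = c("knn", "radius"),
                              radius = NULL) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (n < 2) stop("need at least two cells")
  d2 <- as.matrix(stats::dist(coords))^2
  if (mode == "knn") {
    k <- as.integer(k)
    if (k < 1) stop("k must be a positive integer")
    if (n <= k) stop("knn mode requires more cells than k (n > k)")
    neighbors <- lapply(seq_len(n), function(i) {
      ord <- order(d2[i, ], seq_len(n))   # ties broken by ascending index
      ord <- ord[ord != i]
      ord[seq_len(k)]
    })
    empty <- rep(FALSE, n)
    kr <- k
  } else {
    if (is.null(radius) || radius <= 0) stop("radius mode requires radius > 0")
    r2 <- radius^2
    neighbors <- lapply(seq_len(n), function(i) {
      j <- which(d2[i, ] <= r2 & seq_len(n) != i)
      j[order(d2[i, j], j)]
    })
    empty <- lengths(neighbors) == 0L
    kr <- radius
  }
  structure(list(neighbors = neighbors, mode = mode, k_or_radius = kr,
                 empty = empty),
            class = "niche_index")
}

#' Stack niche expression matrices
#'
#' For each cell i, collects the expression vectors of its niche members into
#' a niche matrix E_i (neighbours x genes), in neighbour-list order.
#'
#' @param expr cells x genes expression matrix with column names.
#' @param niche a [build_niche_index()] result aligned to `expr` rows.
#' @param gene_subset gene names to keep (default: all columns of `expr`).
#' @return an object of class `niche_tensor`: list with `E` (list of k x g
#'   matrices), `genes`, and the originating `niche`.
#' @export
build_niche_tensor <- function(expr, niche, gene_subset = NULL) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr))) colnames(expr) <- paste0("g", seq_len(ncol(expr)))
  if (is.null(gene_subset)) gene_subset <- colnames(expr)
  missing <- setdiff(gene_subset, colnames(expr))
  if (length(missing) > 0)
    stop("unknown gene identifier(s): ", paste(missing, collapse = ", "))
  if (length(niche$neighbors) != nrow(expr))
    stop("niche index and expression matrix disagree on cell count")
  X <- expr[, gene_subset, drop = FALSE]
  E <- lapply(niche$neighbors, function(j) X[j, , drop = FALSE])
  structure(list(E = E, genes = gene_subset, niche = niche),
            class = "niche_tensor")
}

#' Shifted covariance of a niche matrix
#'
#' Covariance of the rows of `E_i` computed around a fixed external reference
#' mean rather than the niche's own mean:
#' \deqn{\Sigma_i = \frac{1}{k}(E_i - \bar X)^\top (E_i - \bar X).}
#' Using the dataset-wide mean for every niche makes the resulting matrices
#' directly comparable while preserving symmetry and positive
#' semi-definiteness. When `global_mean` equals the niche's own column mean
#' this reduces to the classical (population) covariance of `E_i`.
#'
#' @param E_i k x g niche matrix.
#' @param global_mean length-g reference mean.
#' @return g x g symmetric PSD matrix.
#' @export
shifted_covariance <- function(E_i, global_mean) {
  E_i <- as.matrix(E_i)
  if (length(global_mean) != ncol(E_i))
    stop("global_mean length must match the number of genes")
  k <- nrow(E_i)
  if (k < 1) stop("niche must contain at least one cell")
  Z <- sweep(E_i, 2, global_mean, "-")
  crossprod(Z) / k
}

#' Symmetric PSD matrix square root
#'
#' Unique symmetric positive semi-definite square root via eigendecomposition:
#' eigenvalues in `[-tol, 0)` are treated as numerical noise and clipped to
#' zero; anything below `-tol` is rejected as genuinely non-PSD. The
#' tolerance is relative: it is scaled by the largest eigenvalue magnitude
#' (floored at 1) so matrices on count scales are treated consistently.
#'
#' @param A symmetric PSD matrix.
#' @param tol negative-eigenvalue tolerance (default 1e-8, relative).
#' @return symmetric PSD matrix B with `B %*% B` equal to `A` up to `tol`.
#' @export
matrix_sqrt_psd <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  thr <- tol * max(1, abs(e$values))
  if (any(e$values < -thr))
    stop("matrix is not PSD (eigenvalue ", format(min(e$values)),
         " below tolerance)")
  v <- sqrt(pmax(e$values, 0))
  B <- e$vectors %*% (v * t(e$vectors))
  (B + t(B)) / 2
}

#' Compute COVET niche covariance representations
#'
#' Full pipeline from expression + coordinates to per-cell shifted covariance
#' matrices and their symmetric PSD square roots. The reference mean is the
#' column mean of `expr` over all cells on the selected genes. Cells whose
#' radius-mode niche is empty are flagged and carry `NA` matrices; they are
#' skipped by [pairwise_aot()].
#'
#' @param expr cells x genes nonnegative expression matrix (counts or
#'   normalized values).
#' @param coords cells x d coordinates, same row order as `expr`.
#' @param k niche size (default 8).
#' @param gene_subset genes to use (default: all; `hvg = m` overrides).
#' @param hvg optional integer: use the `hvg` most variable genes instead of
#'   `gene_subset`.
#' @param log1p if `TRUE`, apply `log1p` to `expr` before anything else.
#' @param mode,radius passed to [build_niche_index()].
#' @param tol PSD tolerance forwarded to [matrix_sqrt_psd()].
#' @return an object of class `covet_tensor`: list with `sigma` and
#'   `sigma_sqrt` (g x g x n arrays), `global_mean`, `k`, `genes`,
#'   `cell_ids`, and `empty` (flag for excluded cells).
#' @export
compute_covet <- function(expr, coords, k = 8, gene_subset = NULL, hvg = NULL,
                          log1p = FALSE, mode = c("knn", "radius"),
                          radius = NULL, tol = 1e-8) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression must be nonnegative")
  if (is.null(colnames(expr))) colnames(expr) <- paste0("g", seq_len(ncol(expr)))
  if (log1p) expr <- log1p(expr)
  if (!is.null(hvg)) {
    v <- apply(expr, 2, stats::var)
    gene_subset <- colnames(expr)[order(v, decreasing = TRUE)[seq_len(min(hvg, ncol(expr)))]]
    gene_subset <- sort(gene_subset)
  }
  if (is.null(gene_subset)) gene_subset <- colnames(expr)
  niche <- build_niche_index(coords, k = k, mode = mode, radius = radius)
  nt <- build_niche_tensor(expr, niche, gene_subset)
  g <- length(gene_subset)
  n <- nrow(expr)
  global_mean <- colMeans(expr[, gene_subset, drop = FALSE])
  sigma <- array(NA_real_, c(g, g, n),
                 dimnames = list(gene_subset, gene_subset, rownames(expr)))
  sigma_sqrt <- sigma
  for (i in seq_len(n)) {
    if (niche$empty[i]) next
    S <- shifted_covariance(nt$E[[i]], global_mean)
    sigma[, , i] <- S
    sigma_sqrt[, , i] <- matrix_sqrt_psd(S, tol = tol)
  }
  structure(list(sigma = sigma, sigma_sqrt = sigma_sqrt,
                 global_mean = global_mean, k = niche$k_or_radius,
                 genes = gene_subset, cell_ids = rownames(expr),
                 empty = niche$empty, niche = niche),
            class = "covet_tensor")
}

#' @export
print.covet_tensor <- function(x, ...) {
  cat("COVET tensor:", dim(x$sigma)[3], "cells x", dim(x$sigma)[1],
      "genes (niche parameter ", x$k, ")\n", sep = " ")
  if (any(x$empty)) cat(sum(x$empty), "cells with empty niches (excluded)\n")
  invisible(x)
}

#' 2-Wasserstein (Frechet) distance between covariance matrices
#'
#' Closed-form squared optimal-transport distance between zero-mean Gaussians
#' with covariances `sigma_i`, `sigma_j`:
#' \deqn{\Delta = \mathrm{Tr}(\Sigma_i) + \mathrm{Tr}(\Sigma_j)
#'   - 2\,\mathrm{Tr}\left(\sqrt{\Sigma_i \Sigma_j}\right).}
#' The cross term is evaluated through the symmetric form
#' `sqrt(sqrt(Si) Sj sqrt(Si))` for numerical stability.
#'
#' @param sigma_i,sigma_j symmetric PSD matrices of equal size.
#' @param tol PSD tolerance.
#' @return nonnegative squared distance.
#' @export
frechet_distance <- function(sigma_i, sigma_j, tol = 1e-8) {
  A <- matrix_sqrt_psd(sigma_i, tol = tol)
  M <- A %*% sigma_j %*% A
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  d <- sum(diag(as.matrix(sigma_i))) + sum(diag(as.matrix(sigma_j))) -
    2 * sum(sqrt(pmax(ev, 0)))
  max(d, 0)
}

#' Approximate optimal-transport (AOT) distance
#'
#' Replaces the root-of-product term of the Frechet distance with the product
#' of the individual matrix square roots, which collapses to the squared
#' Frobenius distance between the roots:
#' \deqn{\Delta_{AOT} = \|\sqrt{\Sigma_i} - \sqrt{\Sigma_j}\|_2^2.}
#' Exact (equal to the Frechet distance) whenever the two covariances commute.
#' Inputs here are the square roots themselves, as produced by
#' [compute_covet()].
#'
#' @param sqrt_i,sqrt_j symmetric PSD square-root matrices of equal size.
#' @return nonnegative squared distance.
#' @export
aot_distance <- function(sqrt_i, sqrt_j) {
  if (!all(dim(sqrt_i) == dim(sqrt_j))) stop("shape mismatch")
  sum((sqrt_i - sqrt_j)^2)
}

#' Pairwise AOT distance matrix
#'
#' Flattens the per-cell COVET square roots into vectors and computes all
#' pairwise squared Euclidean distances; by the AOT identity this equals the
#' per-pair trace formula while costing only one matrix square root per cell.
#' Flagged (empty-niche) cells are excluded.
#'
#' @param covet a `covet_tensor` (or a g x g x n array of square roots).
#' @return n' x n' symmetric nonnegative matrix with zero diagonal and a
#'   `metric` attribute, n' the number of non-flagged cells; row/column names
#'   follow the cell ids.
#' @export
pairwise_aot <- function(covet) {
  S <- if (inherits(covet, "covet_tensor")) covet$sigma_sqrt else covet
  keep <- if (inherits(covet, "covet_tensor")) !covet$empty else rep(TRUE, dim(S)[3])
  V <- t(apply(S[, , keep, drop = FALSE], 3, as.numeric))
  D <- as.matrix(stats::dist(V))^2
  if (!is.null(dimnames(S)[[3]])) {
    rownames(D) <- colnames(D) <- dimnames(S)[[3]][keep]
  }
  attr(D, "metric") <- "aot"
  D
}

#' Bhattacharyya distance between covariance matrices
#'
#' Zero-mean Gaussian convention:
#' \deqn{D_B = \frac12 \ln\frac{\det((\Sigma_1+\Sigma_2)/2)}
#'   {\sqrt{\det\Sigma_1\,\det\Sigma_2}}.}
#' Provided as a reference metric for benchmarking against AOT; inputs that
#' are not strictly positive definite are regularized by adding `tol` to the
#' diagonal.
#'
#' @param sigma_i,sigma_j symmetric PSD matrices.
#' @param tol diagonal regularization.
#' @return nonnegative symmetric distance.
#' @export
bhattacharyya_distance <- function(sigma_i, sigma_j, tol = 1e-8) {
  g <- nrow(as.matrix(sigma_i))
  R <- diag(tol, g)
  s1 <- as.matrix(sigma_i) + R
  s2 <- as.matrix(sigma_j) + R
  ld <- function(M) {
    d <- determinant(M, logarithm = TRUE)
    if (d$sign <= 0) stop("matrix singular after regularization")
    as.numeric(d$modulus)
  }
  0.5 * (ld((s1 + s2) / 2) - 0.5 * (ld(s1) + ld(s2)))
}

#' AOT mean of a set of COVET matrices
#'
#' The Frechet/AOT barycenter proxy used to summarize a group of niches: the
#' matrix square of the arithmetic mean of the matrix square roots,
#' \deqn{\widehat{COVET} = \left(\frac1n \sum_i \sqrt{\Sigma_i}\right)^2.}
#'
#' @param x a `covet_tensor`, a g x g x n array, or a list of matrices.
#' @param is_sqrt set `FALSE` if `x` holds raw COVET matrices rather than
#'   their square roots (roots are then computed first).
#' @param tol PSD tolerance.
#' @return g x g PSD matrix.
#' @export
covet_mean <- function(x, is_sqrt = TRUE, tol = 1e-8) {
  if (inherits(x, "covet_tensor")) x <- x$sigma_sqrt[, , !x$empty, drop = FALSE]
  if (is.array(x) && length(dim(x)) == 3)
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  if (!is.list(x) || length(x) == 0) stop("need a nonempty set of matrices")
  if (!is_sqrt) x <- lapply(x, matrix_sqrt_psd, tol = tol)
  M <- Reduce(`+`, x) / length(x)
  M %*% M
}
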