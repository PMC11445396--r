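# Multiscale spectral similarity index: SSIM luminance/contrast/structure
# terms evaluated over a 5-level coarsening pyramid of the spatial cell
# graph and combined by a weighted geometric mean.

#' MS-SSIM scale weights
#'
#' The five exponents applied to the per-scale similarity factors,
#' `(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)`.
#' @export
mssi_weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

# one greedy heavy-edge coarsening step: contract the heaviest remaining
# edge's endpoints (union-find; previously merged groups stay eligible),
# halting once the group count reaches ceil(n/2) or edges run out. Returns
# the fine -> coarse membership, groups ordered by their smallest member.
coarsen_membership <- function(A) {
  n <- nrow(A)
  S <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  keep <- S@i < S@j
  ei <- S@i[keep] + 1L; ej <- S@j[keep] + 1L; w <- S@x[keep]
  ord <- order(-w, ei, ej)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  target <- ceiling(n / 2)
  groups <- n
  for (e in ord) {
    if (groups <= target) break
    ra <- find(ei[e]); rb <- find(ej[e])
    if (ra != rb) {
      parent[max(ra, rb)] <- min(ra, rb)
      groups <- groups - 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Build a 5-scale spatial graph pyramid
#'
#' Level 1 is the symmetrized k-nearest-neighbour graph of the cell
#' coordinates. Each subsequent level contracts the heaviest remaining edge
#' of the (weight-accumulated) adjacency until the node count halves —
#' unmerged nodes carry over — which respects connectivity: nodes in
#' different components are never pooled together. The pooling operator `C^s` maps level-s signals to level-(s+1)
#' signals by uniform averaging over merged nodes, so every row is a convex
#' weight vector and constant signals are fixed points.
#'
#' @param coords cells x d spatial coordinates.
#' @param k neighbourhood size of the level-1 graph (default 8, mirroring
#'   the COVET niche default).
#' @param levels number of scales (default 5).
#' @return object of class `graph_pyramid`: `graphs` (sparse adjacencies),
#'   `operators` (sparse pooling matrices, `levels - 1` of them),
#'   `memberships`, and `sizes`.
#' @export
build_pyramid <- function(coords, k = 8, levels = 5) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least two cells")
  k <- min(k, n - 1)
  d2 <- as.matrix(stats::dist(coords))^2
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))
    nb <- ord[ord != i][seq_len(k)]
    ii <- c(ii, rep(i, k)); jj <- c(jj, nb)
  }
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                            x = rep(1, 2 * length(ii)), dims = c(n, n))
  A@x[] <- 1                               # symmetrize as undirected union
  diag(A) <- 0
  A <- Matrix::drop0(A)
  graphs <- list(A)
  operators <- list()
  memberships <- list()
  for (s in seq_len(levels - 1)) {
    As <- graphs[[s]]
    ns <- nrow(As)
    if (Matrix::nnzero(As) == 0) {
      m <- seq_len(ns)          # nothing left to merge: carry all nodes over
    } else {
      m <- coarsen_membership(As)
    }
    nc <- max(m)
    P <- Matrix::sparseMatrix(i = m, j = seq_len(ns), x = 1, dims = c(nc, ns))
    C <- P / Matrix::rowSums(P)
    Ac <- P %*% As %*% Matrix::t(P)
    diag(Ac) <- 0
    Ac <- Matrix::drop0(Ac)
    operators[[s]] <- C
    memberships[[s]] <- m
    graphs[[s + 1]] <- Ac
  }
  structure(list(graphs = graphs, operators = operators,
                 memberships = memberships,
                 sizes = vapply(graphs, nrow, integer(1))),
            class = "graph_pyramid")
}

#' @export
print.graph_pyramid <- function(x, ...) {
  cat("graph pyramid, level sizes:", paste(x$sizes, collapse = " -> "), "\n")
  invisible(x)
}

#' Pool a per-node signal through a coarsening operator
#'
#' @param C coarsening operator (coarse x fine), e.g.
#'   `pyramid$operators[[s]]`.
#' @param x per-node signal (vector or fine x m matrix).
#' @return pooled signal at the coarse scale.
#' @export
pool_signal <- function(C, x) {
  x <- as.matrix(x)
  if (ncol(C) != nrow(x)) stop("operator and signal shapes do not match")
  out <- as.matrix(C %*% x)
  if (ncol(out) == 1) drop(out) else out
}

#' SSIM luminance, contrast and structure components
#'
#' For two equal-length nonnegative signals with means \eqn{\mu_x, \mu_y},
#' standard deviations \eqn{\sigma_x, \sigma_y} (population convention) and
#' covariance \eqn{\sigma_{xy}}, with `M` the joint maximum of the two
#' signals:
#' \deqn{l = \frac{2\mu_x\mu_y + C_1}{\mu_x^2+\mu_y^2 + C_1},\quad
#'  c = \frac{2\sigma_x\sigma_y + C_2}{\sigma_x^2+\sigma_y^2+C_2},\quad
#'  s = \frac{\sigma_{xy} + C_2/2}{\sigma_x\sigma_y + C_2/2}}
#' with \eqn{C_1 = (0.01 M)^2} and \eqn{C_2 = (0.03 M)^2}. The
#' `"as-printed"` luminance variant replaces the denominator constant
#' \eqn{C_1} with \eqn{0.01/M}, reproducing the formula exactly as printed
#' in the source description of the index; the standard constant is the
#' default because it makes the index exactly 1 for identical signals.
#'
#' A fully degenerate pair (joint maximum 0, i.e. both signals identically
#' zero) is treated as the limiting case of identical signals: all three
#' components are 1.
#'
#' @param x,y equal-length nonnegative numeric vectors.
#' @param M joint maximum (default `max(x, y)`).
#' @param luminance `"standard"` or `"as-printed"` (see Details).
#' @return list with components `l`, `c`, `s` and `M`.
#' @export
ssim_components <- function(x, y, M = NULL,
                            luminance = c("standard", "as-printed")) {
  luminance <- match.arg(luminance)
  if (length(x) != length(y)) stop("signals must have equal length")
  if (is.null(M)) M <- max(x, y)
  if (M <= 0) return(list(l = 1, c = 1, s = 1, M = 0))
  mx <- mean(x); my <- mean(y)
  vx <- max(mean(x^2) - mx^2, 0); vy <- max(mean(y^2) - my^2, 0)
  sx <- sqrt(vx); sy <- sqrt(vy)
  sxy <- mean(x * y) - mx * my
  C1 <- (0.01 * M)^2
  C2 <- (0.03 * M)^2
  lden <- if (luminance == "standard") mx^2 + my^2 + C1
          else mx^2 + my^2 + 0.01 / M
  list(l = (2 * mx * my + C1) / lden,
       c = (2 * sx * sy + C2) / (vx + vy + C2),
       s = (sxy + C2 / 2) / (sx * sy + C2 / 2),
       M = M)
}

#' Multiscale spectral similarity index
#'
#' Compares two per-cell expression profiles over a spatial cell graph.
#' Both signals are first normalized to [0, 1] by their own maxima (and not
#' re-normalized at coarser scales), then pooled through the graph pyramid.
#' Contrast and structure are evaluated at scales 1-4 and luminance at
#' scale 5, combined as
#' \deqn{\mathrm{MSSI} = l_5^{\alpha_5}\prod_{s=1}^{4}
#'   c_s^{\alpha_s} s_s^{\alpha_s}}
#' with the MS-SSIM weights [mssi_weights]. Negative structure terms are
#' clipped to 0, so anti-correlation at any scale drives the index to its
#' minimum of 0; identical signals score 1.
#'
#' @param x,y nonnegative per-cell signals aligned to `coords`.
#' @param coords spatial coordinates (ignored when `pyramid` is given).
#' @param k level-1 graph neighbourhood size (default 8).
#' @param pyramid optional precomputed [build_pyramid()] result (reuse it
#'   when scoring many gene pairs on the same tissue).
#' @param luminance forwarded to [ssim_components()].
#' @return a similarity in [0, 1].
#' @export
mssi <- function(x, y, coords = NULL, k = 8, pyramid = NULL,
                 luminance = c("standard", "as-printed")) {
  luminance <- match.arg(luminance)
  if (length(x) != length(y)) stop("signals must have equal length")
  if (any(x < 0) || any(y < 0)) stop("signals must be nonnegative")
  if (is.null(pyramid)) {
    if (is.null(coords)) stop("provide coords or a precomputed pyramid")
    pyramid <- build_pyramid(coords, k = k)
  }
  if (pyramid$sizes[1] != length(x))
    stop("pyramid was built for a different number of cells")
  if (max(x) > 0) x <- x / max(x)
  if (max(y) > 0) y <- y / max(y)
  n_scales <- length(pyramid$graphs)
  score <- 1
  for (s in seq_len(n_scales)) {
    comp <- ssim_components(x, y, luminance = luminance)
    a <- mssi_weights[s]
    if (s < n_scales) {
      score <- score * (comp$c^a) * (max(comp$s, 0)^a)
      x <- pool_signal(pyramid$operators[[s]], x)
      y <- pool_signal(pyramid$operators[[s]], y)
    } else {
      score <- score * (max(comp$l, 0)^a)
    }
  }
  min(max(score, 0), 1)
}

#' Per-gene MSSI table between two expression matrices
#'
#' Scores each column of `truth` against the matching column of `pred`
#' (matched by name when both are named) on a shared graph pyramid.
#'
#' @param truth,pred cells x genes nonnegative matrices.
#' @param coords spatial coordinates aligned to rows.
#' @param k graph neighbourhood size.
#' @param pyramid optional precomputed pyramid.
#' @param luminance forwarded to [mssi()].
#' @return a tibble with columns `gene` and `mssi`.
#' @export
mssi_table <- function(truth, pred, coords = NULL, k = 8, pyramid = NULL,
                       luminance = c("standard", "as-printed")) {
  luminance <- match.arg(luminance)
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (!is.null(colnames(truth)) && !is.null(colnames(pred))) {
    genes <- intersect(colnames(truth), colnames(pred))
    truth <- truth[, genes, drop = FALSE]
    pred <- pred[, genes, drop = FALSE]
  } else if (ncol(truth) != ncol(pred)) {
    stop("matrices must have matching genes")
  }
  if (is.null(pyramid)) pyramid <- build_pyramid(coords, k = k)
  genes <- colnames(truth)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(truth)))
  vals <- vapply(seq_len(ncol(truth)), function(j)
    mssi(truth[, j], pred[, j], pyramid = pyramid, luminance = luminance),
    numeric(1))
  tibble::tibble(gene = genes, mssi = vals)
}
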