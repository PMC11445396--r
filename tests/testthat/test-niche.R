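test_that("diffusion component 1 recovers a planted 1D gradient", {
  set.seed(2)
  g <- seq(0, 1, length.out = 80)
  X <- cbind(g, matrix(rnorm(80 * 4, 0, 0.05), 80))
  dc <- diffusion_components(X, n_components = 2)
  expect_gt(cor(dc$components[, 1], g, method = "spearman"), 0.95)
  # equivariance: permuting input rows permutes components identically
  perm <- sample(80)
  dcp <- diffusion_components(X[perm, ], n_components = 2)
  expect_equal(dcp$components[, 1], dc$components[perm, 1], tolerance = 1e-8)
})

test_that("diffusion on flattened COVET square roots matches diffusion under
explicit AOT geometry", {
  set.seed(14)
  n <- 60; g <- 4
  sq <- array(0, c(g, g, n))
  for (i in seq_len(n)) sq[, , i] <- matrix_sqrt_psd(rand_psd(g))
  V <- t(apply(sq, 3, as.numeric))
  # squared Euclidean on the flattened roots IS the AOT distance
  expect_equal(as.matrix(dist(V))^2, pairwise_aot(sq), tolerance = 1e-9,
               ignore_attr = TRUE)
  d1 <- diffusion_components(sq, n_components = 3)
  d2 <- diffusion_components(V, n_components = 3)
  expect_equal(d1$components, d2$components)
  # disconnected feature sets warn and fall back to the largest component
  far <- rbind(matrix(rnorm(40, 0, 0.1), 20),
               matrix(rnorm(10, 1e6, 0.1), 5))
  expect_warning(diffusion_components(far, n_components = 2, knn = 3),
                 "disconnected")
})

test_that("AOT label transfer is deterministic with fixed tie-breaking", {
  set.seed(15)
  g <- 3
  arch1 <- rand_psd(g); arch2 <- arch1 + diag(c(4, 0, 0))
  make_set <- function(center, n) {
    sq <- array(0, c(g, g, n))
    for (i in seq_len(n)) {
      E <- matrix(rnorm(g * 12), 12, g) %*% matrix_sqrt_psd(center)
      sq[, , i] <- matrix_sqrt_psd(crossprod(E) / 12)
    }
    sq
  }
  train <- array(c(make_set(arch1, 30), make_set(arch2, 30)), c(g, g, 60))
  labels <- rep(c("a", "b"), each = 30)
  test <- array(c(make_set(arch1, 20), make_set(arch2, 20)), c(g, g, 40))
  pred <- aot_knn_label_transfer(train, labels, test, k = 5)
  truth <- rep(c("a", "b"), each = 20)
  bacc <- mean(diag(prop.table(table(factor(pred, c("a", "b")), truth), 2)))
  expect_gt(bacc, 0.9)
  # identical query inherits the training label at k = 1
  expect_equal(aot_knn_label_transfer(train, labels,
                                      train[, , 1, drop = FALSE], k = 1),
               "a")
  # permuting the training labels permutes predictions consistently
  swap <- c(a = "b", b = "a")
  pred2 <- aot_knn_label_transfer(train, swap[labels], test, k = 5)
  expect_equal(unname(swap[pred]), unname(pred2))
  expect_error(aot_knn_label_transfer(train, labels, test, k = 100),
               "exceeds")
})

test_that("niche composition counts sum to the niche size and k = 1
regression returns a cell's own composition", {
  tis <- tiny_tissue()
  cv <- compute_covet(tis$counts_full[, tis$panel], tis$coords, k = 8,
                      log1p = TRUE)
  M <- niche_composition(tis$cell_type, cv$niche, cv)
  expect_true(all(rowSums(M) == 8))
  expect_equal(sort(colnames(M)), sort(as.character(unique(tis$cell_type))))
  own <- niche_composition(tis$cell_type, cv$niche, cv,
                           covet_sqrt_query = cv$sigma_sqrt[, , 3,
                                                            drop = FALSE],
                           k_reg = 1)
  expect_equal(unname(own[1, ]), unname(M[3, ]))
  Mn <- niche_composition(tis$cell_type, cv$niche, cv, cv, k_reg = 5,
                          normalize = TRUE)
  expect_equal(unname(rowSums(Mn)), rep(1, nrow(Mn)))
  # homogeneous tissue: all mass on the single type
  ones <- rep("t1", length(tis$cell_type))
  M1 <- niche_composition(ones, cv$niche, cv)
  expect_true(all(M1[, "t1"] == 8))
  expect_error(niche_composition(c(NA, tis$cell_type[-1]), cv$niche, cv),
               "labeled")
})

test_that("expression-environment concordance is ~1 for identical features
and ~0 for independent noise", {
  set.seed(16)
  centers <- matrix(rnorm(2 * 6, 0, 3), 2, 6)
  X <- exp(centers[rep(1:2, length.out = 100), ] +
             matrix(rnorm(100 * 6, 0, 0.15), 100, 6))
  same <- expression_environment_concordance(X, log1p(X), n_clusters = 2,
                                             restarts = 4, seed = 7)
  expect_gt(same$mean_ari, 0.99)
  expect_equal(dim(same$ari), c(4, 4))
  noise <- matrix(rnorm(100 * 6), 100, 6)
  null <- expression_environment_concordance(X, noise, n_clusters = 2,
                                             restarts = 4, seed = 7)
  expect_lt(abs(null$mean_ari), 0.1)
  expect_error(expression_environment_concordance(X[1:2, ], noise[1:2, ],
                                                  n_clusters = 5),
               "fewer cells")
})

test_that("batch silhouette scores mixed latents near 1 and separated ones
near 0, invariantly to rotation", {
  set.seed(17)
  n <- 120
  ct <- rep(c("A", "B"), each = n / 2)
  base <- matrix(rnorm(n * 12), n, 12) + 3 * cbind(ct == "A", matrix(0, n, 11))
  mod <- rep(c("st", "sc"), n / 2)
  mixed <- batch_asw(base, mod, ct)
  expect_gt(mixed$score, 0.8)
  sep <- base + 40 * cbind(matrix(0, n, 11), mod == "st")
  expect_lt(batch_asw(sep, mod, ct)$score, 0.2)
  Q <- qr.Q(qr(matrix(rnorm(144), 12)))
  expect_equal(batch_asw(base %*% Q, mod, ct)$score, mixed$score,
               tolerance = 1e-8)
  # a type observed in a single modality is excluded with a warning
  mod2 <- mod; mod2[ct == "B"] <- "st"
  expect_warning(out <- batch_asw(base, mod2, ct), "single modality")
  expect_named(out$by_type, "A")
})
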