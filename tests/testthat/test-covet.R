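test_that("niche index matches exhaustive distance sort and excludes self", {
  coords <- cbind(x = c(0, 1, 2, 3), y = 0)
  ni <- build_niche_index(coords, k = 2)
  expect_equal(ni$neighbors[[1]], c(2L, 3L))   # x=1 and x=2 closest to x=0
  expect_equal(ni$neighbors[[4]], c(3L, 2L))
  for (i in 1:4) expect_false(i %in% ni$neighbors[[i]])

  # deterministic tie-break by ascending index on an equidistant square
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  ni2 <- build_niche_index(sq, k = 2)
  expect_equal(ni2$neighbors[[1]], c(2L, 3L))

  expect_error(build_niche_index(coords, k = 4), "n > k")
  expect_error(build_niche_index(cbind(c(0, NA), 0), k = 1), "finite")
})

test_that("radius mode flags empty niches and ragged lists", {
  coords <- cbind(c(0, 1, 2, 10), 0)
  ni <- build_niche_index(coords, mode = "radius", radius = 1.5)
  expect_equal(lengths(ni$neighbors), c(1L, 2L, 1L, 0L))
  expect_equal(ni$empty, c(FALSE, FALSE, FALSE, TRUE))
  # radius below the minimum pairwise distance: all flagged
  ni0 <- build_niche_index(coords, mode = "radius", radius = 0.5)
  expect_true(all(ni0$empty))
})

test_that("niche tensor stacks neighbour expression rows in order", {
  coords <- cbind(c(0, 1, 2, 3), 0)
  expr <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2,
                 dimnames = list(NULL, c("a", "b")))
  nt <- build_niche_tensor(expr, build_niche_index(coords, k = 2))
  expect_equal(nt$E[[1]], expr[c(2, 3), ])
  expect_error(build_niche_tensor(expr, build_niche_index(coords, k = 2),
                                  "missing_gene"),
               "unknown gene")
})

test_that("shifted covariance follows the printed formula and reduces to the
classical covariance at the niche mean", {
  # g = 1, values {0, 2}, reference mean 1 -> ((0-1)^2 + (2-1)^2)/2 = 1
  expect_equal(shifted_covariance(matrix(c(0, 2)), 1)[1, 1], 1)
  # rows equal to the reference -> zero matrix
  E <- matrix(rep(c(3, 5), each = 4), 4, 2)
  expect_equal(shifted_covariance(E, c(3, 5)), matrix(0, 2, 2))
  # reference = niche mean -> population covariance
  set.seed(1)
  E <- matrix(rnorm(40), 8, 5)
  k <- nrow(E)
  expect_equal(shifted_covariance(E, colMeans(E)),
               stats::cov(E) * (k - 1) / k, tolerance = 1e-12)
})

test_that("matrix square root is symmetric PSD and reconstructs its input", {
  expect_equal(matrix_sqrt_psd(diag(2)), diag(2))
  expect_equal(matrix_sqrt_psd(diag(c(4, 9))), diag(c(2, 3)))
  set.seed(7)
  for (i in 1:5) {
    A <- rand_psd(6)
    B <- matrix_sqrt_psd(A)
    expect_equal(B, t(B))
    expect_lt(max(abs(B %*% B - A)), 1e-8)
  }
  bad <- diag(c(1, -1))
  expect_error(matrix_sqrt_psd(bad), "not PSD")
})

test_that("Frechet distance matches its closed forms", {
  S <- rand_psd(4)
  expect_equal(frechet_distance(S, S), 0, tolerance = 1e-10)
  # 1x1: (sqrt(a) - sqrt(b))^2
  expect_equal(frechet_distance(matrix(4), matrix(1)), 1)
  # diagonal: sum over genes of (sqrt(d) - sqrt(e))^2
  d <- c(1, 4, 9); e <- c(4, 1, 16)
  expect_equal(frechet_distance(diag(d), diag(e)),
               sum((sqrt(d) - sqrt(e))^2), tolerance = 1e-10)
})

test_that("AOT equals the trace formula and the Frechet distance on
commuting inputs", {
  set.seed(11)
  for (i in 1:10) {
    p <- rand_commuting_pair(6)
    expect_lt(abs(aot_distance(matrix_sqrt_psd(p$a), matrix_sqrt_psd(p$b)) -
                    frechet_distance(p$a, p$b)), 1e-10)
  }
  for (i in 1:10) {
    A <- rand_psd(5); B <- rand_psd(5)   # generic non-commuting pair
    expect_lt(abs(aot_distance(matrix_sqrt_psd(A), matrix_sqrt_psd(B)) -
                    aot_trace_oracle(A, B)), 1e-10)
  }
  A <- rand_psd(5)
  expect_equal(aot_distance(matrix_sqrt_psd(A), matrix_sqrt_psd(A)), 0)
  expect_error(aot_distance(diag(2), diag(3)), "mismatch")
})

test_that("pairwise AOT equals per-pair calls and the flatten identity", {
  set.seed(3)
  n <- 20; g <- 4
  sq <- array(0, c(g, g, n))
  for (i in seq_len(n)) sq[, , i] <- matrix_sqrt_psd(rand_psd(g))
  D <- pairwise_aot(sq)
  expect_equal(unname(diag(D)), rep(0, n))
  expect_equal(D, t(D))
  for (i in c(1, 5, 12)) for (j in c(3, 9, 20))
    expect_lt(abs(D[i, j] - aot_distance(sq[, , i], sq[, , j])), 1e-9)
  # flatten-then-squared-Euclidean path
  V <- t(apply(sq, 3, as.numeric))
  expect_equal(D, as.matrix(dist(V))^2, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("Bhattacharyya distance matches the zero-mean Gaussian closed form
and is symmetric", {
  expect_equal(bhattacharyya_distance(matrix(1), matrix(4)),
               0.5 * log(((1 + 4) / 2) / sqrt(4)), tolerance = 1e-6)
  S <- rand_psd(4)
  expect_equal(bhattacharyya_distance(S, S), 0, tolerance = 1e-6)
  A <- rand_psd(4); B <- rand_psd(4)
  expect_equal(bhattacharyya_distance(A, B), bhattacharyya_distance(B, A))
})

test_that("AOT mean is the matrix square of the mean square root", {
  expect_equal(covet_mean(list(matrix(1), matrix(3)))[1, 1], 4)
  A <- rand_psd(3)
  sA <- matrix_sqrt_psd(A)
  expect_equal(covet_mean(list(sA, sA)), A, tolerance = 1e-10)
  expect_equal(covet_mean(list(A), is_sqrt = FALSE), A, tolerance = 1e-8)
  expect_error(covet_mean(list()), "nonempty")
})

test_that("compute_covet produces PSD matrices; uniform tissue gives equal
matrices and mean-level niches give zeros", {
  set.seed(21)
  coords <- matrix(runif(100), 50, 2)
  expr <- matrix(rpois(250, 5), 50, 5,
                 dimnames = list(NULL, paste0("g", 1:5)))
  cv <- compute_covet(expr, coords, k = 8)
  min_eig <- apply(cv$sigma, 3, function(S)
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  expect_gt(min(min_eig), -1e-8)
  for (i in 1:50)
    expect_lt(max(abs(cv$sigma_sqrt[, , i] %*% cv$sigma_sqrt[, , i] -
                        cv$sigma[, , i])), 1e-8)
  # identical expression everywhere: every niche sits at the global mean
  uni <- matrix(3, 50, 5, dimnames = list(NULL, paste0("g", 1:5)))
  cvu <- compute_covet(uni, coords, k = 8)
  expect_equal(max(abs(cvu$sigma)), 0)
  expect_error(compute_covet(expr - 10, coords, k = 8), "nonnegative")
})

test_that("AOT ranks agree with brute-force Frechet on a Wishart ensemble", {
  set.seed(5)
  n <- 60; g <- 6
  sig <- lapply(seq_len(n), function(i) rand_psd(g))
  sq <- array(0, c(g, g, n))
  for (i in seq_len(n)) sq[, , i] <- matrix_sqrt_psd(sig[[i]])
  aot <- pairwise_aot(sq)
  fre <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    fre[i, j] <- fre[j, i] <- frechet_distance(sig[[i]], sig[[j]])
  up <- upper.tri(aot)
  expect_gt(cor(aot[up], fre[up], method = "spearman"), 0.9)
})
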