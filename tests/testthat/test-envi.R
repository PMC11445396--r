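tiny_cfg <- function(seed = 5, steps = 200) {
  envi_config(latent_dim = 12, hidden_layers = 2, hidden_width = 48,
              train_steps = steps, batch_size = 64, seed = seed)
}

tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tis <- tiny_tissue()
      sc <- dissociate(tis, seed = 43)
      cache <<- suppressMessages(
        envi_train(sc$counts, tis$counts_full[, tis$panel], tis$coords,
                   tiny_cfg()))
    }
    cache
  }
})

test_that("count log-pmfs normalize, match closed forms and reject bad
parameters", {
  # NB with r = 1 is geometric
  k <- 0:20
  expect_equal(nb_log_pmf(k, 1, 0.3), log((1 - 0.3)^k * 0.3))
  # hand value: r = 2, p = 0.5, k = 1 -> C(2,1) * 0.5 * 0.25 = 0.25
  expect_equal(exp(nb_log_pmf(1, 2, 0.5)), 0.25)
  # normalization by brute-force summation
  ks <- 0:3000
  expect_lt(abs(sum(exp(nb_log_pmf(ks, 2.7, 0.2))) - 1), 1e-6)
  expect_lt(abs(sum(exp(poisson_log_pmf(ks, 17.3))) - 1), 1e-8)
  expect_lt(abs(sum(exp(zinb_log_pmf(ks, 2.7, 0.2, 0.35))) - 1), 1e-6)
  # ZINB mixes a point mass at zero with the NB
  expect_equal(exp(zinb_log_pmf(0, 2, 0.4, 0.3)),
               0.3 + 0.7 * exp(nb_log_pmf(0, 2, 0.4)))
  expect_equal(zinb_log_pmf(3, 2, 0.4, 0.3),
               log(0.7) + nb_log_pmf(3, 2, 0.4))
  # NB expectation is r(1-p)/p
  expect_equal(sum(ks * exp(nb_log_pmf(ks, 2.7, 0.2))), 2.7 * 0.8 / 0.2,
               tolerance = 1e-6)
  expect_error(nb_log_pmf(1, 2, 1.5), "p must")
  expect_error(poisson_log_pmf(1, -1), "positive")
  # Poisson mode sits at floor(lambda)
  expect_equal(which.max(poisson_log_pmf(0:50, 7.6)) - 1, 7)
})

test_that("KL closed form matches a Monte-Carlo estimate", {
  set.seed(31)
  mu <- rnorm(4); sigma <- exp(rnorm(4, 0, 0.3))
  closed <- kl_diag_gaussian(mu, sigma)
  n <- 2e5
  z <- matrix(rnorm(n * 4), n, 4)
  x <- sweep(z, 2, sigma, "*"); x <- sweep(x, 2, mu, "+")
  lq <- rowSums(dnorm(x, matrix(mu, n, 4, byrow = TRUE),
                      matrix(sigma, n, 4, byrow = TRUE), log = TRUE))
  lp <- rowSums(dnorm(x, log = TRUE))
  mc <- mean(lq - lp)
  se <- sd(lq - lp) / sqrt(n)
  expect_lt(abs(closed - mc), 4 * se + 1e-3)
  expect_equal(kl_diag_gaussian(rep(0, 5), rep(1, 5)), 0)
  expect_error(kl_diag_gaussian(0, -1), "positive")
})

test_that("reparameterization is the deterministic affine map", {
  mu <- c(1, -2); sigma <- c(0.5, 2)
  expect_equal(reparameterize(mu, sigma, c(0, 0)), mu)
  expect_equal(reparameterize(mu, c(0, 0), c(5, -5)), mu)
  set.seed(12)
  draws <- replicate(10000, reparameterize(mu, sigma, rnorm(2)))
  expect_equal(rowMeans(draws), mu, tolerance = 0.1)
  expect_error(reparameterize(mu, sigma, 1), "shape")
})

test_that("environment log-density is the Gaussian L2^2 form and equals half
the AOT distance on PSD inputs", {
  set.seed(41)
  g <- 4
  L <- matrix(0, g, g); L[lower.tri(L, diag = TRUE)] <- rnorm(g * (g + 1) / 2)
  M <- L %*% t(L)
  const <- (g * g / 2) * log(2 * pi)
  expect_equal(environment_log_density(M, L), -const)
  S <- matrix_sqrt_psd(rand_psd(g))
  pen <- -(environment_log_density(S, L) + const)
  expect_equal(pen, 0.5 * aot_distance(S, M), tolerance = 1e-10)
  # doubling the residual quadruples the penalty
  S2 <- M + 2 * (S - M)
  pen2 <- -(environment_log_density(S2, L) + const)
  expect_equal(pen2, 4 * pen, tolerance = 1e-8)
  expect_error(environment_log_density(diag(3), diag(2)), "mismatch")
})

test_that("elbo matches a literal term-by-term recomputation on a fixed
batch", {
  m <- tiny_model()
  tis <- tiny_tissue()
  st_idx <- 1:6; sc_idx <- 7:12
  st_b <- tis$counts_full[st_idx, tis$panel]
  sc_b <- m$data$sc_counts[sc_idx, ]
  sq <- m$data$covet$sigma_sqrt[, , st_idx]
  out <- elbo_loss(m, st_b, sc_b, sq)   # eps = 0: latent = posterior mean

  mu_st <- envi_encode(m, st_b, "st")$mu
  post_sc <- envi_encode(m, sc_b[, m$genes$shared], "sc")
  dec_sc <- envi_decode(m, post_sc$mu, "sc")
  sc_ll <- mean(rowSums(nb_log_pmf(sc_b, dec_sc$rate, dec_sc$p)))
  dec_st <- envi_decode(m, mu_st, "st")
  st_ll <- mean(rowSums(matrix(poisson_log_pmf(st_b, dec_st$rate),
                               nrow(st_b))))
  env <- envi_decode_env(m, mu_st)
  env_ll <- mean(vapply(seq_along(st_idx), function(i)
    -0.5 * sum((env$sqrt[, , i] - sq[, , i])^2), numeric(1)))
  sig_st <- envi_encode(m, st_b, "st")$sigma
  kl <- mean(c(kl_diag_gaussian(mu_st, sig_st),
               kl_diag_gaussian(post_sc$mu, post_sc$sigma)))
  expect_equal(unname(out$terms["sc_ll"]), sc_ll, tolerance = 1e-8)
  expect_equal(unname(out$terms["st_ll"]), st_ll, tolerance = 1e-8)
  expect_equal(unname(out$terms["env_ll"]), env_ll, tolerance = 1e-8)
  expect_equal(unname(out$terms["kl"]), kl, tolerance = 1e-8)
  expect_equal(out$loss, -(sc_ll + st_ll + env_ll) + m$beta * kl,
               tolerance = 1e-8)
  # beta = 0: loss is the negative data log-likelihood only
  out0 <- elbo_loss(m, st_b, sc_b, sq, beta = 0)
  expect_equal(out0$loss, -(sc_ll + st_ll + env_ll), tolerance = 1e-8)
})

test_that("encoding is deterministic, conditioned on modality, and the
default architecture matches the reference recipe", {
  m <- tiny_model()
  x <- m$data$st_counts[1:4, ]
  p1 <- envi_encode(m, x, "st"); p2 <- envi_encode(m, x, "st")
  expect_identical(p1, p2)
  p3 <- envi_encode(m, x, "sc")
  expect_gt(max(abs(p1$mu - p3$mu)), 0)    # auxiliary neuron is active
  expect_true(all(p1$sigma > 0))

  cfg <- envi_config()
  expect_equal(cfg$latent_dim, 512)
  expect_equal(cfg$hidden_layers, 3)
  expect_equal(cfg$hidden_width, 1024)
  expect_equal(cfg$train_steps, 2^14)
  expect_equal(cfg$batch_size, 1024)
  expect_equal(cfg$hvg_count, 2048)
  expect_null(cfg$beta)                    # resolved at training time
  expect_error(envi_config(batch_size = 3), "even")
})

test_that("training reduces the loss and resolves beta by dataset size", {
  m <- tiny_model()
  expect_lt(mean(tail(m$loss, 30)), mean(head(m$loss, 30)))
  expect_true(all(is.finite(m$loss)))
  expect_equal(m$beta, 1.0)   # 512 cells total per modality < 10,000
  expect_error(
    envi_train(matrix(1, 4, 2, dimnames = list(NULL, c("a", "b"))),
               matrix(1, 4, 2, dimnames = list(NULL, c("c", "d"))),
               cbind(1:4, 1), tiny_cfg()),
    "intersect")
})

test_that("imputation covers the full gene scope, is nonnegative and tracks
observed shared-panel counts", {
  m <- tiny_model()
  tis <- tiny_tissue()
  imp <- envi_impute(m)
  expect_equal(dim(imp), c(nrow(tis$coords), length(m$genes$sc)))
  expect_setequal(colnames(imp), m$genes$sc)
  expect_true(all(imp >= 0))
  cors <- vapply(m$genes$shared, function(g)
    cor(imp[, g], tis$counts_full[, g]), numeric(1))
  expect_gt(mean(cors), 0.2)
})

test_that("inferred COVET square roots are PSD Gramians of the right shape", {
  m <- tiny_model()
  ic <- envi_infer_covet(m)
  g <- length(m$genes$shared)
  expect_equal(dim(ic), c(g, g, nrow(m$data$sc_counts)))
  for (i in c(1, 17, 101)) {
    S <- ic[, , i]
    expect_equal(S, t(S), tolerance = 1e-10)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})
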