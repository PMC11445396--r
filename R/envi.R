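# Conditional VAE integrating dissociated single-cell and spatial
# transcriptomics. One encoder and two decoders (expression, environment);
# a binary auxiliary input neuron carries the modality (0 = spatial,
# 1 = single cell). Gradients are computed analytically layer by layer.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Negative binomial log-pmf (failures/success parameterization)
#'
#' \deqn{P(X=k) = \binom{k+r-1}{k} (1-p)^k p^r} with `r` the number of
#' failures and `p` the success probability, so that `E[X] = r(1-p)/p`.
#' This is the parameterization produced by the expression decoder
#' (softplus for `r`, sigmoid for `p`).
#'
#' @param k nonnegative integer counts.
#' @param r positive size parameter.
#' @param p success probability in (0, 1).
#' @return log-probabilities, recycled elementwise.
#' @export
nb_log_pmf <- function(k, r, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (any(k < 0)) stop("counts must be nonnegative")
  lgamma(k + r) - lgamma(r) - lgamma(k + 1) + k * log1p(-p) + r * log(p)
}

#' Zero-inflated negative binomial log-pmf
#'
#' Mixture of a point mass at zero (weight `pi0`) and [nb_log_pmf()].
#'
#' @param k nonnegative integer counts.
#' @param r,p negative binomial parameters.
#' @param pi0 zero-inflation probability in [0, 1).
#' @return log-probabilities.
#' @export
zinb_log_pmf <- function(k, r, p, pi0) {
  if (any(pi0 < 0 | pi0 >= 1)) stop("pi0 must lie in [0, 1)")
  nb <- nb_log_pmf(k, r, p)
  out <- log1p(-pi0) + nb
  zero <- k == 0
  if (any(zero)) {
    pz <- if (length(pi0) > 1) pi0[zero] else pi0
    out[zero] <- log(pz + exp(log1p(-pz) + nb[zero]))
  }
  out
}

#' Poisson log-pmf
#'
#' @param k nonnegative integer counts.
#' @param lam positive rate.
#' @return log-probabilities.
#' @export
poisson_log_pmf <- function(k, lam) {
  if (any(lam <= 0)) stop("lam must be positive")
  stats::dpois(k, lam, log = TRUE)
}

#' KL divergence between a diagonal Gaussian and the standard normal
#'
#' Closed form \eqn{\frac12 \sum_j (\mu_j^2 + \sigma_j^2 - 1 - 2\ln\sigma_j)}.
#'
#' @param mu,sigma posterior mean and standard deviation vectors (or
#'   matrices, rows = cells).
#' @return scalar (vector input) or per-row KL (matrix input).
#' @export
kl_diag_gaussian <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  v <- 0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma))
  if (is.matrix(mu)) rowSums(v) else sum(v)
}

#' Reparameterized latent sample
#'
#' `l = mu + eps * sigma` elementwise, with `eps` a standard-normal draw
#' treated as a constant so gradients flow through `mu` and `sigma`.
#'
#' @param mu,sigma posterior parameters.
#' @param eps standard normal draw of the same shape.
#' @return latent sample.
#' @export
reparameterize <- function(mu, sigma, eps) {
  if (length(eps) != length(mu)) stop("eps must match mu in shape")
  mu + eps * sigma
}

#' Gaussian log-density of a COVET square root under the environment head
#'
#' The environment decoder parameterizes the mean of an isotropic Gaussian
#' over matrices as the Gramian `L %*% t(L)` of its lower-triangular output.
#' The log-density is, up to the additive constant,
#' \eqn{-\frac12 \| \sqrt\Sigma - LL^\top \|_2^2}, which is minus one half
#' the AOT distance between the implied COVET matrices.
#'
#' @param target_sqrt observed g x g COVET square root.
#' @param L lower-triangular g x g Cholesky factor (decoder output).
#' @return log-density (including the Gaussian normalizing constant).
#' @export
environment_log_density <- function(target_sqrt, L) {
  if (!all(dim(target_sqrt) == dim(L))) stop("shape mismatch")
  M <- L %*% t(L)
  g <- nrow(L)
  -0.5 * sum((target_sqrt - M)^2) - (g * g / 2) * log(2 * pi)
}

#' ENVI configuration
#'
#' Defaults follow the reference training recipe: a 512-dimensional latent,
#' three hidden layers of 1,024 units in the encoder and both decoders,
#' KL weight `beta = 0.3` (escalated to 1.0 when the combined dataset has
#' fewer than 10,000 cells and `beta` was not set explicitly), negative
#' binomial likelihood for the dissociated modality, Poisson for the imaged
#' modality, 2^14 Adam steps at learning rate 1e-3 dropping to 1e-4 for the
#' final quarter, batches of 1,024 cells split evenly between modalities,
#' and the union of the 2,048 most variable genes with the spatial panel.
#'
#' @param latent_dim latent dimensionality.
#' @param hidden_layers number of hidden layers per network.
#' @param hidden_width units per hidden layer.
#' @param beta KL weight (`NULL` = auto: 0.3, or 1.0 below 10,000 cells).
#' @param sc_likelihood one of `"nb"`, `"zinb"`, `"poisson"`, `"normal"`.
#' @param spatial_likelihood one of `"poisson"`, `"nb"`, `"zinb"`, `"normal"`.
#' @param train_steps number of gradient steps.
#' @param batch_size total batch size (even; half per modality).
#' @param lr,lr_final learning rate and final-quarter learning rate.
#' @param hvg_count number of highly variable genes to keep.
#' @param input_transform encoder input transform (`"log1p"` or `"none"`).
#' @param covet_log1p compute spatial COVET on log1p expression.
#' @param seed RNG seed for initialization and batching.
#' @return a list of class `envi_config`.
#' @export
envi_config <- function(latent_dim = 512, hidden_layers = 3,
                        hidden_width = 1024, beta = NULL,
                        sc_likelihood = c("nb", "zinb", "poisson", "normal"),
                        spatial_likelihood = c("poisson", "nb", "zinb", "normal"),
                        train_steps = 16384, batch_size = 1024,
                        lr = 1e-3, lr_final = 1e-4, hvg_count = 2048,
                        input_transform = c("log1p", "none"),
                        covet_log1p = TRUE, seed = NULL) {
  cfg <- list(latent_dim = as.integer(latent_dim),
              hidden_layers = as.integer(hidden_layers),
              hidden_width = as.integer(hidden_width),
              beta = beta,
              sc_likelihood = match.arg(sc_likelihood),
              spatial_likelihood = match.arg(spatial_likelihood),
              train_steps = as.integer(train_steps),
              batch_size = as.integer(batch_size),
              lr = lr, lr_final = lr_final,
              hvg_count = as.integer(hvg_count),
              input_transform = match.arg(input_transform),
              covet_log1p = isTRUE(covet_log1p),
              seed = seed)
  if (cfg$batch_size %% 2 != 0) stop("batch_size must be even")
  if (!is.null(beta) && beta <= 0) stop("beta must be positive")
  structure(cfg, class = "envi_config")
}

# ---- internal network machinery ------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_params <- function(arch) {
  p <- list()
  add_stack <- function(p, prefix, d_in, width, n_layers) {
    d <- d_in
    for (i in seq_len(n_layers)) {
      p[[paste0(prefix, "_W", i)]] <- glorot(d, width)
      p[[paste0(prefix, "_b", i)]] <- rep(0, width)
      d <- width
    }
    p
  }
  p <- add_stack(p, "enc", arch$g_st + 1, arch$width, arch$layers)
  p$enc_Wmu <- glorot(arch$width, arch$latent); p$enc_bmu <- rep(0, arch$latent)
  p$enc_Wls <- glorot(arch$width, arch$latent); p$enc_bls <- rep(0, arch$latent)
  p <- add_stack(p, "dx", arch$latent + 1, arch$width, arch$layers)
  p$dx_Wout <- glorot(arch$width, arch$out_dim); p$dx_bout <- rep(0, arch$out_dim)
  p <- add_stack(p, "de", arch$latent, arch$width, arch$layers)
  p$de_Wout <- glorot(arch$width, arch$tri_dim); p$de_bout <- rep(0, arch$tri_dim)
  if (arch$sc_lik == "normal") p$sc_logvar <- rep(0, arch$g_sc)
  if (arch$st_lik == "normal") p$st_logvar <- rep(0, arch$g_st)
  p
}

stack_forward <- function(p, prefix, X, n_layers) {
  A <- list(X)
  Z <- list()
  for (i in seq_len(n_layers)) {
    Zi <- sweep(A[[i]] %*% p[[paste0(prefix, "_W", i)]], 2,
                p[[paste0(prefix, "_b", i)]], "+")
    Z[[i]] <- Zi
    A[[i + 1]] <- pmax(Zi, 0)
  }
  list(A = A, Z = Z)
}

stack_backward <- function(p, prefix, cache, dTop, n_layers, grads) {
  dA <- dTop
  for (i in rev(seq_len(n_layers))) {
    dZ <- dA * (cache$Z[[i]] > 0)
    grads[[paste0(prefix, "_W", i)]] <- crossprod(cache$A[[i]], dZ)
    grads[[paste0(prefix, "_b", i)]] <- colSums(dZ)
    dA <- dZ %*% t(p[[paste0(prefix, "_W", i)]])
  }
  list(grads = grads, dX = dA)
}

# log-likelihood and gradients wrt raw output-layer activations for one
# modality's count block. K: counts (B x g); act: list of raw activation
# blocks (rate / p / pi, each B x g); logvar: per-gene vector (normal only).
head_ll <- function(lik, K, act, logvar = NULL) {
  if (lik == "normal") {
    m <- act$rate
    lv <- matrix(logvar, nrow(K), ncol(K), byrow = TRUE)
    v <- exp(lv)
    ll <- -0.5 * ((K - m)^2 / v + lv + log(2 * pi))
    return(list(ll = rowSums(ll), d_rate = (K - m) / v,
                d_logvar = colSums(0.5 * ((K - m)^2 / v - 1))))
  }
  if (lik == "poisson") {
    lam <- softplus(act$rate) + 1e-8
    ll <- K * log(lam) - lam - lgamma(K + 1)
    return(list(ll = rowSums(ll),
                d_rate = (K / lam - 1) * sigmoid(act$rate)))
  }
  r <- softplus(act$rate) + 1e-6
  p <- pmin(pmax(sigmoid(act$p), 1e-6), 1 - 1e-6)
  nb <- lgamma(K + r) - lgamma(r) - lgamma(K + 1) + K * log1p(-p) + r * log(p)
  d_r <- (digamma(K + r) - digamma(r) + log(p)) * sigmoid(act$rate)
  d_p <- r * (1 - p) - K * p
  if (lik == "nb")
    return(list(ll = rowSums(nb), d_rate = d_r, d_p = d_p))
  # zinb
  pi0 <- pmin(pmax(sigmoid(act$pi), 1e-6), 1 - 1e-6)
  zero <- K == 0
  q <- exp(r * log(p))                       # NB mass at zero
  A0 <- pi0 + (1 - pi0) * q
  ll <- log1p(-pi0) + nb
  ll[zero] <- log(A0[zero])
  d_pi <- -pi0
  d_pi[zero] <- ((1 - q) / A0 * pi0 * (1 - pi0))[zero]
  dr <- d_r
  dr[zero] <- ((1 - pi0) * q * log(p) / A0 * sigmoid(act$rate))[zero]
  dp <- d_p
  dp[zero] <- ((1 - pi0) * r * q / p / A0 * p * (1 - p))[zero]
  list(ll = rowSums(ll), d_rate = dr, d_p = dp, d_pi = d_pi)
}

# one forward (+ optional backward) pass over a joint half-and-half batch
envi_pass <- function(par, arch, xst_in, xst_tgt, xsc_in, xsc_tgt,
                      st_sqrt, eps, beta, want_grads = TRUE) {
  B1 <- nrow(xst_in); B2 <- nrow(xsc_in); B <- B1 + B2
  L <- arch$layers
  Xin <- rbind(cbind(xst_in, 0), cbind(xsc_in, 1))
  enc <- stack_forward(par, "enc", Xin, L)
  H <- enc$A[[L + 1]]
  mu <- sweep(H %*% par$enc_Wmu, 2, par$enc_bmu, "+")
  ls_raw <- sweep(H %*% par$enc_Wls, 2, par$enc_bls, "+")
  ls <- pmin(pmax(ls_raw, -8), 4)
  sig <- exp(ls)
  lat <- mu + eps * sig
  cflag <- c(rep(0, B1), rep(1, B2))
  dx <- stack_forward(par, "dx", cbind(lat, cflag), L)
  Aout <- sweep(dx$A[[L + 1]] %*% par$dx_Wout, 2, par$dx_bout, "+")

  bl <- arch$block_idx   # named list of column ranges into Aout
  gst <- arch$g_st
  sc_rows <- (B1 + 1):B
  st_rows <- 1:B1
  get_blocks <- function(rows, cols) {
    out <- list()
    for (nm in names(bl)) out[[nm]] <- Aout[rows, bl[[nm]][cols], drop = FALSE]
    out
  }
  sc_head <- head_ll(arch$sc_lik, xsc_tgt, get_blocks(sc_rows, seq_len(arch$g_sc)),
                     logvar = par$sc_logvar)
  st_head <- head_ll(arch$st_lik, xst_tgt, get_blocks(st_rows, seq_len(gst)),
                     logvar = par$st_logvar)

  # environment decoder on the spatial half
  de <- stack_forward(par, "de", lat[st_rows, , drop = FALSE], L)
  V <- sweep(de$A[[L + 1]] %*% par$de_Wout, 2, par$de_bout, "+")
  lowidx <- arch$low_idx
  env_ll <- numeric(B1)
  Lmats <- vector("list", B1)
  Rmats <- vector("list", B1)
  for (i in seq_len(B1)) {
    Li <- matrix(0, gst, gst)
    Li[lowidx] <- V[i, ]
    M <- tcrossprod(Li)
    R <- M - st_sqrt[, , i]
    env_ll[i] <- -0.5 * sum(R^2)
    Lmats[[i]] <- Li; Rmats[[i]] <- R
  }

  kl <- kl_diag_gaussian(mu, sig)
  loss <- -(mean(sc_head$ll) + mean(st_head$ll) + mean(env_ll)) +
    beta * mean(kl)
  terms <- c(sc_ll = mean(sc_head$ll), st_ll = mean(st_head$ll),
             env_ll = mean(env_ll), kl = mean(kl))
  if (!want_grads)
    return(list(loss = loss, terms = terms))

  grads <- list()
  # output-layer gradient (d loss / d Aout)
  dAout <- matrix(0, B, arch$out_dim)
  put <- function(dAout, rows, cols, nm, val) {
    dAout[rows, bl[[nm]][cols]] <- dAout[rows, bl[[nm]][cols], drop = FALSE] + val
    dAout
  }
  for (nm in intersect(c("rate", "p", "pi"), names(bl))) {
    dn <- paste0("d_", sub("rate", "rate", nm))
    if (!is.null(sc_head[[dn]]))
      dAout <- put(dAout, sc_rows, seq_len(arch$g_sc), nm, -sc_head[[dn]] / B2)
    if (!is.null(st_head[[dn]]))
      dAout <- put(dAout, st_rows, seq_len(gst), nm, -st_head[[dn]] / B1)
  }
  if (arch$sc_lik == "normal") grads$sc_logvar <- -sc_head$d_logvar / B2
  if (arch$st_lik == "normal") grads$st_logvar <- -st_head$d_logvar / B1

  grads$dx_Wout <- crossprod(dx$A[[L + 1]], dAout)
  grads$dx_bout <- colSums(dAout)
  bk <- stack_backward(par, "dx", dx, dAout %*% t(par$dx_Wout), L, grads)
  grads <- bk$grads
  dLat <- bk$dX[, seq_len(arch$latent), drop = FALSE]

  # environment decoder gradients
  dV <- matrix(0, B1, arch$tri_dim)
  for (i in seq_len(B1)) {
    dLi <- (2 / B1) * Rmats[[i]] %*% Lmats[[i]]
    dV[i, ] <- dLi[lowidx]
  }
  grads$de_Wout <- crossprod(de$A[[L + 1]], dV)
  grads$de_bout <- colSums(dV)
  bk2 <- stack_backward(par, "de", de, dV %*% t(par$de_Wout), L, grads)
  grads <- bk2$grads
  dLat[st_rows, ] <- dLat[st_rows, , drop = FALSE] + bk2$dX

  # KL + reparameterization
  dMu <- dLat + beta * mu / B
  dLs <- dLat * eps * sig + beta * (sig^2 - 1) / B
  dLs <- dLs * (ls_raw > -8 & ls_raw < 4)

  grads$enc_Wmu <- crossprod(H, dMu); grads$enc_bmu <- colSums(dMu)
  grads$enc_Wls <- crossprod(H, dLs); grads$enc_bls <- colSums(dLs)
  dH <- dMu %*% t(par$enc_Wmu) + dLs %*% t(par$enc_Wls)
  bk3 <- stack_backward(par, "enc", enc, dH, L, grads)
  grads <- bk3$grads
  list(loss = loss, terms = terms, grads = grads)
}

build_arch <- function(g_st, g_sc, config) {
  blocks <- c("rate")
  if (config$sc_likelihood %in% c("nb", "zinb") ||
      config$spatial_likelihood %in% c("nb", "zinb")) blocks <- c(blocks, "p")
  if (config$sc_likelihood == "zinb" || config$spatial_likelihood == "zinb")
    blocks <- c(blocks, "pi")
  block_idx <- list()
  off <- 0
  for (nm in blocks) {
    block_idx[[nm]] <- off + seq_len(g_sc)
    off <- off + g_sc
  }
  list(g_st = g_st, g_sc = g_sc, latent = config$latent_dim,
       width = config$hidden_width, layers = config$hidden_layers,
       out_dim = off, tri_dim = g_st * (g_st + 1) / 2,
       low_idx = which(lower.tri(matrix(0, g_st, g_st), diag = TRUE)),
       sc_lik = config$sc_likelihood, st_lik = config$spatial_likelihood,
       block_idx = block_idx)
}

# ---- training -------------------------------------------------------------

#' Train the ENVI conditional variational autoencoder
#'
#' Embeds spatial and dissociated single-cell expression in a shared latent
#' space by maximizing the evidence lower bound: negative binomial
#' reconstruction of the full single-cell transcriptome, Poisson
#' reconstruction of the imaged counts, isotropic-Gaussian reconstruction of
#' the COVET square roots through the environment decoder, minus a
#' beta-weighted KL to the standard-normal prior. Each mini-batch draws half
#' its cells from each modality (with replacement, independently).
#'
#' The single-cell gene scope is the union of the spatial panel with the most
#' variable remaining genes; shared genes occupy the leading output neurons
#' so the two modalities share them, and the remaining neurons are trained
#' from the single-cell data alone.
#'
#' @param sc_counts dissociated cells x genes count matrix (gene names
#'   required; a superset of the spatial panel is expected).
#' @param st_counts spatial cells x genes count matrix.
#' @param st_coords spatial coordinates aligned to `st_counts` rows.
#' @param config an [envi_config()].
#' @param k COVET niche size (default 8).
#' @param covet optional precomputed `covet_tensor` for the spatial data
#'   (must use the shared gene panel in training order).
#' @param verbose print progress every 10% of steps.
#' @return an object of class `envi` holding parameters, architecture,
#'   gene manifests, the training inputs needed for downstream inference,
#'   and the per-step loss trace.
#' @export
envi_train <- function(sc_counts, st_counts, st_coords,
                       config = envi_config(), k = 8, covet = NULL,
                       verbose = FALSE) {
  sc_counts <- as.matrix(sc_counts); st_counts <- as.matrix(st_counts)
  if (is.null(colnames(sc_counts)) || is.null(colnames(st_counts)))
    stop("both count matrices need gene names")
  shared <- intersect(colnames(st_counts), colnames(sc_counts))
  if (length(shared) == 0) stop("gene panels do not intersect")
  dropped <- setdiff(colnames(st_counts), shared)
  if (length(dropped) > 0)
    message(length(dropped), " spatial gene(s) absent from the single-cell ",
            "data were dropped: ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (!is.null(config$seed)) set.seed(config$seed)

  # gene scope: shared panel first, then top HVGs of the remaining sc genes
  rest <- setdiff(colnames(sc_counts), shared)
  if (length(rest) > 0) {
    v <- apply(log1p(sc_counts[, rest, drop = FALSE]), 2, stats::var)
    n_extra <- min(length(rest), max(config$hvg_count - length(shared), 0))
    rest <- rest[order(v, decreasing = TRUE)][seq_len(n_extra)]
  }
  sc_genes <- c(shared, rest)
  g_st <- length(shared); g_sc <- length(sc_genes)

  n_sc <- nrow(sc_counts); n_st <- nrow(st_counts)
  beta <- config$beta
  if (is.null(beta)) beta <- if (n_sc + n_st < 10000) 1.0 else 0.3

  tf <- if (config$input_transform == "log1p") log1p else identity
  st_in <- tf(st_counts[, shared, drop = FALSE])
  sc_in <- tf(sc_counts[, shared, drop = FALSE])
  st_tgt <- st_counts[, shared, drop = FALSE]
  sc_tgt <- sc_counts[, sc_genes, drop = FALSE]

  if (is.null(covet)) {
    covet <- compute_covet(st_counts[, shared, drop = FALSE], st_coords,
                           k = k, log1p = config$covet_log1p)
  }
  if (!identical(covet$genes, shared))
    stop("precomputed COVET gene panel must equal the shared panel")
  if (any(covet$empty)) stop("COVET has empty niches; use knn mode")
  st_sqrt <- covet$sigma_sqrt

  arch <- build_arch(g_st, g_sc, config)
  par <- init_params(arch)
  mstate <- lapply(par, function(x) x * 0)
  vstate <- mstate
  half <- config$batch_size / 2
  losses <- numeric(config$train_steps)
  b1 <- 0.9; b2 <- 0.999
  for (step in seq_len(config$train_steps)) {
    i_st <- sample.int(n_st, half, replace = TRUE)
    i_sc <- sample.int(n_sc, half, replace = TRUE)
    eps <- matrix(stats::rnorm(config$batch_size * arch$latent),
                  config$batch_size, arch$latent)
    out <- envi_pass(par, arch,
                     st_in[i_st, , drop = FALSE], st_tgt[i_st, , drop = FALSE],
                     sc_in[i_sc, , drop = FALSE], sc_tgt[i_sc, , drop = FALSE],
                     st_sqrt[, , i_st, drop = FALSE], eps, beta)
    if (!is.finite(out$loss))
      stop("non-finite loss at step ", step, " (terms: ",
           paste(names(out$terms), round(out$terms, 3), collapse = ", "), ")")
    losses[step] <- out$loss
    lr <- if (step > 0.75 * config$train_steps) config$lr_final else config$lr
    for (nm in names(out$grads)) {
      g <- out$grads[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
      mhat <- mstate[[nm]] / (1 - b1^step)
      vhat <- vstate[[nm]] / (1 - b2^step)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
    }
    if (verbose && step %% max(1, config$train_steps %/% 10) == 0)
      message("step ", step, "/", config$train_steps,
              " loss ", round(out$loss, 3))
  }
  structure(list(par = par, arch = arch, config = config, beta = beta,
                 genes = list(shared = shared, sc = sc_genes),
                 data = list(st_in = st_in, sc_in = sc_in,
                             st_counts = st_tgt, sc_counts = sc_tgt,
                             covet = covet),
                 loss = losses),
            class = "envi")
}

#' @export
print.envi <- function(x, ...) {
  cat("ENVI model:", length(x$genes$shared), "shared /", length(x$genes$sc),
      "single-cell genes; latent", x$arch$latent, "\n")
  cat("trained", length(x$loss), "steps; loss",
      round(x$loss[1], 2), "->", round(x$loss[length(x$loss)], 2), "\n")
  invisible(x)
}

#' Encode expression into the latent posterior
#'
#' @param model a trained `envi` model.
#' @param x cells x shared-genes matrix on the encoder's input scale
#'   (`envi_train` applies the configured transform for you when you pass
#'   raw counts and `transform = TRUE`).
#' @param modality `"st"` (auxiliary neuron 0) or `"sc"` (1).
#' @param transform apply the configured input transform to `x`.
#' @return list with `mu` and `sigma` matrices (cells x latent).
#' @export
envi_encode <- function(model, x, modality = c("st", "sc"), transform = TRUE) {
  modality <- match.arg(modality)
  x <- as.matrix(x)
  if (ncol(x) != model$arch$g_st) stop("input must cover the shared panel")
  if (transform && model$config$input_transform == "log1p") x <- log1p(x)
  Xin <- cbind(x, if (modality == "sc") 1 else 0)
  enc <- stack_forward(model$par, "enc", Xin, model$arch$layers)
  H <- enc$A[[model$arch$layers + 1]]
  mu <- sweep(H %*% model$par$enc_Wmu, 2, model$par$enc_bmu, "+")
  ls <- pmin(pmax(sweep(H %*% model$par$enc_Wls, 2, model$par$enc_bls, "+"), -8), 4)
  list(mu = mu, sigma = exp(ls))
}

#' Decode latent vectors through the expression head
#'
#' @param model a trained `envi` model.
#' @param latent cells x latent matrix.
#' @param modality which auxiliary flag to decode with.
#' @return list of head parameter matrices (`rate`/`p`/`pi` as applicable,
#'   transformed to their natural scale) and `mean`, the expected expression.
#' @export
envi_decode <- function(model, latent, modality = c("sc", "st")) {
  modality <- match.arg(modality)
  arch <- model$arch
  cflag <- if (modality == "sc") 1 else 0
  dx <- stack_forward(model$par, "dx", cbind(latent, cflag), arch$layers)
  Aout <- sweep(dx$A[[arch$layers + 1]] %*% model$par$dx_Wout, 2,
                model$par$dx_bout, "+")
  lik <- if (modality == "sc") arch$sc_lik else arch$st_lik
  cols <- if (modality == "sc") seq_len(arch$g_sc) else seq_len(arch$g_st)
  out <- list()
  raw_rate <- Aout[, arch$block_idx$rate[cols], drop = FALSE]
  if (lik == "normal") {
    out$mean <- raw_rate
    return(out)
  }
  out$rate <- softplus(raw_rate) + if (lik == "poisson") 1e-8 else 1e-6
  if (lik == "poisson") {
    out$mean <- out$rate
    return(out)
  }
  out$p <- pmin(pmax(sigmoid(Aout[, arch$block_idx$p[cols], drop = FALSE]),
                     1e-6), 1 - 1e-6)
  out$mean <- out$rate * (1 - out$p) / out$p
  if (lik == "zinb") {
    out$pi <- sigmoid(Aout[, arch$block_idx$pi[cols], drop = FALSE])
    out$mean <- (1 - out$pi) * out$mean
  }
  out
}

#' Decode latent vectors through the environment head
#'
#' @param model a trained `envi` model.
#' @param latent cells x latent matrix.
#' @return list with `L` (g x g x n lower-triangular factors) and `sqrt`
#'   (g x g x n predicted COVET square roots, the Gramians `L L^T`).
#' @export
envi_decode_env <- function(model, latent) {
  arch <- model$arch
  de <- stack_forward(model$par, "de", as.matrix(latent), arch$layers)
  V <- sweep(de$A[[arch$layers + 1]] %*% model$par$de_Wout, 2,
             model$par$de_bout, "+")
  n <- nrow(V); g <- arch$g_st
  Larr <- array(0, c(g, g, n))
  Sarr <- array(0, c(g, g, n),
                dimnames = list(model$genes$shared, model$genes$shared, NULL))
  for (i in seq_len(n)) {
    Li <- matrix(0, g, g)
    Li[arch$low_idx] <- V[i, ]
    Larr[, , i] <- Li
    Sarr[, , i] <- tcrossprod(Li)
  }
  list(L = Larr, sqrt = Sarr)
}

#' Evidence lower bound on a fixed batch
#'
#' Deterministic given `eps`; returns the total loss (negative ELBO up to
#' likelihood constants dropped during training) and its four terms, each a
#' per-cell mean: single-cell log-likelihood, spatial log-likelihood,
#' environment log-likelihood (without the Gaussian constant) and the KL.
#'
#' @param model a trained (or freshly initialized) `envi` model.
#' @param st_batch,sc_batch count matrices on the training gene panels.
#' @param st_sqrt g x g x n array of COVET square roots for `st_batch`.
#' @param eps standard-normal draw, `(n_st + n_sc) x latent`; 0 uses the
#'   posterior mean.
#' @param beta KL weight (defaults to the trained value).
#' @return list with `loss` and `terms`.
#' @export
elbo_loss <- function(model, st_batch, sc_batch, st_sqrt, eps = NULL,
                      beta = NULL) {
  tf <- if (model$config$input_transform == "log1p") log1p else identity
  st_batch <- as.matrix(st_batch); sc_batch <- as.matrix(sc_batch)
  if (is.null(beta)) beta <- model$beta
  B <- nrow(st_batch) + nrow(sc_batch)
  if (is.null(eps)) eps <- matrix(0, B, model$arch$latent)
  out <- envi_pass(model$par, model$arch,
                   tf(st_batch[, model$genes$shared, drop = FALSE]),
                   st_batch[, model$genes$shared, drop = FALSE],
                   tf(sc_batch[, model$genes$shared, drop = FALSE]),
                   sc_batch[, model$genes$sc, drop = FALSE],
                   st_sqrt, eps, beta, want_grads = FALSE)
  out
}

#' Impute unimaged genes for spatial cells
#'
#' Passes each spatial cell through the encoder with its own modality flag,
#' then decodes the posterior-mean latent with the single-cell flag, yielding
#' the expected expression of the full single-cell gene scope (negative
#' binomial expectation `r(1-p)/p` under the default configuration).
#'
#' @param model a trained `envi` model.
#' @param st_counts optional spatial counts (defaults to the training data).
#' @param sample draw one posterior sample instead of using the mean.
#' @return nonnegative matrix, spatial cells x single-cell genes.
#' @export
envi_impute <- function(model, st_counts = NULL, sample = FALSE) {
  if (is.null(model$par)) stop("model is not trained")
  x <- if (is.null(st_counts)) model$data$st_counts
       else as.matrix(st_counts)[, model$genes$shared, drop = FALSE]
  post <- envi_encode(model, x, "st")
  lat <- if (sample)
    reparameterize(post$mu, post$sigma,
                   matrix(stats::rnorm(length(post$mu)), nrow(post$mu)))
  else post$mu
  imp <- envi_decode(model, lat, "sc")$mean
  dimnames(imp) <- list(rownames(x), model$genes$sc)
  imp
}

#' Infer COVET square roots for dissociated cells
#'
#' Encodes single-cell expression (restricted to the shared panel, modality
#' flag 1) and applies the environment decoder to the posterior-mean latent.
#' Outputs are Gramians, hence symmetric PSD by construction, and directly
#' comparable to measured COVET square roots under the AOT
#' (flatten-and-Euclidean) metric.
#'
#' @param model a trained `envi` model.
#' @param sc_counts optional single-cell counts (defaults to training data).
#' @return g_st x g_st x n_sc array of predicted square roots.
#' @export
envi_infer_covet <- function(model, sc_counts = NULL) {
  if (is.null(model$par)) stop("model is not trained")
  x <- if (is.null(sc_counts)) model$data$sc_counts[, model$genes$shared, drop = FALSE]
       else as.matrix(sc_counts)[, model$genes$shared, drop = FALSE]
  post <- envi_encode(model, x, "sc")
  envi_decode_env(model, post$mu)$sqrt
}

#' Latent posterior means for either modality
#'
#' @param model a trained `envi` model.
#' @param counts count matrix covering the shared panel (defaults to the
#'   training data of `modality`).
#' @param modality `"st"` or `"sc"`.
#' @return cells x latent matrix of posterior means.
#' @export
envi_latent <- function(model, counts = NULL, modality = c("st", "sc")) {
  modality <- match.arg(modality)
  x <- if (!is.null(counts)) as.matrix(counts)[, model$genes$shared, drop = FALSE]
       else if (modality == "st") model$data$st_counts
       else model$data$sc_counts[, model$genes$shared, drop = FALSE]
  envi_encode(model, x, modality)$mu
}
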