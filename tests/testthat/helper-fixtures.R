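# Shared fixtures, generated in code.

# random symmetric PSD matrix (Wishart-style Gramian)
rand_psd <- function(g, df = g + 2) {
  X <- matrix(rnorm(g * df), df, g)
  crossprod(X) / df
}

# pair of simultaneously diagonalizable (hence commuting) PSD matrices
rand_commuting_pair <- function(g) {
  Q <- qr.Q(qr(matrix(rnorm(g * g), g)))
  list(a = Q %*% (runif(g, 0.2, 3) * t(Q)),
       b = Q %*% (runif(g, 0.2, 3) * t(Q)))
}

# literal transcription of the trace-form AOT formula (independent of the
# Frobenius fast path used by aot_distance)
aot_trace_oracle <- function(sigma_i, sigma_j) {
  A <- matrix_sqrt_psd(sigma_i)
  B <- matrix_sqrt_psd(sigma_j)
  sum(diag(sigma_i)) + sum(diag(sigma_j)) - 2 * sum(diag(A %*% B))
}

# small tissue shared across tests (built once per test run)
tiny_tissue <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_preset("small", seed = 42)
    cache
  }
})
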