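# Shared builders for the test suite; everything is generated in code.

circle120 <- function() uniform_circular_grid(120)

# Smooth exponential-cosine kernel on a circular grid.
k1_kernel <- function(grid = circle120(), scale = 0.25) {
  th <- drop(grid$values)
  new_kernel(exp(scale * cos(outer(th, th, "-"))), grid)
}

# Random Gaussian code: well-conditioned generic responses.
gaussian_code <- function(n, grid, seed = 1) {
  m <- nrow(grid$values)
  population_code(
    withr::with_seed(seed, matrix(stats::rnorm(n * m), n, m)), grid
  )
}

rel_frob <- function(a, b) norm(a - b, "F") / max(norm(b, "F"), 1e-300)

# Fourier-basis spectrum of the bounded-frequency kernel sum_k cos(k Delta):
# all eigenvalues are 1/2-degenerate, so the eigendecomposition's basis within
# the eigenspace is arbitrary; tests about per-frequency coefficients pin the
# basis explicitly to (sqrt(2) cos(k theta), sqrt(2) sin(k theta)), ordered by
# frequency, which is an equally valid spectrum of the same kernel.
fourier_spectrum <- function(grid, k_max = 20) {
  th <- drop(grid$values)
  psi <- do.call(cbind, lapply(seq_len(k_max), function(k) {
    cbind(sqrt(2) * cos(k * th), sqrt(2) * sin(k * th))
  }))
  structure(
    list(eigenvalues = rep(0.5, 2 * k_max), eigenfunctions = psi, grid = grid),
    class = "kernel_spectrum"
  )
}

# Measure-weighted Gram matrix of eigenfunctions (identity when orthonormal).
ortho_gram <- function(spectrum) {
  p <- spectrum$grid$probabilities
  crossprod(spectrum$eigenfunctions, p * spectrum$eigenfunctions)
}
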