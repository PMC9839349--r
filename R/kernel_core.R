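#' Inner-product kernel of a population code
#'
#' Computes the similarity kernel `K(theta_m, theta_m') = (1/N) sum_i
#' r_i(theta_m) r_i(theta_m')` (with `normalize = TRUE`) or the raw Gram
#' matrix `t(R) %*% R` (with `normalize = FALSE`). The kernel encodes the
#' geometry of the code: it is invariant to orthogonal rotations `Q %*% R`
#' of the response matrix, and it fully determines the behavior of any
#' linear readout trained with the delta rule.
#'
#' @param code a [population_code()].
#' @param normalize divide by the number of neurons N (default `TRUE`).
#' @return an object of class `pop_kernel`: list with `matrix` (M x M,
#'   symmetric PSD) and `grid`.
#' @export
compute_kernel <- function(code, normalize = TRUE) {
  stopifnot(inherits(code, "population_code"))
  r <- code$responses
  check_finite_matrix(r, "responses")
  if (ncol(r) < 2) stop_invalid("need at least 2 stimuli")
  k <- crossprod(r)
  if (normalize) k <- k / nrow(r)
  new_kernel(k, code$grid)
}

#' Construct a kernel object from a matrix
#'
#' Validates symmetry (to 1e-10 relative) and positive semidefiniteness
#' (smallest eigenvalue >= -1e-8 * largest) before wrapping.
#'
#' @param matrix symmetric PSD `M x M` matrix of kernel values.
#' @param grid the [stimulus_grid()] the rows/columns refer to.
#' @return a `pop_kernel`.
#' @export
new_kernel <- function(matrix, grid) {
  check_finite_matrix(matrix, "kernel matrix")
  stopifnot(inherits(grid, "stimulus_grid"))
  if (nrow(matrix) != ncol(matrix) || nrow(matrix) != n_stimuli(grid)) {
    stop_invalid("kernel must be square with one row per grid stimulus")
  }
  scale <- max(abs(matrix), 1e-300)
  if (max(abs(matrix - t(matrix))) > 1e-10 * scale) {
    stop_invalid("kernel matrix is not symmetric")
  }
  matrix <- (matrix + t(matrix)) / 2
  ev <- eigen(matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev, 0)) {
    stop_invalid("kernel matrix is not positive semidefinite")
  }
  structure(list(matrix = matrix, grid = grid), class = "pop_kernel")
}

#' @export
print.pop_kernel <- function(x, ...) {
  cat(sprintf("<pop_kernel: %d x %d>\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Measure-weighted eigendecomposition of a kernel
#'
#' Solves the discrete kernel eigenproblem
#' `sum_m' p_m' K(theta_m, theta_m') psi_k(theta_m') = lambda_k psi_k(theta_m)`
#' via the symmetrized matrix `diag(sqrt(p)) K diag(sqrt(p))`. The returned
#' eigenfunctions are orthonormal under the grid measure,
#' `sum_m p_m psi_k(theta_m) psi_l(theta_m) = delta_kl`, so on a uniform
#' grid of M points the eigenvalues carry a factor 1/M relative to a plain
#' matrix eigendecomposition of K. Eigenvalues below `1e-12 * lambda_1`
#' are clipped to exact zeros and their eigenfunctions dropped.
#'
#' @param kernel a `pop_kernel`.
#' @return object of class `kernel_spectrum`: `eigenvalues` (nonincreasing,
#'   all > 0), `eigenfunctions` (M x K matrix, k-th column is `psi_k` on the
#'   grid), and `grid`.
#' @export
eigendecompose <- function(kernel) {
  stopifnot(inherits(kernel, "pop_kernel"))
  p <- kernel$grid$probabilities
  if (any(p <= 0)) {
    stop_invalid("all grid probabilities must be strictly positive; drop ",
                 "zero-probability stimuli first", class = "popkernel_invalid_measure")
  }
  sp <- sqrt(p)
  sym <- kernel$matrix * (sp %o% sp)
  ee <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  lam <- ee$values
  lam[lam < 1e-12 * max(lam[1], 0)] <- 0
  keep <- lam > 0
  psi <- ee$vectors[, keep, drop = FALSE] / sp
  structure(
    list(eigenvalues = lam[keep], eigenfunctions = psi, grid = kernel$grid),
    class = "kernel_spectrum"
  )
}

#' @export
print.kernel_spectrum <- function(x, ...) {
  cat(sprintf(
    "<kernel_spectrum: %d modes, trace %.4g, top eigenvalue %.4g>\n",
    length(x$eigenvalues), sum(x$eigenvalues), x$eigenvalues[1]
  ))
  invisible(x)
}

#' Reconstruct a kernel from its spectrum (Mercer sum)
#'
#' `K = Psi %*% diag(lambda) %*% t(Psi)`; used for round-trip checks.
#'
#' @param spectrum a `kernel_spectrum`.
#' @return a `pop_kernel`.
#' @export
mercer_reconstruct <- function(spectrum) {
  psi <- spectrum$eigenfunctions
  k <- psi %*% (spectrum$eigenvalues * t(psi))
  new_kernel(k, spectrum$grid)
}

#' Translation average of a kernel on a uniform circular grid
#'
#' Averages the kernel along diagonals: `K(Delta) = (1/M) sum_mu
#' K(theta_mu, theta_(mu+Delta))` with index addition modulo M. For a
#' translation-invariant (circulant) kernel this recovers its profile
#' exactly; for other kernels it is the translation-symmetrized profile
#' used when fitting orientation tuning models.
#'
#' @param kernel a `pop_kernel` on a uniform circular grid.
#' @return numeric vector of length M; element `d+1` is `K(Delta = d)` in
#'   grid steps.
#' @export
translation_average <- function(kernel) {
  stopifnot(inherits(kernel, "pop_kernel"))
  if (!is_uniform_circular(kernel$grid)) {
    stop_invalid("translation_average requires a uniform circular grid",
                 class = "popkernel_unsupported_grid")
  }
  k <- kernel$matrix
  m <- nrow(k)
  vapply(0:(m - 1), function(d) {
    idx <- ((seq_len(m) - 1 + d) %% m) + 1
    mean(k[cbind(seq_len(m), idx)])
  }, numeric(1))
}

#' Convex mixture of two kernels
#'
#' `s * ks + (1 - s) * kc` on a shared grid; positive semidefiniteness is
#' preserved. This is the composition rule for a population made of an
#' `s` fraction of one cell type and `1 - s` of another (e.g. simple and
#' complex cells).
#'
#' @param ks,kc `pop_kernel` objects on the same grid.
#' @param s mixing fraction in `[0, 1]` (weight of `ks`).
#' @return a `pop_kernel`.
#' @export
mix_kernels <- function(ks, kc, s) {
  stopifnot(inherits(ks, "pop_kernel"), inherits(kc, "pop_kernel"))
  if (!same_grid(ks$grid, kc$grid)) stop_invalid("kernels live on different grids")
  if (!is.numeric(s) || length(s) != 1 || s < 0 || s > 1) {
    stop_invalid("s must be a single fraction in [0, 1]")
  }
  new_kernel(s * ks$matrix + (1 - s) * kc$matrix, ks$grid)
}

#' Write a kernel spectrum to plain-text files
#'
#' Eigenvalues go to `<stem>_eigenvalues.txt` (one per line) and the
#' eigenfunction matrix to `<stem>_eigenfunctions.tsv`.
#'
#' @param spectrum a `kernel_spectrum`.
#' @param stem path stem for the two output files.
#' @return invisibly, the two file paths.
#' @export
write_spectrum <- function(spectrum, stem) {
  ev_path <- paste0(stem, "_eigenvalues.txt")
  ef_path <- paste0(stem, "_eigenfunctions.tsv")
  writeLines(format(spectrum$eigenvalues, digits = 17, scientific = TRUE), ev_path)
  write_matrix(spectrum$eigenfunctions, ef_path)
  invisible(c(eigenvalues = ev_path, eigenfunctions = ef_path))
}
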