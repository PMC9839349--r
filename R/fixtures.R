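#' Generate the bundled synthetic fixture set
#'
#' Writes a small, fully synthetic input bundle to `dir`: the classic
#' smooth/rapid code pair (kernels `exp(0.25 cos(Delta))` and
#' `sum_{k<=20} cos(k Delta)` on a 120-point circular grid, with the low-
#' and high-frequency targets), a von Mises triplet (narrow / intermediate
#' / wide bandwidths), Gabor mixtures at simple-cell fractions
#' `s = 0, 0.5, 1`, a toy one-hot code for RROS analysis, and a small
#' recurrent-network task bundle. Regeneration with the same seed is
#' bit-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return invisibly, a named list of written paths.
#' @export
make_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  grid <- uniform_circular_grid(120)
  th <- grid_angles(grid)

  k1 <- new_kernel(exp(0.25 * cos(outer(th, th, "-"))), grid)
  k2 <- fourier_sum_kernel(grid, 20)
  for (nm in c("k1", "k2")) {
    kern <- if (nm == "k1") k1 else k2
    code <- code_from_kernel(kern, 120, seed = derive_seed(seed, match(nm, c("k1", "k2"))))
    p <- file.path(dir, paste0("code_", nm, ".tsv"))
    write_matrix(code$responses, p, sidecar = grid_to_sidecar(grid))
    paths[[paste0("code_", nm)]] <- p
  }
  for (tn in c("low_freq", "high_freq")) {
    p <- file.path(dir, paste0("target_", tn, ".tsv"))
    write_matrix(matrix(make_target(tn, grid), ncol = 1), p)
    paths[[paste0("target_", tn)]] <- p
  }

  sigmas <- c(narrow = sqrt(1 / 12), mid = 0.5, wide = 1.5)
  for (i in seq_along(sigmas)) {
    code <- von_mises_population(120, sigmas[i], grid,
                                 mode = "spectral", seed = derive_seed(seed, 10 + i))
    p <- file.path(dir, paste0("code_von_mises_", names(sigmas)[i], ".tsv"))
    write_matrix(code$responses, p, sidecar = grid_to_sidecar(grid))
    paths[[paste0("von_mises_", names(sigmas)[i])]] <- p
  }

  prof <- tuning_profile("gabor_simple", sigma_sq = 0.2, q = 1.7, a = 0.2)
  for (s in c(0, 0.5, 1)) {
    spec <- gabor_mixture_spec(s, n_neurons = 96, n_theta = 16, n_phi = 8)
    code <- gabor_mixture_code(spec, prof)
    p <- file.path(dir, sprintf("code_gabor_s%02d.tsv", round(100 * s)))
    write_matrix(code$responses, p, sidecar = grid_to_sidecar(code$grid))
    paths[[sprintf("gabor_s%02d", round(100 * s))]] <- p
  }

  onehot <- matrix(0, 50, 100)
  onehot[cbind(1:50, withr::with_seed(derive_seed(seed, 20), sample.int(100, 50, TRUE)))] <- 1
  p <- file.path(dir, "code_onehot.tsv")
  write_matrix(onehot, p)
  paths$onehot <- p

  rnn_cfg <- list(
    network = list(n_neurons = 100, gain = 1.5, tau = 0.05, n_store = 30,
                   n_sequences = 8, seed = derive_seed(seed, 30)),
    task = list(delays = c(0, 0.5, 1)),
    theory = list(p_grid = c(10, 20, 50, 100), ridge = 0),
    simulation = list(repeats = 10, seed = derive_seed(seed, 31))
  )
  p <- file.path(dir, "rnn_task.yaml")
  write_config(rnn_cfg, p)
  paths$rnn_config <- p

  invisible(paths)
}
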