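#' Named target families
#'
#' Evaluates a standard target function on a grid. Available families:
#' `"low_freq"` is `cos(theta) - 0.6 cos(4 theta)` and `"high_freq"` is
#' `cos(6 theta) - cos(8 theta)` (the classic smooth-vs-rapid pair on a
#' circular grid); `"cosine"` is `cos(k * theta)` with frequency `k`;
#' `"phase_only"` is `cos(phi)` on an orientation-phase product grid
#' (depends on phase alone); `"orientation_only"` is `cos(2 * theta)` on a
#' product grid.
#'
#' @param name target family name.
#' @param grid a [stimulus_grid()].
#' @param k frequency for the `"cosine"` family.
#' @return numeric target vector over the grid.
#' @export
make_target <- function(name = c("low_freq", "high_freq", "cosine",
                                 "phase_only", "orientation_only"),
                        grid, k = 1) {
  name <- match.arg(name)
  if (name %in% c("phase_only", "orientation_only")) {
    if (ncol(grid$values) < 2) stop_invalid(name, " needs an orientation-phase grid")
    theta <- grid$values[, 1]; phi <- grid$values[, 2]
    return(switch(name,
      phase_only = cos(phi),
      orientation_only = cos(2 * theta)
    ))
  }
  th <- grid_angles(grid)
  switch(name,
    low_freq = cos(th) - 0.6 * cos(4 * th),
    high_freq = cos(6 * th) - cos(8 * th),
    cosine = cos(k * th)
  )
}

#' Fourier-pair kernel of bounded frequency content
#'
#' `K(theta, theta') = sum_{k=1..k_max} cos(k (theta - theta'))`: a
#' rank-`2*k_max` kernel whose eigenfunctions under the uniform measure
#' are the Fourier pairs `cos(k theta), sin(k theta)`, each with
#' eigenvalue 1/2. Induces rapidly varying tuning curves.
#'
#' @param grid uniform circular [stimulus_grid()].
#' @param k_max highest frequency (default 20).
#' @return a `pop_kernel`.
#' @export
fourier_sum_kernel <- function(grid, k_max = 20) {
  th <- grid_angles(grid)
  d <- outer(th, th, "-")
  k <- Reduce(`+`, lapply(seq_len(k_max), function(k) cos(k * d)))
  new_kernel(k, grid)
}
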