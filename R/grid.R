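#' Stimulus grid with a probability measure
#'
#' A `stimulus_grid` holds the discrete stimulus coordinates `theta_m` at
#' which a population code is evaluated, together with the probability
#' `p_m` that each stimulus occurs. All spectral quantities in the package
#' (eigenvalues, eigenfunction orthonormality, generalization error) are
#' defined with respect to this measure.
#'
#' @param values numeric vector (scalar stimuli, e.g. an angle in radians)
#'   or a matrix with one row per stimulus (e.g. orientation-phase pairs).
#' @param probabilities nonnegative weights, one per stimulus; they must sum
#'   to 1 (within 1e-12). Defaults to the uniform measure.
#' @param period for circular scalar grids, the period of the stimulus
#'   variable (e.g. `2*pi` for direction, `pi` for grating orientation);
#'   `NA` for non-circular grids.
#' @return an object of class `stimulus_grid`.
#' @export
stimulus_grid <- function(values, probabilities = NULL, period = NA_real_) {
  vals <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1)
  m <- nrow(vals)
  if (m < 2) stop_invalid("a stimulus grid needs at least 2 stimuli")
  if (anyDuplicated(split(vals, row(vals)))) {
    stop_invalid("stimulus values must be distinct")
  }
  if (is.null(probabilities)) probabilities <- rep(1 / m, m)
  p <- as.numeric(probabilities)
  if (length(p) != m || any(p < 0)) {
    stop_invalid("probabilities must be nonnegative, one per stimulus")
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop_invalid("probabilities must sum to 1 (got ", format(sum(p)), ")")
  }
  structure(
    list(values = vals, probabilities = p, period = period),
    class = "stimulus_grid"
  )
}

#' Uniform circular stimulus grid
#'
#' Half-open uniform grid on `[0, period)` with the uniform measure, the
#' standard setting for orientation (`period = pi`) and direction
#' (`period = 2*pi`) stimuli. Index arithmetic on such grids is modulo `m`.
#'
#' @param m number of grid points.
#' @param period circumference of the stimulus circle.
#' @return a `stimulus_grid`.
#' @export
uniform_circular_grid <- function(m, period = 2 * pi) {
  stimulus_grid(seq(0, period, length.out = m + 1)[seq_len(m)], period = period)
}

#' Product grid of orientations and phases
#'
#' Grid over `(theta, phi)` pairs: `n_theta` orientations uniform on
#' `[0, pi)` crossed with `n_phi` phases uniform on `[0, 2*pi)`, with the
#' uniform product measure. Column 1 is orientation, column 2 phase.
#'
#' @param n_theta,n_phi number of orientation / phase points.
#' @return a `stimulus_grid` whose `values` is an `n_theta*n_phi` x 2 matrix.
#' @export
orientation_phase_grid <- function(n_theta, n_phi) {
  theta <- seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
  vals <- as.matrix(expand.grid(theta = theta, phi = phi))
  g <- stimulus_grid(vals)
  g$period <- c(pi, 2 * pi)
  g
}

n_stimuli <- function(grid) nrow(grid$values)

grid_angles <- function(grid) {
  if (ncol(grid$values) != 1) stop_invalid("grid is not one-dimensional")
  drop(grid$values)
}

is_uniform_circular <- function(grid, tol = 1e-10) {
  if (ncol(grid$values) != 1 || is.na(grid$period[1])) return(FALSE)
  m <- n_stimuli(grid)
  th <- grid_angles(grid)
  step <- grid$period[1] / m
  max(abs(th - (th[1] + step * (seq_len(m) - 1)))) <= tol &&
    max(abs(grid$probabilities - 1 / m)) <= tol
}

same_grid <- function(a, b, tol = 1e-10) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$values - b$values)) <= tol &&
    max(abs(a$probabilities - b$probabilities)) <= tol
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf(
    "<stimulus_grid: %d stimuli, dim %d%s>\n",
    n_stimuli(x), ncol(x$values),
    if (!all(is.na(x$period))) paste0(", period ", paste(signif(x$period, 4), collapse = " x ")) else ""
  ))
  invisible(x)
}
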