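#' Tuning profile for the Gabor model
#'
#' Parameters of the orientation tuning nonlinearity: the response of a
#' simple cell preferring `theta_i` is
#' `g_{q,a}(z) = max(0, z - a)^q` applied to the drive
#' `z = cosh(cos(theta - theta_i)/sigma_sq) / cosh(1/sigma_sq)`,
#' which is periodic in `theta` with period `pi`.
#'
#' @param kind one of `"von_mises"`, `"gabor_simple"`, `"gabor_complex"`.
#' @param sigma_sq tuning width parameter `sigma^2 > 0` (dimensionless; the
#'   drive uses its inverse `sigma^-2`).
#' @param q power-law exponent of the nonlinearity, `q > 0`.
#' @param a threshold in `[0, 1)`.
#' @return an object of class `tuning_profile`.
#' @export
tuning_profile <- function(kind = c("gabor_simple", "gabor_complex", "von_mises"),
                           sigma_sq, q = 1, a = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma_sq) || sigma_sq <= 0) stop_invalid("sigma_sq must be > 0")
  if (!is.numeric(q) || q <= 0) stop_invalid("q must be > 0")
  if (!is.numeric(a) || a < 0 || a >= 1) stop_invalid("a must lie in [0, 1)")
  structure(list(kind = kind, sigma_sq = sigma_sq, q = q, a = a),
            class = "tuning_profile")
}

#' Von Mises kernel matrix on a grid
#'
#' `K(theta, theta') = exp(cos(theta - theta') / sigma^2)`, the kernel
#' induced by populations of von Mises tuning curves; the bandwidth
#' `sigma` controls how fast the kernel's Fourier spectrum decays (narrow
#' tuning keeps more high-frequency power).
#'
#' @param grid a one-dimensional [stimulus_grid()].
#' @param sigma tuning bandwidth; the kernel uses `1/sigma^2`.
#' @return a `pop_kernel`.
#' @export
von_mises_kernel <- function(grid, sigma) {
  th <- grid_angles(grid)
  new_kernel(exp(cos(outer(th, th, "-")) / sigma^2), grid)
}

#' Build a code with a prescribed kernel
#'
#' Factorizes the kernel through its measure-weighted spectrum,
#' `R = sqrt(N) * Q[, 1:K] %*% diag(sqrt(lambda)) %*% t(Psi)`, with `Q` a
#' seeded Haar-random orthogonal matrix. By construction
#' `compute_kernel(code, normalize = TRUE)` returns the input kernel, so
#' infinitely many codes (one per rotation `Q`) share the same kernel and
#' hence the same inductive bias.
#'
#' @param kernel a `pop_kernel` (PSD).
#' @param n_neurons number of neurons N; must be at least `rank(K)`.
#' @param seed integer seed for the Haar rotation.
#' @return a [population_code()].
#' @export
code_from_kernel <- function(kernel, n_neurons, seed = 1) {
  spec <- eigendecompose(kernel)
  k <- length(spec$eigenvalues)
  if (n_neurons < k) {
    stop_invalid("n_neurons (", n_neurons, ") is below the kernel rank (", k, ")",
                 class = "popkernel_rank_deficiency")
  }
  q <- haar_orthogonal(n_neurons, seed = seed)
  r <- sqrt(n_neurons) * q[, seq_len(k), drop = FALSE] %*%
    (sqrt(spec$eigenvalues) * t(spec$eigenfunctions))
  population_code(r, kernel$grid)
}

#' Von Mises tuning-curve population
#'
#' Two constructions of a code on a uniform circular grid whose kernel is
#' translation invariant with von Mises-type bandwidth `sigma`:
#' `mode = "profile"` places `n_neurons` tuning curves
#' `h(theta - theta_i) = exp((cos(theta - theta_i) - 1)/sigma^2)` with
#' preferred angles tiling the circle; `mode = "spectral"` builds a
#' kernel-matched code via [code_from_kernel()] whose kernel is exactly
#' `exp(cos(Delta)/sigma^2)`.
#'
#' @param n_neurons number of neurons.
#' @param sigma tuning bandwidth.
#' @param grid uniform circular [stimulus_grid()].
#' @param mode `"spectral"` (exact kernel) or `"profile"` (tuning curves).
#' @param seed seed for the spectral-mode rotation.
#' @return a [population_code()].
#' @export
von_mises_population <- function(n_neurons, sigma, grid,
                                 mode = c("spectral", "profile"), seed = 1) {
  mode <- match.arg(mode)
  if (!is_uniform_circular(grid)) {
    stop_invalid("von Mises populations require a uniform circular grid",
                 class = "popkernel_unsupported_grid")
  }
  if (mode == "spectral") {
    return(code_from_kernel(von_mises_kernel(grid, sigma), n_neurons, seed = seed))
  }
  th <- grid_angles(grid)
  pref <- seq(0, grid$period[1], length.out = n_neurons + 1)[seq_len(n_neurons)]
  r <- exp((cos(outer(pref, th, "-")) - 1) / sigma^2)
  population_code(r, grid)
}

gabor_drive <- function(theta, theta_i, sigma_sq) {
  cosh(cos(theta - theta_i) / sigma_sq) / cosh(1 / sigma_sq)
}

#' Simple-cell orientation response
#'
#' Threshold-power-law response `g_{q,a}(z) = max(0, z - a)^q` to the
#' orientation drive `z = cosh(cos(theta - theta_i)/sigma^2) /
#' cosh(1/sigma^2)`; periodic in `theta` with period `pi`. At the preferred
#' orientation the response is `(1 - a)^q`.
#'
#' @param theta stimulus orientation(s), radians.
#' @param theta_i preferred orientation, radians.
#' @param profile a [tuning_profile()] with `kind = "gabor_simple"`.
#' @return numeric response(s).
#' @export
gabor_simple_response <- function(theta, theta_i, profile) {
  stopifnot(inherits(profile, "tuning_profile"))
  if (profile$kind != "gabor_simple") stop_invalid("profile kind must be gabor_simple")
  z <- gabor_drive(theta, theta_i, profile$sigma_sq)
  pmax(0, z - profile$a)^profile$q
}

#' Threshold giving a desired coding level
#'
#' A simple cell with drive precision `sigma^-2` fires on a fraction `f`
#' of uniformly sampled orientations exactly when the threshold is
#' `a = cosh(sigma^-2 * cos(pi*f/2)) / cosh(sigma^-2)`; `f = 1` puts the
#' threshold at the tuning minimum `1/cosh(sigma^-2)`. `a` is strictly
#' decreasing in `f`.
#'
#' @param f coding level (firing fraction), `0 < f <= 1`.
#' @param sigma_inv_sq drive precision `sigma^-2`.
#' @return threshold `a`.
#' @export
threshold_from_coding_level <- function(f, sigma_inv_sq) {
  if (!is.numeric(f) || any(f <= 0) || any(f > 1)) {
    stop_invalid("coding level f must lie in (0, 1]")
  }
  cosh(sigma_inv_sq * cos(pi * f / 2)) / cosh(sigma_inv_sq)
}

#' Gabor mixture specification
#'
#' @param s simple-cell fraction in `[0, 1]`.
#' @param n_neurons total number of cells.
#' @param n_theta,n_phi orientation/phase grid sizes of the stimulus grid.
#' @return an object of class `gabor_mixture_spec`.
#' @export
gabor_mixture_spec <- function(s, n_neurons, n_theta = 24, n_phi = 12) {
  if (!is.numeric(s) || s < 0 || s > 1) stop_invalid("s must lie in [0, 1]")
  if (n_neurons < 1) stop_invalid("population must be nonempty")
  structure(list(s = s, n_neurons = n_neurons, n_theta = n_theta, n_phi = n_phi),
            class = "gabor_mixture_spec")
}

#' Mixed simple/complex cell population on an orientation-phase grid
#'
#' Generates `round(s * N)` simple cells and the remaining complex cells on
#' the `(theta, phi)` product grid. A simple cell with preferred pair
#' `(theta_i, phi_i)` responds `g_{q,a}(z(theta, theta_i) * cos(phi - phi_i))`:
#' a phase-modulated Gabor drive through the threshold-power nonlinearity.
#' A complex cell is the Adelson-Bergen energy model -- the sum of squares
#' of two quadrature-phase drives, `z^2 * (cos^2 + sin^2) = z(theta,
#' theta_i)^2` -- scaled by `(1 - a)^q` so its peak matches the simple-cell
#' peak; it is exactly independent of phase. Preferred orientations tile
#' their period deterministically; simple-cell preferred phases follow a
#' golden-ratio progression so phase is covered quasi-uniformly for any
#' cell count. The population kernel approximates the convex mixture
#' `s * Ks + (1 - s) * Kc` of the pure simple and pure complex kernels.
#'
#' @param spec a [gabor_mixture_spec()].
#' @param profile a [tuning_profile()] (`sigma_sq`, `q`, `a` are used).
#' @param seed reserved for jitter options; tiling itself is deterministic.
#' @return a [population_code()] on an [orientation_phase_grid()].
#' @export
gabor_mixture_code <- function(spec, profile, seed = 1) {
  stopifnot(inherits(spec, "gabor_mixture_spec"), inherits(profile, "tuning_profile"))
  grid <- orientation_phase_grid(spec$n_theta, spec$n_phi)
  theta <- grid$values[, 1]
  phi <- grid$values[, 2]
  n_s <- round(spec$s * spec$n_neurons)
  n_c <- spec$n_neurons - n_s
  rows <- list()
  if (n_s > 0) {
    pref_th <- pi * (seq_len(n_s) - 1) / n_s
    golden <- (sqrt(5) - 1) / 2
    pref_ph <- 2 * pi * ((seq_len(n_s) - 1) * golden %% 1)
    rows$simple <- t(vapply(seq_len(n_s), function(i) {
      z <- gabor_drive(theta, pref_th[i], profile$sigma_sq)
      pmax(0, z * cos(phi - pref_ph[i]) - profile$a)^profile$q
    }, numeric(length(theta))))
  }
  if (n_c > 0) {
    pref_th <- pi * (seq_len(n_c) - 1) / n_c
    rows$complex <- t(vapply(seq_len(n_c), function(i) {
      (1 - profile$a)^profile$q * gabor_drive(theta, pref_th[i], profile$sigma_sq)^2
    }, numeric(length(theta))))
  }
  population_code(do.call(rbind, rows), grid)
}

# Model translation profile of a pure simple-cell orientation kernel:
# K(Delta) = < g(z(Delta, t)) g(z(0, t)) > over preferred angles t,
# integrated numerically on a dense uniform tiling.
gabor_model_profile <- function(lags, sigma_sq, q, a, n_pref = 360) {
  pref <- pi * (seq_len(n_pref) - 1) / n_pref
  g0 <- pmax(0, gabor_drive(0, pref, sigma_sq) - a)^q
  vapply(lags, function(d) {
    gd <- pmax(0, gabor_drive(d, pref, sigma_sq) - a)^q
    mean(gd * g0)
  }, numeric(1))
}

#' Fit Gabor-model parameters to a kernel profile
#'
#' Least-squares fit of the orientation-averaged simple-cell model kernel
#' to an observed translation profile (from [translation_average()]).
#' Free parameters are `(sigma_sq, q)`; the threshold `a` is tied to
#' `sigma_sq` through the coding level `f` via
#' [threshold_from_coding_level()], mirroring how sparsity constrains the
#' nonlinearity. Optimization is Nelder-Mead on log-parameters.
#'
#' @param k_profile numeric vector `K(Delta)` over uniform lags covering
#'   one orientation period `[0, pi)`.
#' @param f coding level in `(0, 1]` used to tie `a` to `sigma_sq`.
#' @param init optional starting values `c(sigma_sq, q)`.
#' @param n_pref number of preferred angles for numeric integration.
#' @return list with `sigma_sq`, `q`, `a`, `loss`, `converged`, and
#'   `degenerate` (constant input profile; no fit attempted). Failure to
#'   converge is flagged, not raised.
#' @export
fit_gabor_kernel <- function(k_profile, f, init = c(0.25, 1.5), n_pref = 360) {
  if (!is.numeric(f) || f <= 0 || f > 1) stop_invalid("f must lie in (0, 1]")
  k_profile <- as.numeric(k_profile)
  lags <- pi * (seq_along(k_profile) - 1) / length(k_profile)
  if (stats::var(k_profile) < 1e-14 * max(mean(k_profile)^2, 1e-300)) {
    return(list(sigma_sq = NA_real_, q = NA_real_, a = NA_real_,
                loss = NA_real_, converged = FALSE, degenerate = TRUE))
  }
  loss_fn <- function(par) {
    sigma_sq <- exp(par[1]); q <- exp(par[2])
    a <- threshold_from_coding_level(f, 1 / sigma_sq)
    mod <- gabor_model_profile(lags, sigma_sq, q, a, n_pref = n_pref)
    mean((mod - k_profile)^2)
  }
  fit <- stats::optim(log(init), loss_fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  sigma_sq <- exp(fit$par[1])
  list(
    sigma_sq = sigma_sq,
    q = exp(fit$par[2]),
    a = threshold_from_coding_level(f, 1 / sigma_sq),
    loss = fit$value,
    converged = fit$convergence == 0,
    degenerate = FALSE
  )
}

#' Evaluate the Gabor-model fit objective at given parameters
#'
#' Utility for diagnostics: squared-error loss of the model profile
#' against an observed profile at `(sigma_sq, q)` with `a` tied via `f`.
#'
#' @inheritParams fit_gabor_kernel
#' @param sigma_sq,q model parameters.
#' @return scalar loss.
#' @export
gabor_fit_loss <- function(k_profile, f, sigma_sq, q, n_pref = 360) {
  lags <- pi * (seq_along(k_profile) - 1) / length(k_profile)
  a <- threshold_from_coding_level(f, 1 / sigma_sq)
  mod <- gabor_model_profile(lags, sigma_sq, q, a, n_pref = n_pref)
  mean((mod - as.numeric(k_profile))^2)
}
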