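#' Cue input sequence for the delayed-response task
#'
#' Two-dimensional step input `theta(t) = H(t) H(1 - t) [cos g, sin g]`:
#' equal to the cue vector `(cos gamma, sin gamma)` for `t` in `[0, 1]`
#' (Heaviside convention `H(0) = 1`, so the window is closed at both
#' ends) and zero afterwards.
#'
#' @param gamma cue angle (radians).
#' @param times numeric time grid covering `[0, T_end]`.
#' @return length(times) x 2 matrix.
#' @export
make_input_sequence <- function(gamma, times) {
  on <- as.numeric(times >= 0 & times <= 1)
  cbind(on * cos(gamma), on * sin(gamma))
}

#' Target sequence for a delayed-response task
#'
#' `y(t) = H(1.5 + d - t) H(t - d - 1) [cos g, sin g]`: the cue vector
#' must be reproduced during the response window `[1 + d, 1.5 + d]`
#' (closed, `H(0) = 1`) and zero elsewhere. Larger delays `d` make the
#' task harder for a fixed temporal code.
#'
#' @param gamma cue angle (radians).
#' @param d delay (time units, `>= 0`).
#' @param times numeric time grid; must reach the end of the response
#'   window.
#' @return length(times) x 2 matrix.
#' @export
make_target_sequence <- function(gamma, d, times) {
  if (d < 0) stop_invalid("delay must be >= 0")
  if (length(times) > 1 && max(times) < 1.5 + d) {
    # pointwise evaluation is always allowed; a grid must cover the window
    stop_invalid("time grid ends at ", max(times),
                 " but the response window extends to ", 1.5 + d)
  }
  on <- as.numeric(times >= 1 + d & times <= 1.5 + d)
  cbind(on * cos(gamma), on * sin(gamma))
}

#' Simulate a rate-based recurrent reservoir on cue sequences
#'
#' Integrates the standard rate model
#' `tau du/dt = -u + g J tanh(u) + W_in theta(t)` by fixed-step Euler
#' integration from `u(0) = 0`, with recurrent weights `J` i.i.d. normal
#' of variance `1/N` and input columns `W_in` i.i.d. standard normal
#' (scaled by `input_scale`). The stored code is `tanh(u)` (or `u` with
#' `responses = "u"`) sampled on `n_store` equally spaced stored times;
#' responses for all sequences are flattened over (sequence, time) into a
#' single `N x (PT)` response matrix with a recorded index map, so the
#' kernel/theory/readout machinery applies unchanged.
#'
#' @param angles cue angles `gamma_mu` (one sequence per angle).
#' @param n_neurons network size N.
#' @param gain recurrent gain `g` (chaos onset near `g = 1`).
#' @param tau time constant.
#' @param t_end end of integration window.
#' @param n_store number of stored time points per sequence.
#' @param dt Euler step; default `tau/10`. Must satisfy `dt <= tau/5`.
#' @param seed master seed; `J` and `W_in` use derived streams.
#' @param input_scale multiplier on the input weights.
#' @param responses store `"tanh"` (default) or raw `"u"`.
#' @return object of class `temporal_code`: `responses` (N x PT),
#'   `index` (data frame with `sequence`, `time`), `times` (stored grid),
#'   `angles`, `grid` (uniform [stimulus_grid()] over the PT flattened
#'   points), and the network parameters.
#' @export
simulate_reservoir <- function(angles, n_neurons = 500, gain = 1.5, tau = 0.05,
                               t_end = 3, n_store = 50, dt = tau / 10, seed = 1,
                               input_scale = 1, responses = c("tanh", "u")) {
  responses <- match.arg(responses)
  if (dt > tau / 5 + 1e-12) stop_invalid("dt must be <= tau/5 for stable Euler integration")
  n_steps <- ceiling(t_end / dt)
  store_idx <- unique(round(seq(1, n_steps + 1, length.out = n_store)))
  times <- (store_idx - 1) * dt
  J <- withr::with_seed(derive_seed(seed, 1),
                        matrix(stats::rnorm(n_neurons^2, sd = 1 / sqrt(n_neurons)),
                               n_neurons, n_neurons))
  W_in <- withr::with_seed(derive_seed(seed, 2),
                           matrix(stats::rnorm(2 * n_neurons), n_neurons, 2)) * input_scale
  p_seq <- length(angles)
  inputs <- lapply(angles, make_input_sequence, times = (0:n_steps) * dt)
  U <- matrix(0, n_neurons, p_seq)                 # state, all sequences at once
  out <- matrix(0, n_neurons, p_seq * length(times))
  store_pos <- 1L
  for (step in 1:(n_steps + 1)) {
    if (store_pos <= length(store_idx) && step == store_idx[store_pos]) {
      val <- if (responses == "tanh") tanh(U) else U
      out[, (store_pos - 1) * p_seq + seq_len(p_seq)] <- val
      store_pos <- store_pos + 1L
    }
    if (step > n_steps) break
    theta_t <- t(vapply(inputs, function(ip) ip[step, ], numeric(2)))  # p_seq x 2
    drive <- gain * (J %*% tanh(U)) + W_in %*% t(theta_t)
    U <- U + (dt / tau) * (-U + drive)
    if (!all(is.finite(U))) {
      stop_invalid("reservoir state diverged (non-finite activity)",
                   class = "popkernel_instability")
    }
  }
  # reorder so flattening is sequence-major: (mu = 1, all t), (mu = 2, all t), ...
  idx_df <- data.frame(
    sequence = rep(seq_len(p_seq), each = length(times)),
    time = rep(times, times = p_seq)
  )
  flat <- matrix(0, n_neurons, nrow(idx_df))
  for (mu in seq_len(p_seq)) {
    cols <- (seq_along(times) - 1) * p_seq + mu
    flat[, (mu - 1) * length(times) + seq_along(times)] <- out[, cols]
  }
  grid <- stimulus_grid(cbind(idx_df$sequence, idx_df$time))
  structure(
    list(responses = flat, index = idx_df, times = times, angles = angles,
         grid = grid, n_neurons = n_neurons, gain = gain, tau = tau,
         dt = dt, seed = seed, input_scale = input_scale),
    class = "temporal_code"
  )
}

#' @export
print.temporal_code <- function(x, ...) {
  cat(sprintf(
    "<temporal_code: %d neurons, %d sequences x %d times (gain %.2f, tau %.3g)>\n",
    x$n_neurons, length(x$angles), length(x$times), x$gain, x$tau
  ))
  invisible(x)
}

#' Kernel of a temporal code over flattened (sequence, time) points
#'
#' The `PT x PT` gram matrix `(1/N) <r(gamma_mu, t), r(gamma_nu, t')>`
#' over all flattened points, with the uniform measure. Same-sequence and
#' equal-time slices can be extracted through the code's `index` map.
#'
#' @param code a `temporal_code`.
#' @return a `pop_kernel` on the flattened grid.
#' @export
temporal_kernel <- function(code) {
  stopifnot(inherits(code, "temporal_code"))
  new_kernel(crossprod(code$responses) / code$n_neurons, code$grid)
}

#' Participation ratio of a kernel spectrum
#'
#' `(sum lambda)^2 / sum lambda^2`, an effective dimensionality of the
#' representation. Computed directly from the kernel matrix as
#' `tr(K)^2 / ||K||_F^2` (the measure weighting cancels on uniform
#' grids), so no eigendecomposition is needed.
#'
#' @param kernel a `pop_kernel` (uniform measure) or `kernel_spectrum`.
#' @return scalar participation ratio.
#' @export
participation_ratio <- function(kernel) {
  if (inherits(kernel, "kernel_spectrum")) {
    lam <- kernel$eigenvalues
    return(sum(lam)^2 / sum(lam^2))
  }
  stopifnot(inherits(kernel, "pop_kernel"))
  k <- kernel$matrix
  sum(diag(k))^2 / sum(k^2)
}

#' Full target matrix for the delayed-response task on a temporal code
#'
#' Evaluates [make_target_sequence()] for every (sequence, time) point of
#' the flattened code.
#'
#' @param code a `temporal_code`.
#' @param d delay.
#' @return PT x 2 matrix aligned with the code's flattened columns.
#' @export
delay_task_targets <- function(code, d) {
  stopifnot(inherits(code, "temporal_code"))
  y <- matrix(0, nrow(code$index), 2)
  for (mu in seq_along(code$angles)) {
    rows <- which(code$index$sequence == mu)
    y[rows, ] <- make_target_sequence(code$angles[mu], d, code$index$time[rows])
  }
  y
}

#' Learning experiment on a temporal code across delays
#'
#' For each delay: builds the delayed-response targets over all PT
#' flattened points, computes the theory curve from the temporal kernel's
#' spectrum, the cumulative power distribution, and the empirical learning
#' curve obtained by randomly sampling P of the PT points (training-set
#' draws i.i.d. uniform with replacement) and fitting the readout.
#'
#' @param code a `temporal_code`.
#' @param delays numeric delays `d`.
#' @param p_grid sample sizes.
#' @param repeats Monte-Carlo repeats per P.
#' @param ridge `lambda >= 0`.
#' @param seed master seed.
#' @return list (one element per delay) of lists with `delay`, `theory`
#'   (a `theory_curve`), `empirical` (an `empirical_curve`), and
#'   `cumulative_power`.
#' @export
temporal_learning_experiment <- function(code, delays, p_grid, repeats = 20,
                                         ridge = 0, seed = 1) {
  stopifnot(inherits(code, "temporal_code"))
  kern <- temporal_kernel(code)
  spec <- eigendecompose(kern)
  pc <- population_code(code$responses, code$grid)
  lapply(seq_along(delays), function(i) {
    d <- delays[i]
    y <- delay_task_targets(code, d)
    dec <- decompose_target(y, spec)
    list(
      delay = d,
      theory = learning_curve(spec, dec, p_grid, ridge = ridge),
      empirical = empirical_learning_curve(pc, y, p_grid, repeats = repeats,
                                           ridge = ridge,
                                           seed = derive_seed(seed, i)),
      cumulative_power = cumulative_power(dec)
    )
  })
}
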