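#' Training set of stimulus-response examples
#'
#' Indices into the code's stimulus grid (sampled i.i.d. from the grid
#' measure, with replacement) together with the target values at those
#' stimuli.
#'
#' @param indices integer stimulus indices `mu = 1..P`.
#' @param targets numeric vector of length P (or P x D matrix).
#' @return object of class `training_set`.
#' @export
training_set <- function(indices, targets) {
  indices <- as.integer(indices)
  if (length(indices) < 1 || any(indices < 1)) stop_invalid("need P >= 1 valid indices")
  targets <- as.matrix(targets)
  if (nrow(targets) != length(indices)) stop_invalid("one target row per index required")
  structure(list(indices = indices, targets = targets), class = "training_set")
}

#' Sample a training set from the grid measure
#'
#' @param code a [population_code()].
#' @param y full target vector/matrix over the grid.
#' @param P number of examples (drawn i.i.d. with replacement from `p`).
#' @param seed integer seed.
#' @return a [training_set()].
#' @export
sample_training_set <- function(code, y, P, seed) {
  y <- as.matrix(y)
  m <- n_stimuli(code$grid)
  if (nrow(y) != m) stop_invalid("target must cover the grid")
  idx <- withr::with_seed(seed,
    sample.int(m, P, replace = TRUE, prob = code$grid$probabilities))
  training_set(idx, y[idx, , drop = FALSE])
}

#' Train a readout with the biologically plausible delta rule
#'
#' Batch delta-rule updates on N-normalized features `phi = r/sqrt(N)`:
#' `w <- w + eta * (Phi %*% (y - t(Phi) %*% w) - weight_decay * w)`,
#' iterated until `max(abs(delta w)) < tol`. With this normalization the
#' weight-decay constant coincides with the gram-matrix ridge, so the
#' converged readout's predictions equal kernel (ridge) regression
#' `k(theta)' (K + lambda I)^-1 y` (pseudo-inverse when ridgeless); the
#' fixed point, not the trajectory, is what determines generalization.
#'
#' @param code a [population_code()].
#' @param data a [training_set()].
#' @param eta learning rate; default `1/(2*lmax)` where `lmax` is the top
#'   eigenvalue of the empirical feature covariance. Values at or above
#'   the stability bound `2/lmax` are rejected.
#' @param weight_decay ridge `lambda >= 0` (gram-matrix convention).
#' @param max_iters,tol iteration cap and convergence tolerance on the
#'   weight update.
#' @return object of class `readout_model`: `weights` (N x D), `eta`,
#'   `weight_decay`, `iterations`, `converged`.
#' @export
delta_rule_train <- function(code, data, eta = NULL, weight_decay = 0,
                             max_iters = 1e6, tol = 1e-10) {
  stopifnot(inherits(code, "population_code"), inherits(data, "training_set"))
  n <- n_neurons(code)
  phi <- code$responses[, data$indices, drop = FALSE] / sqrt(n)
  y <- data$targets
  cov_top <- max(eigen(tcrossprod(phi), symmetric = TRUE, only.values = TRUE)$values)
  lmax <- cov_top + weight_decay
  if (is.null(eta)) eta <- 1 / (2 * lmax)
  if (eta <= 0 || eta >= 2 / lmax) {
    stop_invalid("eta = ", format(eta), " is outside the stable range (0, ",
                 format(2 / lmax), "); suggested eta = ", format(1 / (2 * lmax)),
                 class = "popkernel_learning_rate")
  }
  w <- matrix(0, n, ncol(y))
  w_scale <- max(sqrt(sum(y^2)), 1)
  it <- 0L
  converged <- FALSE
  while (it < max_iters) {
    it <- it + 1L
    dw <- eta * (phi %*% (y - crossprod(phi, w)) - weight_decay * w)
    w <- w + dw
    if (!all(is.finite(w)) || sqrt(sum(w^2)) > 1e8 * w_scale) {
      stop_invalid("delta rule diverged; reduce eta (suggested ",
                   format(1 / (2 * lmax)), ")", class = "popkernel_learning_rate")
    }
    if (max(abs(dw)) < tol) { converged <- TRUE; break }
  }
  structure(
    list(weights = w, eta = eta, weight_decay = weight_decay,
         iterations = it, converged = converged),
    class = "readout_model"
  )
}

#' Predict from a trained readout on the full grid
#'
#' @param object a `readout_model`.
#' @param code the [population_code()] it was trained on.
#' @param ... unused.
#' @return M x D matrix of readout predictions `w . phi(theta)`.
#' @export
predict.readout_model <- function(object, code, ...) {
  crossprod(code$responses / sqrt(n_neurons(code)), object$weights)
}

#' Kernel (ridge) regression prediction
#'
#' The closed-form fixed point of the delta rule:
#' `f(theta) = k(theta)' (K + lambda I)^-1 y`, where `k(theta)` holds the
#' kernel between `theta` and the training stimuli and `K` is the P x P
#' training gram matrix. Ridgeless (`lambda = 0`) uses the eigenvalue
#' pseudo-inverse with the package-wide rank floor `1e-12 * lambda_max`,
#' returning the least-norm interpolant.
#'
#' @param k_rows M x P matrix `K(theta_m, theta_mu)` at evaluation points.
#' @param gram P x P symmetric PSD training gram matrix.
#' @param y targets (length P vector or P x D matrix).
#' @param ridge `lambda >= 0`.
#' @return M x D matrix of predictions.
#' @export
kernel_regression_predict <- function(k_rows, gram, y, ridge = 0) {
  gram <- as.matrix(gram)
  scale <- max(abs(gram), 1e-300)
  if (max(abs(gram - t(gram))) > 1e-8 * scale) stop_invalid("gram matrix is not symmetric")
  ev_min <- min(eigen((gram + t(gram)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * scale) stop_invalid("gram matrix is not positive semidefinite")
  y <- as.matrix(y)
  alpha <- if (ridge > 0) {
    solve(gram + diag(ridge, nrow(gram)), y)
  } else {
    psd_pinv_solve(gram, y)
  }
  as.matrix(k_rows) %*% alpha
}

#' Empirical learning curve by Monte-Carlo dataset sampling
#'
#' For each sample size P and repeat: draw P stimuli i.i.d. from the grid
#' measure (with replacement), fit the readout, and compute the exact
#' measure-weighted generalization error on the full grid,
#' `Eg(D) = sum_m p_m (f(theta_m) - y(theta_m))^2` (summed over output
#' dimensions). `P = 0` rows use the convention `Eg = ` total target power.
#'
#' @param code a [population_code()].
#' @param y target vector/matrix over the grid.
#' @param p_grid sample sizes (nonnegative integers).
#' @param repeats number of independent datasets per P (`>= 2`).
#' @param ridge `lambda >= 0` shared with the theory.
#' @param seed master seed; per-(P, repeat) streams are derived from it.
#' @param method `"regression"` (closed-form fixed point; default) or
#'   `"delta"` (iterate the delta rule to convergence).
#' @return object of class `empirical_curve`: data frame `curve` with
#'   columns `P`, `mean`, `sd`, `sem`, and matrix `errors`
#'   (repeats x length(p_grid)) of per-dataset `Eg(D)`.
#' @export
empirical_learning_curve <- function(code, y, p_grid, repeats = 30, ridge = 0,
                                     seed = 1, method = c("regression", "delta")) {
  method <- match.arg(method)
  stopifnot(inherits(code, "population_code"))
  if (repeats < 2) stop_invalid("repeats must be >= 2")
  y <- as.matrix(y)
  p <- code$grid$probabilities
  kernel <- compute_kernel(code, normalize = TRUE)
  errors <- matrix(NA_real_, repeats, length(p_grid))
  total_power <- sum(p * y^2)
  for (j in seq_along(p_grid)) {
    P <- p_grid[j]
    for (rep in seq_len(repeats)) {
      if (P == 0) { errors[rep, j] <- total_power; next }
      ts <- sample_training_set(code, y, P, derive_seed(seed, j * 100003 + rep))
      f <- if (method == "regression") {
        kernel_regression_predict(
          kernel$matrix[, ts$indices, drop = FALSE],
          kernel$matrix[ts$indices, ts$indices, drop = FALSE],
          ts$targets, ridge
        )
      } else {
        model <- delta_rule_train(code, ts, weight_decay = ridge)
        predict(model, code)
      }
      errors[rep, j] <- sum(p * (f - y)^2)
    }
  }
  mu <- colMeans(errors)
  sdv <- apply(errors, 2, stats::sd)
  structure(
    list(
      curve = data.frame(P = p_grid, mean = mu, sd = sdv,
                         sem = sdv / sqrt(repeats)),
      errors = errors, ridge = ridge, repeats = repeats
    ),
    class = "empirical_curve"
  )
}

#' @export
print.empirical_curve <- function(x, ...) {
  cat(sprintf("<empirical_curve: %d sample sizes x %d repeats, ridge %.3g>\n",
              nrow(x$curve), x$repeats, x$ridge))
  print(x$curve)
  invisible(x)
}
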