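#' Decompose a target function in the kernel eigenbasis
#'
#' Projects target values `y(theta_m)` (a vector, or an M x D matrix for
#' D-dimensional targets) onto the measure-orthonormal eigenfunctions:
#' `v_k = sum_m p_m y(theta_m) psi_k(theta_m)`. The coefficients `v_k`
#' determine which kernel eigenmodes carry the target's power; any power
#' outside the span of the (nonzero-eigenvalue) eigenfunctions is reported
#' as residual and is unlearnable by the readout.
#'
#' @param y numeric vector of length M, or M x D matrix.
#' @param spectrum a `kernel_spectrum` from [eigendecompose()].
#' @return object of class `target_decomposition`: `coefficients` (K x D
#'   matrix of `v_k`), `total_power` (per output dim, `sum_m p_m y_m^2`),
#'   `residual_power` (out-of-span power per dim), and `spectrum`.
#' @export
decompose_target <- function(y, spectrum) {
  stopifnot(inherits(spectrum, "kernel_spectrum"))
  y <- as.matrix(y)
  m <- nrow(spectrum$eigenfunctions)
  if (nrow(y) != m) {
    stop_invalid("target has ", nrow(y), " values but the grid has ", m, " stimuli")
  }
  p <- spectrum$grid$probabilities
  v <- crossprod(spectrum$eigenfunctions, p * y)            # K x D
  total <- colSums(p * y^2)
  residual <- pmax(total - colSums(v^2), 0)
  structure(
    list(coefficients = v, total_power = total, residual_power = residual,
         spectrum = spectrum),
    class = "target_decomposition"
  )
}

#' Solve the implicit effective regularization kappa
#'
#' Returns the unique `kappa >= 0` solving the self-consistent equation
#' `kappa = ridge + kappa * sum_k lambda_k / (lambda_k * P + kappa)`.
#' `kappa(P)` interpolates between `ridge + sum(lambda)` at `P = 0` and
#' `ridge` as `P -> Inf`; it acts as a sample-size-dependent implicit
#' regularizer of the readout. Solved by bracketed root finding on
#' `g(kappa) = kappa - ridge - kappa * sum_k lambda_k/(lambda_k P + kappa)`
#' followed by Newton polishing (`g'(kappa) = 1 - gamma(kappa)`); in the
#' ridgeless case with `P >=` the number of nonzero modes the solution is
#' exactly 0.
#'
#' @param eigenvalues nonnegative kernel eigenvalues.
#' @param P sample size (continuous, `>= 0`).
#' @param ridge explicit ridge `lambda >= 0` (gram-matrix convention
#'   `K + lambda I`).
#' @return scalar `kappa`.
#' @export
solve_kappa <- function(eigenvalues, P, ridge = 0) {
  lam <- as.numeric(eigenvalues)
  if (any(lam < 0) || any(!is.finite(lam))) stop_invalid("eigenvalues must be finite and >= 0")
  if (P < 0 || ridge < 0) stop_invalid("P and ridge must be >= 0")
  lam <- lam[lam > 0]
  tot <- sum(lam)
  if (P == 0 || length(lam) == 0) return(ridge + tot)
  if (ridge == 0 && P >= length(lam)) return(0)
  g <- function(kap) kap - ridge - kap * sum(lam / (lam * P + kap))
  upper <- ridge + tot
  lower <- max(ridge, 1e-300) * (1 + 1e-12) + 1e-300 * upper
  if (ridge == 0) lower <- upper * 1e-14
  if (g(lower) > 0 || g(upper) < 0) {
    # widen the lower end; a numerically degenerate spectrum may defeat it
    lower <- upper * 1e-18
    if (g(lower) > 0 || g(upper) < 0) {
      stop_invalid("no sign change when bracketing kappa; spectrum is degenerate",
                   class = "popkernel_kappa_bracket")
    }
  }
  kap <- stats::uniroot(g, c(lower, upper), tol = 1e-14 * upper)$root
  for (i in 1:8) {                                   # Newton polish: g' = 1 - gamma
    gp <- 1 - P * sum(lam^2 / (lam * P + kap)^2)
    if (abs(gp) < 1e-12) break
    step <- g(kap) / gp
    kap_new <- kap - step
    if (!is.finite(kap_new) || kap_new < 0) break
    kap <- kap_new
    if (abs(step) <= 1e-12 * max(kap, ridge, 1e-300)) break
  }
  kap
}

#' Analytical learning curve from a kernel spectrum and target
#'
#' For each sample size P on the grid, computes the effective
#' regularization `kappa(P)`, the effective fraction of variance
#' `gamma = P * sum_k lambda_k^2/(lambda_k P + kappa)^2`, the normalized
#' per-mode errors `E_k = kappa^2 / ((1 - gamma) (lambda_k P + kappa)^2)`,
#' the total generalization error `Eg = sum_k v_k^2 E_k` (plus any residual
#' out-of-span target power, carried through as an irreducible floor), and
#' the expected learned coefficients `lambda_k P/(lambda_k P + kappa) v_k`.
#'
#' @param spectrum a `kernel_spectrum`.
#' @param decomposition a [decompose_target()] result (or a coefficient
#'   vector aligned with the eigenvalues, taken to have zero residual).
#' @param p_grid nonnegative sample sizes.
#' @param ridge explicit ridge `lambda >= 0`.
#' @return object of class `theory_curve`: data frame `curve` with columns
#'   `P`, `kappa`, `gamma`, `Eg`, plus `mode_errors` (K x length(P)),
#'   `learned_coefficients` (K x D x length(P) array), `ridge`.
#' @export
learning_curve <- function(spectrum, decomposition, p_grid, ridge = 0) {
  stopifnot(inherits(spectrum, "kernel_spectrum"))
  if (!inherits(decomposition, "target_decomposition")) {
    v <- as.matrix(as.numeric(decomposition))
    decomposition <- structure(
      list(coefficients = v, total_power = colSums(v^2),
           residual_power = rep(0, ncol(v)), spectrum = spectrum),
      class = "target_decomposition"
    )
  }
  lam <- spectrum$eigenvalues
  v <- decomposition$coefficients
  if (nrow(v) != length(lam)) stop_invalid("coefficients not aligned with eigenvalues")
  p_grid <- as.numeric(p_grid)
  if (any(p_grid < 0)) stop_invalid("sample sizes must be >= 0")
  resid <- sum(decomposition$residual_power)
  nk <- length(lam); np <- length(p_grid); nd <- ncol(v)
  mode_err <- matrix(NA_real_, nk, np)
  learned <- array(NA_real_, c(nk, nd, np))
  kappa <- gamma <- eg <- numeric(np)
  for (j in seq_len(np)) {
    P <- p_grid[j]
    kap <- solve_kappa(lam, P, ridge)
    if (kap == 0) {                       # ridgeless interpolation regime
      gam <- if (P > 0) length(lam) / P else 0
      ek <- rep(0, nk)
    } else {
      gam <- P * sum(lam^2 / (lam * P + kap)^2)
      if (gam >= 1) {
        stop_invalid("gamma >= 1 encountered (numerically degenerate curve)",
                     class = "popkernel_gamma_degenerate")
      }
      ek <- kap^2 / ((1 - gam) * (lam * P + kap)^2)
    }
    kappa[j] <- kap; gamma[j] <- gam
    mode_err[, j] <- ek
    learned[, , j] <- (lam * P / (lam * P + kap)) * v
    eg[j] <- sum(v^2 * ek) + resid
  }
  structure(
    list(
      curve = data.frame(P = p_grid, kappa = kappa, gamma = gamma, Eg = eg),
      mode_errors = mode_err,
      learned_coefficients = learned,
      eigenvalues = lam,
      ridge = ridge,
      residual_power = resid
    ),
    class = "theory_curve"
  )
}

#' @export
print.theory_curve <- function(x, ...) {
  cat(sprintf("<theory_curve: %d sample sizes, %d modes, ridge %.3g>\n",
              nrow(x$curve), length(x$eigenvalues), x$ridge))
  print(utils::head(x$curve, 8))
  invisible(x)
}

#' Cumulative power distribution C(k)
#'
#' Fraction of the target's in-span power carried by the top `k`
#' eigenmodes: `C(k) = sum_{l<=k} v_l^2 / sum_l v_l^2`, with modes ordered
#' by eigenvalue. A fast-rising `C(k)` means the code and task are aligned
#' and the task is learnable from few samples.
#'
#' @param decomposition a [decompose_target()] result or coefficient vector.
#' @param k optional mode counts at which to evaluate; defaults to `1:K`.
#' @return numeric vector `C(k)`, nondecreasing with `C(K) = 1`.
#' @export
cumulative_power <- function(decomposition, k = NULL) {
  v <- if (inherits(decomposition, "target_decomposition")) {
    decomposition$coefficients
  } else {
    as.matrix(as.numeric(decomposition))
  }
  pow <- rowSums(v^2)
  tot <- sum(pow)
  if (tot <= 0) {
    stop_invalid("target has zero power along every eigenmode; alignment undefined",
                 class = "popkernel_undefined_alignment")
  }
  ck <- cumsum(pow) / tot
  if (is.null(k)) ck else ck[k]
}

#' Check the spectral-bias ordering of a theory curve
#'
#' Verifies that larger eigenvalues imply smaller normalized mode errors:
#' `lambda_k > lambda_l  =>  E_k(P) < E_l(P)` at every `P > 0` in the
#' curve (strict where eigenvalues differ by more than `1e-10`; degenerate
#' eigenvalues must give equal errors). Ties are judged at `1e-10` relative
#' to the mode-error scale, since double precision cannot resolve the
#' ordering when eigenvalues sit orders of magnitude below `kappa / P`.
#'
#' @param curve a `theory_curve`.
#' @return list with `n_violations` and a data frame `violations`
#'   (columns `P`, `k`, `l`) describing any ordering failures.
#' @export
spectral_bias_check <- function(curve) {
  stopifnot(inherits(curve, "theory_curve"))
  lam <- curve$eigenvalues
  viol <- list()
  for (j in seq_len(nrow(curve$curve))) {
    P <- curve$curve$P[j]
    if (P <= 0) next
    ek <- curve$mode_errors[, j]
    kap <- curve$curve$kappa[j]
    gam <- curve$curve$gamma[j]
    mode_error_at <- function(lm) {
      if (kap == 0) 0 else kap^2 / ((1 - gam) * (lm * P + kap)^2)
    }
    for (k in seq_along(lam)[-length(lam)]) {
      l <- k + 1                       # eigenvalues are sorted nonincreasing
      # mode errors can exceed 1 near the interpolation threshold (the
      # 1/(1 - gamma) factor), so ties are judged relative to their scale
      scale_tol <- 1e-10 * max(1, abs(ek[k]), abs(ek[l]))
      if (lam[k] > lam[l] + 1e-10) {
        # strict ordering up to floating point: errors for eigenvalues far
        # below kappa/P approach the common limit 1/(1 - gamma) and tie in
        # double precision; only a reversal beyond tolerance is a violation
        if (ek[k] - ek[l] > scale_tol) viol[[length(viol) + 1]] <- c(P, k, l)
      } else {
        # near-degenerate eigenvalues: any spread must be explained by the
        # curve's own error formula applied to the (tiny) eigenvalue split
        analytic <- abs(mode_error_at(lam[k]) - mode_error_at(lam[l]))
        if (abs(ek[k] - ek[l]) > scale_tol + analytic) {
          viol[[length(viol) + 1]] <- c(P, k, l)
        }
      }
    }
  }
  violations <- if (length(viol)) {
    as.data.frame(do.call(rbind, viol)) |> stats::setNames(c("P", "k", "l"))
  } else {
    data.frame(P = numeric(), k = numeric(), l = numeric())
  }
  list(n_violations = nrow(violations), violations = violations)
}

#' Export a theory curve as a delimited table
#'
#' Writes `P`, `kappa`, `gamma`, `Eg`, then one `Ek_<k>` column per mode.
#'
#' @param curve a `theory_curve`.
#' @param path output path (TSV).
#' @return invisibly, the written data frame.
#' @export
write_theory_curve <- function(curve, path) {
  ek <- t(curve$mode_errors)
  colnames(ek) <- paste0("Ek_", seq_len(ncol(ek)))
  out <- cbind(curve$curve, as.data.frame(ek))
  utils::write.table(format(out, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}
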