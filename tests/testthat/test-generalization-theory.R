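test_that("target decomposition respects orthonormality and quadrature", {
  grid <- circle120()
  spec <- fourier_spectrum(grid, 20)
  expect_lt(rel_frob(mercer_reconstruct(spec)$matrix,
                     fourier_sum_kernel(grid, 20)$matrix), 1e-10)

  y1 <- spec$eigenfunctions[, 1]
  d1 <- decompose_target(y1, spec)
  v <- drop(d1$coefficients)
  expect_equal(v[1], 1, tolerance = 1e-10)
  expect_lt(max(abs(v[-1])), 1e-10)
  expect_lt(d1$residual_power, 1e-10)

  th <- drop(grid$values)
  y <- cos(6 * th) - cos(8 * th)
  d <- decompose_target(y, spec)
  pow <- drop(d$coefficients)^2
  big <- which(pow > 1e-16)
  expect_length(big, 2)
  expect_equal(unname(pow[big]), c(0.5, 0.5), tolerance = 1e-10)
  # quadrature oracle: v_k = sum_m p_m y psi_k computed independently
  expect_equal(unname(big),
               unname(which(vapply(seq_len(40), function(k) {
                 abs(mean(y * spec$eigenfunctions[, k])) > 1e-10
               }, logical(1)))))
  # Parseval under the measure
  expect_equal(sum(pow), sum(grid$probabilities * y^2), tolerance = 1e-10)

  # frequency 25 is outside the rank-40 kernel span
  y_out <- cos(25 * th)
  d_out <- decompose_target(y_out, spec)
  expect_lt(max(abs(d_out$coefficients)), 1e-10)
  expect_equal(d_out$residual_power, 0.5, tolerance = 1e-10)

  expect_error(decompose_target(y[-1], spec), "stimuli")
})

test_that("kappa matches its closed forms and limits", {
  lam <- c(2, 1, 0.25, 0.01)
  expect_equal(solve_kappa(lam, 0, ridge = 0.3), 0.3 + sum(lam), tolerance = 1e-12)
  expect_equal(solve_kappa(2, 0.5, 0), 1, tolerance = 1e-10)
  for (P in c(0.1, 0.4, 0.9)) {
    expect_equal(solve_kappa(5, P, 0), 5 * (1 - P), tolerance = 1e-9)
  }
  expect_lt(abs(solve_kappa(lam, 1e8, ridge = 0.3) - 0.3), 1e-6)
  expect_identical(solve_kappa(lam, 10, 0), 0)  # ridgeless past the rank
  # strictly decreasing in P below the rank
  ps <- c(0, 0.5, 1, 1.5, 2, 3)
  ks <- vapply(ps, function(P) solve_kappa(lam, P, 0), numeric(1))
  expect_true(all(diff(ks) < -1e-9))
  expect_error(solve_kappa(c(-1, 2), 1), ">= 0")
})

test_that("single-mode learning curve matches the algebraic solution", {
  grid <- uniform_circular_grid(8)
  spec <- structure(
    list(eigenvalues = 2, eigenfunctions = matrix(1, 8, 1), grid = grid),
    class = "kernel_spectrum"
  )
  ps <- c(0, 0.25, 0.5, 0.75, 1, 2)
  lc <- learning_curve(spec, 1, ps)
  expect_equal(lc$curve$Eg, pmax(1 - ps, 0), tolerance = 1e-10)
  expect_equal(lc$curve$Eg[1], 1)            # Eg(0) = total power exactly
  expect_equal(drop(lc$mode_errors[, 1]), 1) # every mode error is 1 at P = 0
})

test_that("mode errors are ordered by eigenvalue for a two-mode spectrum", {
  lam <- c(1, 0.01)
  grid <- uniform_circular_grid(4)
  spec <- structure(
    list(eigenvalues = lam, eigenfunctions = matrix(0, 4, 2), grid = grid),
    class = "kernel_spectrum"
  )
  ps <- c(0, 0.5, 1, 1.5, 1.9)
  lc <- learning_curve(spec, c(1, 1), ps)
  for (j in which(ps > 0)) {
    expect_lt(lc$mode_errors[1, j], lc$mode_errors[2, j])
  }
  chk <- spectral_bias_check(lc)
  expect_identical(chk$n_violations, 0L)
})

test_that("learning curves decrease with data when target power sits on top modes", {
  grid <- circle120()
  spec <- eigendecompose(von_mises_kernel(grid, 0.5))
  dec <- decompose_target(make_target("low_freq", grid), spec)
  lc <- learning_curve(spec, dec, c(0, 1, 2, 4, 8, 16, 32, 64, 120))
  expect_true(all(diff(lc$curve$Eg) < 1e-12))
  # kappa decreases strictly until the ridgeless interpolation regime
  # (P >= rank), where it is exactly zero
  kap <- lc$curve$kappa
  expect_true(all(diff(kap) < 0 | kap[-1] == 0))
  expect_identical(kap[length(kap)], 0)
  expect_true(all(lc$curve$gamma >= 0 & lc$curve$gamma < 1))
})

test_that("out-of-span residual power is an irreducible error floor", {
  grid <- circle120()
  spec <- eigendecompose(fourier_sum_kernel(grid, 20))
  th <- drop(grid$values)
  y <- cos(6 * th) + cos(30 * th)      # second term is unlearnable
  dec <- decompose_target(y, spec)
  lc <- learning_curve(spec, dec, c(0, 10, 40, 120))
  expect_equal(dec$residual_power, 0.5, tolerance = 1e-10)
  expect_true(all(lc$curve$Eg >= 0.5 - 1e-12))
  expect_equal(lc$curve$Eg[1], 1, tolerance = 1e-10)
})

test_that("cumulative power distribution behaves as an alignment measure", {
  expect_equal(cumulative_power(c(1, 0, 0)), c(1, 1, 1))
  expect_equal(cumulative_power(c(0, 0, 2)), c(0, 0, 1))
  grid <- circle120()
  spec <- fourier_spectrum(grid, 20)
  th <- drop(grid$values)
  dec <- decompose_target(cos(6 * th) - cos(8 * th), spec)
  ck <- cumulative_power(dec)
  expect_true(all(diff(ck) >= -1e-15))
  expect_equal(ck[length(ck)], 1, tolerance = 1e-12)
  jumps <- which(diff(c(0, ck)) > 1e-10)
  expect_length(jumps, 2)
  expect_equal(unname(ck[jumps]), c(0.5, 1), tolerance = 1e-10)
  # the jump locations sit at the cos6 and cos8 eigenmodes
  pow <- drop(dec$coefficients)^2
  expect_equal(which(pow > 1e-10), jumps)
  expect_error(cumulative_power(c(0, 0, 0)),
               class = "popkernel_undefined_alignment")
})

test_that("degenerate eigenvalues give equal mode errors and a swap is detected", {
  grid <- uniform_circular_grid(4)
  spec <- structure(
    list(eigenvalues = c(1, 1, 0.1), eigenfunctions = matrix(0, 4, 3),
         grid = grid),
    class = "kernel_spectrum"
  )
  lc <- learning_curve(spec, c(1, 1, 1), c(0.5, 1))
  expect_lt(max(abs(lc$mode_errors[1, ] - lc$mode_errors[2, ])), 1e-10)
  expect_identical(spectral_bias_check(lc)$n_violations, 0L)

  tampered <- lc
  tampered$mode_errors[c(2, 3), 1] <- tampered$mode_errors[c(3, 2), 1]
  chk <- spectral_bias_check(tampered)
  expect_gt(chk$n_violations, 0)
})

test_that("theory curves export to a delimited table", {
  grid <- uniform_circular_grid(16)
  spec <- eigendecompose(k1_kernel(grid, 0.5))
  dec <- decompose_target(cos(drop(grid$values)), spec)
  lc <- learning_curve(spec, dec, c(0, 2, 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_theory_curve(lc, path)
  tab <- utils::read.delim(path)
  expect_equal(tab$Eg, lc$curve$Eg, tolerance = 1e-12)
  expect_true(all(paste0("Ek_", seq_along(spec$eigenvalues)) %in% names(tab)))
})
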