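test_that("kernel-matched codes differ across seeds but share the kernel exactly", {
  grid <- uniform_circular_grid(40)
  kern <- k1_kernel(grid)
  c1 <- code_from_kernel(kern, 40, seed = 1)
  c2 <- code_from_kernel(kern, 40, seed = 2)
  expect_gt(max(abs(c1$responses - c2$responses)), 0.1)
  expect_lt(max(abs(compute_kernel(c1)$matrix - compute_kernel(c2)$matrix)), 1e-10)
})

test_that("rank-1 kernel with one neuron gives the generating vector up to sign/scale", {
  grid <- uniform_circular_grid(12)
  v <- cos(drop(grid$values))
  kern <- new_kernel(outer(v, v), grid)
  code <- code_from_kernel(kern, 1, seed = 5)
  r <- drop(code$responses)
  expect_lt(min(max(abs(r - v)), max(abs(r + v))), 1e-8)
  expect_error(code_from_kernel(k1_kernel(grid), 1),
               class = "popkernel_rank_deficiency")
})

test_that("spectral-mode von Mises population has the exact von Mises kernel", {
  grid <- circle120()
  code <- von_mises_population(120, sigma = 0.5, grid, mode = "spectral", seed = 2)
  target <- exp(cos(outer(drop(grid$values), drop(grid$values), "-")) / 0.25)
  expect_lt(max(abs(compute_kernel(code)$matrix - target)), 1e-8)
})

test_that("narrower tuning keeps more high-frequency spectral power", {
  grid <- circle120()
  narrow <- eigendecompose(von_mises_kernel(grid, sigma = 0.4))
  wide <- eigendecompose(von_mises_kernel(grid, sigma = 1.2))
  # normalize scales so only the decay shape is compared
  expect_gt(narrow$eigenvalues[10] / narrow$eigenvalues[1],
            wide$eigenvalues[10] / wide$eigenvalues[1])
})

test_that("infinitely wide tuning collapses the kernel to rank one", {
  grid <- uniform_circular_grid(30)
  kern <- von_mises_kernel(grid, sigma = 1e6)
  ev <- eigen(kern$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-6)
  prof <- von_mises_population(30, sigma = 1e6, grid, mode = "profile")
  expect_lt(diff(range(prof$responses)), 1e-6)
})

test_that("profile-mode von Mises code has a translation-invariant kernel", {
  grid <- uniform_circular_grid(60)
  code <- von_mises_population(60, sigma = 0.7, grid, mode = "profile")
  kern <- compute_kernel(code)
  prof <- translation_average(kern)
  m <- 60
  rebuilt <- outer(seq_len(m), seq_len(m),
                   function(i, j) prof[((j - i) %% m) + 1])
  expect_lt(rel_frob(rebuilt, kern$matrix), 1e-8)
  expect_error(von_mises_population(10, 0.5, stimulus_grid(c(0, 0.2, 1))),
               class = "popkernel_unsupported_grid")
})

test_that("simple-cell response peaks at (1-a)^q and matches direct evaluation", {
  prof <- tuning_profile("gabor_simple", sigma_sq = 1 / 5, q = 1.7, a = 0.2)
  expect_equal(gabor_simple_response(1.1, 1.1, prof), 0.8^1.7, tolerance = 1e-12)
  for (ssq in c(0.1, 0.5, 2)) {
    p <- tuning_profile("gabor_simple", sigma_sq = ssq, q = 2, a = 0.3)
    expect_equal(gabor_simple_response(0.4, 0.4, p), 0.7^2, tolerance = 1e-12)
  }
  # period pi in orientation
  th <- seq(0, pi, length.out = 11)
  expect_equal(gabor_simple_response(th, 0.3, prof),
               gabor_simple_response(th + pi, 0.3, prof), tolerance = 1e-12)
})

test_that("coding-level threshold matches the counting oracle and is monotone", {
  expect_equal(threshold_from_coding_level(1, 5), 1 / cosh(5), tolerance = 1e-14)
  a <- threshold_from_coding_level(0.5, 5)
  th <- seq(0, pi, length.out = 1e4 + 1)[-(1e4 + 1)]
  z <- cosh(5 * cos(th)) / cosh(5)
  expect_lt(abs(mean(z > a) - 0.5), 1e-3)
  fs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(threshold_from_coding_level(fs, 5)) < 0))
  expect_error(threshold_from_coding_level(0, 5), "0, 1")
  # threshold at f = 1 sits at the tuning minimum: response positive
  # everywhere except the single minimizing offset
  prof <- tuning_profile("gabor_simple", sigma_sq = 0.2, q = 1,
                         a = threshold_from_coding_level(1, 5))
  th60 <- seq(0, pi, length.out = 61)[-61]
  resp <- gabor_simple_response(th60, 0, prof)
  expect_equal(sum(resp <= 1e-12), 1)  # only theta - theta_i = pi/2
})

test_that("complex cells are exactly phase invariant; simple cells are not", {
  prof <- tuning_profile("gabor_simple", sigma_sq = 0.2, q = 1.7, a = 0.2)
  c0 <- gabor_mixture_code(gabor_mixture_spec(0, 48, 12, 8), prof)
  th <- c0$grid$values[, 1]
  for (t in unique(th)) {
    cols <- which(th == t)
    spread <- apply(c0$responses[, cols, drop = FALSE], 1,
                    function(r) diff(range(r)))
    expect_lt(max(spread), 1e-10)
  }
  c1 <- gabor_mixture_code(gabor_mixture_spec(1, 96, 12, 8), prof)
  k1 <- compute_kernel(c1)$matrix
  same_th <- which(th == th[1])
  expect_gt(stats::var(k1[same_th[1], same_th]), 0)
  expect_error(gabor_mixture_code(gabor_mixture_spec(0.5, 0, 4, 4), prof),
               "nonempty")
})

test_that("pure complex-cell orientation kernel is translation invariant in theta", {
  prof <- tuning_profile("gabor_simple", sigma_sq = 0.2, q = 1.7, a = 0.2)
  c0 <- gabor_mixture_code(gabor_mixture_spec(0, 24, 24, 1), prof)
  # collapse to the orientation-only grid and check circulant structure
  th_grid <- uniform_circular_grid(24, period = pi)
  kern <- new_kernel(compute_kernel(c0)$matrix, th_grid)
  prof_k <- translation_average(kern)
  m <- 24
  rebuilt <- outer(seq_len(m), seq_len(m),
                   function(i, j) prof_k[((j - i) %% m) + 1])
  expect_lt(rel_frob(rebuilt, kern$matrix), 1e-8)
  # eigenvectors of a circulant PSD kernel are Fourier modes: DFT leakage
  spec <- eigendecompose(kern)
  f <- stats::mvfft(spec$eigenfunctions)
  # each eigenfunction concentrates on one frequency pair
  power <- abs(f)^2
  leak <- apply(power, 2, function(pw) {
    ord <- order(pw, decreasing = TRUE)
    1 - sum(pw[ord[1:2]]) / sum(pw)
  })
  expect_lt(max(leak), 1e-6)
})

test_that("Gabor kernel fit recovers generating parameters within 5%", {
  grid <- uniform_circular_grid(180, period = pi)
  th <- drop(grid$values)
  f <- 0.5
  a <- threshold_from_coding_level(f, 5)
  prof <- tuning_profile("gabor_simple", sigma_sq = 0.2, q = 1.7, a = a)
  pref <- pi * (0:179) / 180
  r <- t(vapply(pref, function(ti) gabor_simple_response(th, ti, prof),
                numeric(180)))
  k_prof <- translation_average(compute_kernel(population_code(r, grid)))
  fit <- fit_gabor_kernel(k_prof, f)
  expect_true(fit$converged)
  expect_lt(abs(fit$sigma_sq - 0.2) / 0.2, 0.05)
  expect_lt(abs(fit$q - 1.7) / 1.7, 0.05)
  # loss landscape: truth beats a doubled precision
  expect_lte(gabor_fit_loss(k_prof, f, 0.2, 1.7),
             gabor_fit_loss(k_prof, f, 0.1, 1.7))
})

test_that("constant kernel profile is flagged as a degenerate fit", {
  fit <- fit_gabor_kernel(rep(2, 50), f = 0.5)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_true(is.na(fit$sigma_sq))
})

test_that("tuning profile validates its parameters", {
  expect_error(tuning_profile("gabor_simple", sigma_sq = -1), "> 0")
  expect_error(tuning_profile("gabor_simple", sigma_sq = 1, q = 0), "> 0")
  expect_error(tuning_profile("gabor_simple", sigma_sq = 1, a = 1), "\\[0, 1\\)")
})
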