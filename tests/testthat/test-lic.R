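# Small random state used by the brute-force comparisons.
small_state <- function(n = 8, seed = 1) {
  set.seed(seed)
  I <- matrix(runif(n * n, 50, 200), n, n)
  phi <- matrix(rnorm(n * n, 0, 2), n, n)
  b <- 1 + 0.3 * matrix(seq(0, 1, length.out = n), n, n, byrow = TRUE)
  list(I = I, state = list(phi = phi, bias = b, cluster_means = c(180, 70)))
}

# lsn_slice requires >= 32 px; wrap small grids directly for operator tests.
tiny_slice <- function(I) {
  structure(list(intensities = I, pixel_spacing = 1, metadata = list()),
            class = "lsn_slice")
}

test_that("lic_energy matches the four-nested-loop oracle on 8x8", {
  ss <- small_state(8)
  params <- lic_params(kernel_scale = 1.5, length_weight = 0,
                       regularization_weight = 0)
  e <- lic_energy(tiny_slice(ss$I), ss$state, params)
  e_oracle <- oracle_lic_data_energy(ss$I, ss$state$phi, ss$state$bias,
                                     ss$state$cluster_means, sigma = 1.5,
                                     eps = params$heaviside_width)
  expect_equal(e, e_oracle, tolerance = 1e-8)
})

test_that("lic_energy: perfect fit is zero, and is linear in nu", {
  # piecewise-constant image, b = 1, c = true means, phi = signed mask step
  I <- matrix(70, 16, 16); I[5:12, 5:12] <- 180
  phi <- matrix(-2, 16, 16); phi[5:12, 5:12] <- 2
  st <- list(phi = phi, bias = matrix(1, 16, 16), cluster_means = c(180, 70))
  # memberships crisp up to the atan tail of H_eps, which is O(eps)
  p0 <- lic_params(kernel_scale = 2, length_weight = 0, regularization_weight = 0,
                   heaviside_width = 1e-12)
  expect_equal(lic_energy(tiny_slice(I), st, p0), 0, tolerance = 1e-6)

  ss <- small_state(8, seed = 2)
  base <- lic_params(kernel_scale = 1.5, length_weight = 0, regularization_weight = 0)
  with_nu <- lic_params(kernel_scale = 1.5, length_weight = 3, regularization_weight = 0)
  gr <- lsnquant:::grad_row(ss$state$phi); gc <- lsnquant:::grad_col(ss$state$phi)
  len <- sum(lsnquant:::smooth_delta(ss$state$phi, 1) * sqrt(gr^2 + gc^2))
  expect_equal(lic_energy(tiny_slice(ss$I), ss$state, with_nu),
               lic_energy(tiny_slice(ss$I), ss$state, base) + 3 * len,
               tolerance = 1e-10)
})

test_that("cluster-mean update: closed form, oracle, and b-scaling", {
  # b = 1, crisp memberships -> plain region means
  I <- matrix(70, 16, 16); I[5:12, 5:12] <- 180
  set.seed(3); I <- I + matrix(rnorm(256, 0, 5), 16, 16)
  phi <- matrix(-2, 16, 16); phi[5:12, 5:12] <- 2
  inside <- phi > 0
  st <- list(phi = phi, bias = matrix(1, 16, 16), cluster_means = c(1, 1))
  p <- lic_params(kernel_scale = 2, heaviside_width = 1e-9)
  cm <- update_cluster_means(tiny_slice(I), st, p)
  expect_equal(cm, c(mean(I[inside]), mean(I[!inside])), tolerance = 1e-6)

  # 8x8: matches brute-force minimization of the energy over a c grid
  ss <- small_state(8, seed = 4)
  p8 <- lic_params(kernel_scale = 1.5, length_weight = 0, regularization_weight = 0)
  cm8 <- update_cluster_means(tiny_slice(ss$I), ss$state, p8)
  for (phase in 1:2) {
    grid <- seq(cm8[phase] - 3, cm8[phase] + 3, by = 0.1)
    evals <- vapply(grid, function(cv) {
      cms <- ss$state$cluster_means; cms[phase] <- cv
      st2 <- ss$state; st2$cluster_means <- cms
      oracle_lic_data_energy(ss$I, st2$phi, st2$bias, st2$cluster_means,
                             sigma = 1.5, eps = 1)
    }, numeric(1))
    expect_equal(grid[which.min(evals)], cm8[phase], tolerance = 0.1)
  }

  # scaling b by k scales c by 1/k (b*c identifiability)
  st_k <- ss$state; st_k$bias <- ss$state$bias * 2.5
  expect_equal(update_cluster_means(tiny_slice(ss$I), st_k, p8), cm8 / 2.5,
               tolerance = 1e-10)
})

test_that("bias update: unbiased case, oracle, smoothness", {
  I <- matrix(70, 16, 16); I[5:12, 5:12] <- 180
  phi <- matrix(-2, 16, 16); phi[5:12, 5:12] <- 2
  st <- list(phi = phi, bias = matrix(1, 16, 16), cluster_means = c(180, 70))
  p <- lic_params(kernel_scale = 2, heaviside_width = 1e-9)
  b <- update_bias(tiny_slice(I), st, p)
  expect_equal(b, matrix(1, 16, 16), tolerance = 1e-6)

  ss <- small_state(8, seed = 5)
  p8 <- lic_params(kernel_scale = 1.5, bias_floor = 0)
  b8 <- update_bias(tiny_slice(ss$I), ss$state, p8)
  b_or <- oracle_bias_update(ss$I, ss$state$phi, ss$state$cluster_means,
                             sigma = 1.5, eps = 1)
  expect_equal(b8, b_or, tolerance = 1e-8)

  # smoothness: gradient no larger than the unfloored smoothed ratio's
  gmag <- function(f) {
    sqrt(lsnquant:::grad_row(f)^2 + lsnquant:::grad_col(f)^2)
  }
  expect_lte(max(gmag(pmax(b_or, 0.1))), max(gmag(b_or)) + 1e-12)
})

test_that("level-set step: e-field oracle, zero force, mirror equivariance", {
  ss <- small_state(8, seed = 6)
  p8 <- lic_params(kernel_scale = 1.5, length_weight = 0, regularization_weight = 0)
  ef <- lsnquant:::lic_e_fields(ss$I, ss$state, p8)
  ef_or <- oracle_e_fields(ss$I, ss$state$bias, ss$state$cluster_means, 1.5)
  expect_equal(ef$e1, ef_or[[1]], tolerance = 1e-8)
  expect_equal(ef$e2, ef_or[[2]], tolerance = 1e-8)

  # e1 = e2 (equal cluster means) and nu = mu = 0 -> phi unchanged
  st_eq <- ss$state; st_eq$cluster_means <- c(120, 120)
  expect_equal(evolve_level_set(tiny_slice(ss$I), st_eq, p8), st_eq$phi,
               tolerance = 1e-12)

  # mirror input and phi -> mirrored output
  p_full <- lic_params(kernel_scale = 1.5)
  out <- evolve_level_set(tiny_slice(ss$I), ss$state, p_full)
  mir <- function(m) m[, rev(seq_len(ncol(m)))]
  st_m <- list(phi = mir(ss$state$phi), bias = mir(ss$state$bias),
               cluster_means = ss$state$cluster_means)
  out_m <- evolve_level_set(tiny_slice(mir(ss$I)), st_m, p_full)
  expect_equal(out_m, mir(out), tolerance = 1e-10)
})

test_that("segment_with_bias: preconditions and parameter guards", {
  ph <- test_phantom(A = 1, seed = 2, size = 64L, radius = 20)
  sl <- phantom_slice(ph)
  empty <- matrix(FALSE, 64, 64)
  expect_error(segment_with_bias(sl, empty), class = "lsn_parameter_error")
  expect_error(segment_with_bias(sl, !empty), class = "lsn_parameter_error")
  expect_error(lic_params(time_step = 0.3, regularization_weight = 1),
               class = "lsn_parameter_error")
  expect_error(lic_params(kernel_scale = -1), class = "lsn_parameter_error")
})

test_that("scale ambiguity: k * image scales c and J by k, mask unchanged", {
  ph <- test_phantom(A = 1, seed = 8, noise_sd = 4, size = 64L, radius = 20)
  sl <- phantom_slice(ph)
  init <- initial_liver_mask(sl)
  k <- 3
  # the energy is invariant under (I, nu, mu, dt) -> (kI, k^2 nu, k^2 mu,
  # dt / k^2): nu and mu trade off against the intensity^2-scaled data term,
  # so rescaling them with k^2 (and the step accordingly) reproduces the
  # identical evolution with c and J scaled by k
  p1 <- lic_params(max_iters = 30, length_weight = 0.002 * 255^2)
  pk <- lic_params(max_iters = 30, length_weight = 0.002 * 255^2 * k^2,
                   regularization_weight = k^2, time_step = 0.1 / k^2)
  s1 <- segment_with_bias(sl, init, p1)
  sk <- segment_with_bias(lsn_slice(sl$intensities * k, sl$pixel_spacing),
                          init, pk)
  expect_identical(sk$mask, s1$mask)
  expect_equal(sk$cluster_means, k * s1$cluster_means, tolerance = 1e-6)
  expect_equal(sk$corrected, k * s1$corrected, tolerance = 1e-6)
})
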