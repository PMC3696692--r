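grid128 <- r_grid(n = 128)

test_that("the dipolar kernel starts at 1 and depends only on omega*t", {
  t <- seq(0, 3, length.out = 40)
  kern <- build_kernel(t, grid128)
  expect_equal(kern$K[1, ], rep(1, 128))
  expect_true(all(kern$K <= 1 + 1e-12))

  # entries with equal omega * t products are equal: scale r by 2 and
  # t by 8 (omega ~ r^-3)
  g2 <- r_grid(3, 16, 128)
  k1 <- build_kernel(c(0, 0.25), grid128)
  k2 <- build_kernel(c(0, 2.0), g2)
  expect_equal(k1$K[2, ], k2$K[2, ], tolerance = 1e-10)
})

test_that("quadrature and Fresnel kernels agree to 1e-6 on the default grid", {
  g <- r_grid()
  t <- seq(0, 4, length.out = 80)
  kf <- build_kernel(t, g, method = "fresnel")
  kq <- build_kernel(t, g, method = "quadrature")
  expect_lt(max(abs(kf$K - kq$K)), 1e-6)
})

test_that("kernel columns stay within the powder-average bounds", {
  kern <- build_kernel(seq(0, 4, length.out = 200), grid128)
  expect_true(all(kern$K >= -0.5 - 1e-9 & kern$K <= 1 + 1e-9))
  expect_error(build_kernel(seq(0.1, 1, 0.1), grid128), "t = 0")
  bad <- grid128; bad$r[5] <- bad$r[5] + 0.01
  expect_error(build_kernel(c(0, 1), bad), "uniform")
})

test_that("simulate_deer reproduces its closed-form components", {
  t <- seq(0, 3, length.out = 60)
  p <- distance_distribution(grid128, dnorm(grid128$r, 4, 0.3))
  # lambda = 0: pure background
  v0 <- simulate_deer(p, t, deer_params(lambda = 0, bg_k = 0.2))
  expect_equal(v0$v, exp(-0.2 * t), tolerance = 1e-12)
  # delta distribution: V = 1 - lambda + lambda K(t, r0)
  pd <- rep(0, 128); pd[60] <- 1
  pdelta <- distance_distribution(grid128, pd)
  kern <- build_kernel(t, grid128)
  vd <- simulate_deer(pdelta, t, deer_params(lambda = 0.4, bg_k = 0))
  expect_equal(vd$v, 1 - 0.4 + 0.4 * kern$K[, 60], tolerance = 1e-10)
  # seeded noise is reproducible and does not touch the global stream
  set.seed(999); before <- runif(1)
  v1 <- simulate_deer(p, t, noise_sigma = 0.01, seed = 7)
  v2 <- simulate_deer(p, t, noise_sigma = 0.01, seed = 7)
  expect_identical(v1$v, v2$v)
  expect_error(simulate_deer(p, t, noise_sigma = 0.01), "seed")
})

test_that("background correction recovers the planted decay and depth", {
  t <- seq(0, 4, length.out = 250)
  # pure background: form factor identically 1
  bg <- deer_trace(t, exp(-0.3 * t))
  bc0 <- background_correct(bg)
  expect_equal(bc0$form_factor$v, rep(1, 250), tolerance = 1e-6)

  p <- distance_distribution(r_grid(), dnorm(r_grid()$r, 4, 0.3))
  tr <- simulate_deer(p, t, deer_params(lambda = 0.3, bg_k = 0.15))
  bc <- background_correct(tr)
  expect_lt(abs(bc$bg_k - 0.15) / 0.15, 0.05)
  expect_lt(abs(bc$lambda_est - 0.3), 0.02)
  expect_equal(bc$form_factor$v[1], 1, tolerance = 1e-3)

  short <- deer_trace(seq(0, 1, length.out = 12), exp(-seq(0, 1, length.out = 12)))
  expect_error(background_correct(short), "fewer than 10")
  neg <- deer_trace(t, exp(-0.3 * t) - 0.5)
  expect_error(background_correct(neg), "non-positive")
})

test_that("noiseless Tikhonov inversion recovers a single Gaussian", {
  g <- grid128
  t <- seq(0, 4, length.out = 200)
  truth <- distance_distribution(g, dnorm(g$r, 4.0, 0.3))
  tr <- simulate_deer(truth, t, deer_params(lambda = 0.3, bg_k = 0.15))
  bc <- background_correct(tr)
  kern <- build_kernel(t, g)
  alpha <- select_alpha_lcurve(bc$form_factor, g, kernel = kern)
  fit <- tikhonov_invert(bc$form_factor, g, as.numeric(alpha), kernel = kern)
  expect_true(all(fit$p_hat$p >= 0))
  expect_equal(sum(fit$p_hat$p) * g$dr, 1, tolerance = 1e-9)
  st <- distribution_stats(fit$p_hat)
  expect_lt(abs(st$mean - 4.0), 0.05)
  sd_hat <- st$fwhm / 2.355
  expect_lt(abs(sd_hat - 0.3) / 0.3, 0.20)
})

test_that("inversion with a fixed modulation depth solves the stated problem", {
  g <- grid128
  t <- seq(0, 4, length.out = 200)
  truth <- distance_distribution(g, dnorm(g$r, 4.5, 0.4))
  tr <- simulate_deer(truth, t, deer_params(lambda = 0.35, bg_k = 0))
  fit <- tikhonov_invert(tr, g, alpha = 0.1, lambda = 0.35)
  expect_equal(fit$lambda_est, 0.35)
  expect_lt(abs(distribution_stats(fit$p_hat)$mean - 4.5), 0.05)
})

test_that("the smoothness penalty decreases monotonically with alpha", {
  g <- grid128
  t <- seq(0, 4, length.out = 150)
  truth <- distance_distribution(g, dnorm(g$r, 4.0, 0.3))
  tr <- simulate_deer(truth, t, deer_params(lambda = 0.3, bg_k = 0.1),
                      noise_sigma = 0.01, seed = 31)
  bc <- background_correct(tr)
  kern <- build_kernel(t, g)
  alphas <- 10^seq(-2, 1, length.out = 7)
  fits <- lapply(alphas, function(a)
    tikhonov_invert(bc$form_factor, g, a, kernel = kern))
  pens <- vapply(fits, `[[`, 0, "penalty_norm")
  resids <- vapply(fits, `[[`, 0, "residual_norm")
  expect_true(all(diff(pens) <= 1e-8))
  expect_true(all(diff(resids) >= -1e-8))
})

test_that("L-curve selection is deterministic and validates its inputs", {
  g <- grid128
  sim <- make_synthetic_deer(deer_sim_config(
    components = data.frame(mean = 4, sd = 0.3, weight = 1),
    noise_sigma = 0.01, grid = g, seed = 41))
  bc <- background_correct(sim$trace)
  kern <- build_kernel(sim$trace$t, g)
  a1 <- select_alpha_lcurve(bc$form_factor, g, kernel = kern)
  a2 <- select_alpha_lcurve(bc$form_factor, g, kernel = kern)
  expect_identical(as.numeric(a1), as.numeric(a2))
  expect_s3_class(attr(a1, "lcurve"), "data.frame")
  expect_error(select_alpha_lcurve(bc$form_factor, g, alphas = rep(1, 10)), "distinct")
  expect_error(select_alpha_lcurve(bc$form_factor, g, alphas = 1:5), "at least 8")
})

test_that("the inversion residual at the L-curve alpha tracks the noise floor", {
  g <- grid128
  sigma <- 0.01
  sim <- make_synthetic_deer(deer_sim_config(
    components = data.frame(mean = 4, sd = 0.3, weight = 1),
    noise_sigma = sigma, grid = g, seed = 43))
  bc <- background_correct(sim$trace)
  kern <- build_kernel(sim$trace$t, g)
  alpha <- select_alpha_lcurve(bc$form_factor, g, kernel = kern)
  fit <- tikhonov_invert(bc$form_factor, g, as.numeric(alpha), kernel = kern)
  noise_floor <- sigma * sqrt(length(sim$trace$t))
  expect_lt(fit$residual_norm, 2 * noise_floor)
})

test_that("two nearby Gaussian components are resolved at high SNR", {
  g <- r_grid()
  sim <- make_synthetic_deer(deer_sim_config(
    components = data.frame(mean = c(4.0, 5.5), sd = c(0.25, 0.25),
                            weight = c(0.5, 0.5)),
    t_max = 4, lambda = 0.3, noise_sigma = 0.3 / 50, grid = g, seed = 47))
  bc <- background_correct(sim$trace)
  kern <- build_kernel(sim$trace$t, g)
  alpha <- select_alpha_lcurve(bc$form_factor, g, kernel = kern)
  fit <- tikhonov_invert(bc$form_factor, g, as.numeric(alpha), kernel = kern)
  expect_gte(n_modes(fit$p_hat), 2)
  modes_r <- g$r[which(diff(sign(diff(fit$p_hat$p))) == -2) + 1]
  expect_true(any(abs(modes_r - 4.0) < 0.3))
  expect_true(any(abs(modes_r - 5.5) < 0.3))
})

test_that("distribution statistics match closed forms", {
  g <- grid128
  pd <- rep(0, 128); pd[100] <- 1
  delta <- distance_distribution(g, pd)
  st <- distribution_stats(delta)
  expect_equal(st$mean, g$r[100])
  expect_equal(st$mode, g$r[100])

  gaus <- distance_distribution(g, dnorm(g$r, 5.8, 0.5))
  st2 <- distribution_stats(gaus)
  expect_lt(abs(st2$mean - st2$mode), g$dr)
  expect_lt(abs(st2$fwhm - 2.355 * 0.5), 2 * g$dr)
})
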