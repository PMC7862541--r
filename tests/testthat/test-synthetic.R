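test_that("gaussian work generator honours the zero-dissipation limit and determinism", {
  ws <- gen_gaussian_work(5, 1e-9, 10, 10, 300.15, seed = 1)
  expect_true(all(abs(ws$forward_works - 5) < 1e-6))
  expect_true(all(abs(ws$reverse_works + 5) < 1e-6))

  a <- gen_gaussian_work(-3, 2, 100, 80, seed = 99)
  b <- gen_gaussian_work(-3, 2, 100, 80, seed = 99)
  expect_identical(a, b)

  expect_error(gen_gaussian_work(0, 1, 100, 100, temperature = -1))
  expect_error(gen_gaussian_work(0, 1, 0, 100))
})

test_that("forward and reverse work distributions coincide at dg = 0", {
  # at dg = 0 the 0->1 and 1->0 switches are statistically identical, so
  # the measured work samples of both directions share one distribution
  ws <- gen_gaussian_work(0, 2, 2000, 2000, seed = 7)
  ks <- suppressWarnings(ks.test(ws$forward_works, ws$reverse_works))
  expect_gt(ks$p.value, 0.01)
})

test_that("forward work mean follows dg + beta sigma^2 / 2", {
  sigma <- 3; n <- 5000; temperature <- 300.15
  ws <- gen_gaussian_work(-10, sigma, n, n, temperature, seed = 11)
  mu_expect <- -10 + sigma^2 / (2 * 0.0083144621 * temperature)
  expect_lt(abs(mean(ws$forward_works) - mu_expect), 3 * sigma / sqrt(n))
})

test_that("work distributions satisfy the Crooks relation (log-ratio slope beta, root at dg)", {
  dg <- -4; sigma <- 2.5; temperature <- 300.15
  b <- 1 / (0.0083144621 * temperature)
  ws <- gen_gaussian_work(dg, sigma, 1e5, 1e5, temperature, seed = 3)
  mf <- mean(ws$forward_works); sf <- sd(ws$forward_works)
  mr <- mean(-ws$reverse_works); sr <- sd(-ws$reverse_works)
  w_grid <- seq(dg - sigma, dg + sigma, length.out = 50)
  log_ratio <- dnorm(w_grid, mf, sf, log = TRUE) -
    dnorm(w_grid, mr, sr, log = TRUE)
  fit <- lm(log_ratio ~ w_grid)
  slope <- coef(fit)[2]
  root <- -coef(fit)[1] / slope
  expect_lt(abs(slope - b) / b, 0.05)
  expect_lt(abs(root - dg), 0.25)
})

test_that("gaussian ensemble generator reproduces the requested covariance", {
  sig2 <- c(0.02, 0.01, 0.005)
  ens <- gen_gaussian_ensemble(diag(rep(sig2, each = 1), 3), masses = 12,
                               n_frames = 50000, seed = 5)
  x <- ens$coordinates[, 1, ]
  for (k in 1:3)
    expect_lt(abs(var(x[, k]) - sig2[k]) / sig2[k], 0.03)

  z <- gen_gaussian_ensemble(matrix(0, 3, 3), 12, 100, seed = 1)
  expect_equal(max(abs(sweep(z$coordinates[, 1, ], 2,
                             z$coordinates[1, 1, ]))), 0)

  e1 <- gen_gaussian_ensemble(diag(0.01, 6), c(12, 16), 50, seed = 42)
  e2 <- gen_gaussian_ensemble(diag(0.01, 6), c(12, 16), 50, seed = 42)
  expect_identical(e1, e2)

  neg <- diag(c(1, -1, 1))
  expect_error(gen_gaussian_ensemble(neg, 12, 10), "semi-definite")
})

test_that("pose series generator plants flips and unbinding exactly", {
  s <- gen_pose_series(100, noise_sd = 0, seed = 1)
  expect_true(all(s$orientation_cos == 1))
  expect_true(all(s$com_distance == 0.3))

  s <- gen_pose_series(1000, flip_frame = 500, noise_sd = 0, seed = 1)
  expect_true(all(s$orientation_cos[s$frame_index < 500] == 1))
  expect_true(all(s$orientation_cos[s$frame_index >= 500] == -1))

  s <- gen_pose_series(1000, unbind_frame = 250, noise_sd = 0, seed = 1)
  expect_true(all(s$com_distance[s$frame_index >= 250] > 1.5))

  expect_error(gen_pose_series(100, flip_frame = 100))
})

test_that("dhdl generator returns exact analytic integrals", {
  g <- gen_dhdl_series(5, 11)
  expect_equal(g$analytic_integral, 5)
  expect_equal(integrate_work(g$series), 5)

  g <- gen_dhdl_series(c(0, 0, 3), 151)          # 3 l^2
  expect_equal(g$analytic_integral, 1)
  h <- 1 / 150                                   # even-grid trapezoid defect
  expect_equal(integrate_work(g$series), 1 + h^2 / 2, tolerance = 1e-12)

  g <- gen_dhdl_series(c(-0.5, 1), 101)          # odd about l = 0.5
  expect_equal(g$analytic_integral, 0)
  expect_lt(abs(integrate_work(g$series)), 1e-12)

  expect_error(gen_dhdl_series(1, 1))
})

test_that("ff fixture generator round-trips and carries its ground truth", {
  fx <- gen_ff_fixture(10, seed = 3)
  expect_identical(fx$truth, character(0))
  p <- parse_dihedral_params(fx$text, "amber-dat")
  expect_identical(nrow(p), fx$n_lines)
  expect_identical(detect_overdefined(p)$canonical, character(0))

  # write -> parse fixed point
  p2 <- parse_dihedral_params(write_dihedral_params(p), "amber-dat")
  expect_equal(p2$barrier_kj, p$barrier_kj, tolerance = 1e-9)
  expect_identical(p2$quad, p$quad)
  expect_identical(p2$periodicity, p$periodicity)

  fx <- gen_ff_fixture(5, duplicates = list(
    list(quad = "c3-c3-os-c3", periodicity = 3, barriers = c(0.16, 1.4))),
    seed = 8)
  expect_identical(fx$truth, "c3-c3-os-c3")
  expect_error(gen_ff_fixture(5, duplicates = list(
    list(quad = "c3-X-os-c3", periodicity = 3, barriers = c(0.1, 0.2)))),
    "wildcard")
})
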