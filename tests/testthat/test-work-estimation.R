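test_that("work integration follows the series' own lambda path", {
  s <- dhdl_series(seq(0, 1, 0.1), rep(5, 11), "forward")
  expect_equal(integrate_work(s), 5)

  # reverse series integrate along 1 -> 0: constant 5 gives -5
  r <- dhdl_series(seq(1, 0, -0.1), rep(5, 11), "reverse")
  expect_equal(integrate_work(r), -5)

  lam <- seq(0, 1, length.out = 200)
  s <- dhdl_series(lam, lam - 0.5, "forward")
  expect_lt(abs(integrate_work(s)), 1e-12)

  expect_error(dhdl_series(c(0, 0.5), c(1, 2, 3), "forward"))
  expect_error(dhdl_series(c(0, 0.6, 0.4, 1), c(1, 2, 3, 4), "forward"),
               "monotone")
  expect_error(dhdl_series(c(0, 0.5, 1), c(1, NaN, 2), "forward"), "finite")
})

test_that("CFT-ML solves the delta-distribution case exactly for any offset", {
  for (a in c(-7.5, 0, 3.3)) {
    ws <- work_set(rep(a, 5), rep(-a, 5))
    expect_equal(estimate_cft_ml(ws)$dg, a, tolerance = 1e-9)
  }
})

test_that("CFT-ML is antisymmetric under direction swap", {
  ws <- gen_gaussian_work(-6, 2, 300, 200, seed = 21)
  fwd <- estimate_cft_ml(ws)
  swapped <- work_set(ws$reverse_works, ws$forward_works, ws$temperature)
  expect_equal(estimate_cft_ml(swapped)$dg, -fwd$dg, tolerance = 1e-8)
})

test_that("CFT-ML shifts covariantly with a constant work offset", {
  ws <- gen_gaussian_work(2, 1.5, 200, 200, seed = 5)
  base <- estimate_cft_ml(ws)$dg
  c0 <- 11.25
  shifted <- work_set(ws$forward_works + c0, ws$reverse_works - c0,
                      ws$temperature)
  expect_equal(estimate_cft_ml(shifted)$dg, base + c0, tolerance = 1e-8)
})

test_that("CFT-ML matches the grid-likelihood oracle and recovers planted dg", {
  ws <- gen_gaussian_work(-10, 2, 500, 500, seed = 17)
  est <- estimate_cft_ml(ws)
  oracle <- grid_bar_oracle(ws, -20, 0)
  expect_lt(abs(est$dg - oracle), 1e-6)
  expect_lt(abs(est$dg + 10), 3 * est$stderr + 1e-12)
  expect_gt(est$stderr, 0)
})

test_that("CFT-ML reports non-overlapping work distributions", {
  ws <- work_set(rep(100, 10) + rnorm(10, sd = 0.01),
                 rep(100, 10) + rnorm(10, sd = 0.01))
  expect_error(estimate_cft_ml(ws), "overlap")
})

test_that("Jarzynski handles degenerate and two-sample cases in closed form", {
  expect_equal(estimate_jarzynski(rep(4.2, 8), n_boot = 0)$dg, 4.2)
  expect_equal(estimate_jarzynski(c(0, 0), n_boot = 0)$dg, 0)

  # works {0, W2}: dG = -kT ln((1 + e^(-b W2)) / 2), direct evaluation
  temperature <- 300.15
  b <- 1 / (0.0083144621 * temperature)
  w2 <- 5
  direct <- -log((1 + exp(-b * w2)) / 2) / b
  expect_equal(estimate_jarzynski(c(0, w2), temperature, n_boot = 0)$dg,
               direct, tolerance = 1e-12)
})

test_that("Jarzynski estimate never exceeds the mean work (Jensen)", {
  for (seed in 1:5) {
    ws <- gen_gaussian_work(3, 2, 200, 200, seed = seed)
    est <- estimate_jarzynski(ws, n_boot = 0)
    expect_lte(est$dg, mean(ws$forward_works) + 1e-12)
  }
})

test_that("CGI degenerates to the midpoint / common mean and matches a numeric intersection", {
  # equal variances: midpoint of the means
  ws <- work_set(c(1, 2, 3), -c(5, 6, 7))
  expect_equal(estimate_cgi(ws, n_boot = 0)$dg, 4)

  # identical distributions: common mean
  ws <- work_set(c(1, 2, 3), -c(1, 2, 3))
  expect_equal(estimate_cgi(ws, n_boot = 0)$dg, 2)

  # unequal variances with well-separated means: compare to a numeric
  # crossing of the two fitted densities between the means
  set.seed(31)
  wf <- rnorm(400, -3, 1.5)
  wfr <- rnorm(400, -7, 2.5)      # negated-reverse works
  ws <- work_set(wf, -wfr)
  m1 <- mean(wf); s1 <- sd(wf)
  m2 <- mean(wfr); s2 <- sd(wfr)
  crossing <- uniroot(function(x) dnorm(x, m1, s1) - dnorm(x, m2, s2),
                      c(m2, m1), tol = 1e-12)$root
  expect_lt(abs(estimate_cgi(ws, n_boot = 0)$dg - crossing), 1e-9)

  expect_error(estimate_cgi(work_set(c(1, 1), c(2, 3))), "zero-variance")
})

test_that("estimators agree on CFT-consistent gaussian work sets", {
  dg <- -8; sigma <- 1.5
  ws <- gen_gaussian_work(dg, sigma, 2000, 2000, seed = 13)
  ml <- estimate_cft_ml(ws)
  cgi <- estimate_cgi(ws, n_boot = 0)
  jar <- estimate_jarzynski(ws, n_boot = 0)
  expect_lt(abs(ml$dg - dg), 0.2)
  expect_lt(abs(cgi$dg - dg), 0.2)
  expect_lt(abs(jar$dg - dg), 0.3)   # small beta sigma^2 regime
})

test_that("bootstrap stderr is deterministic, zero for degenerate sets, and scales ~ 1/sqrt(n)", {
  ws <- work_set(rep(2, 20), rep(-2, 20))
  expect_equal(bootstrap_stderr("cft-ml", ws, 50, seed = 1), 0)

  ws_small <- gen_gaussian_work(0, 2, 100, 100, seed = 2)
  ws_big <- gen_gaussian_work(0, 2, 400, 400, seed = 2)
  s_small <- bootstrap_stderr("cgi", ws_small, 100, seed = 9)
  s_big <- bootstrap_stderr("cgi", ws_big, 100, seed = 9)
  expect_gt(s_big / s_small, 0.35)
  expect_lt(s_big / s_small, 0.7)

  expect_identical(bootstrap_stderr("jarzynski", ws_small, 50, seed = 4),
                   bootstrap_stderr("jarzynski", ws_small, 50, seed = 4))
  expect_error(bootstrap_stderr("cgi", ws_small, 1))
})

test_that("work files round-trip through the xvg dialect with comments", {
  tmp <- withr::local_tempdir()
  s <- dhdl_series(seq(0, 1, length.out = 21), sin(1:21), "forward")
  p <- file.path(tmp, "w.xvg")
  write_dhdl_xvg(s, p, comment = "test series")
  s2 <- read_dhdl_xvg(p, "forward")
  expect_equal(s2$lambda_values, s$lambda_values, tolerance = 1e-9)
  expect_equal(s2$dhdl_values, s$dhdl_values, tolerance = 1e-9)

  # time-axis abscissa is rescaled onto lambda
  writeLines(c("# comment", "@ legend", "0 1.0", "250 2.0", "500 3.0"),
             p)
  s3 <- read_dhdl_xvg(p, "forward")
  expect_equal(s3$lambda_values, c(0, 0.5, 1))
  expect_equal(integrate_work(s3), 2)

  writeLines(c("0 1.0", "0.5 oops", "1 2.0"), p)
  expect_error(read_dhdl_xvg(p, "forward"), "non-numeric|non-finite")
})
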