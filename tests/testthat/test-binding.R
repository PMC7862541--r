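test_that("Boresch correction obeys its analytic scaling laws", {
  r <- restraint_definition(0.5, pi / 2, pi / 2, 4184,
                            41.84, 41.84, 41.84, 41.84, 41.84)
  kt <- 0.0083144621 * 300.15
  base <- restraint_correction(r, 300.15)

  r4 <- restraint_definition(0.5, pi / 2, pi / 2, 4 * 4184,
                             4 * 41.84, 4 * 41.84, 4 * 41.84, 4 * 41.84,
                             4 * 41.84)
  expect_equal(restraint_correction(r4, 300.15) - base, -kt * log(64),
               tolerance = 1e-10)

  r2v <- restraint_definition(0.5, pi / 2, pi / 2, 4184,
                              41.84, 41.84, 41.84, 41.84, 41.84,
                              standard_volume = 2 * 1.6605)
  expect_equal(restraint_correction(r2v, 300.15) - base, -kt * log(2),
               tolerance = 1e-10)

  expect_error(restraint_definition(0.5, 0, pi / 2, 4184,
                                    41.84, 41.84, 41.84, 41.84, 41.84))
  expect_error(restraint_definition(0.5, pi / 2, pi / 2, -1,
                                    41.84, 41.84, 41.84, 41.84, 41.84))
  # near-collinear reference geometry is caught at evaluation
  soft <- restraint_definition(0.5, 1e-7, pi / 2, 4184,
                               41.84, 41.84, 41.84, 41.84, 41.84)
  expect_error(restraint_correction(soft, 300.15), "collinear")
})

test_that("Boresch correction matches the configurational-integral oracle at the restraint constants", {
  r <- restraint_definition(0.5, pi / 2, pi / 2, 4184,
                            41.84, 41.84, 41.84, 41.84, 41.84)
  # stiff-spring-regime integral (Jacobian at the reference geometry)
  expect_lt(abs(restraint_correction(r, 300.15) -
                boresch_quadrature_oracle(r, 300.15, "reference")), 0.02)
  # the exact-Jacobian integral differs only by the anharmonic Jacobian
  # correction, small on the kJ/mol scale at these constants
  expect_lt(abs(restraint_correction(r, 300.15) -
                boresch_quadrature_oracle(r, 300.15, "full")), 0.2)
})

test_that("Boresch correction matches quadrature across a random stiff-spring sweep", {
  set.seed(77)
  for (i in 1:15) {
    temperature <- runif(1, 280, 320)
    kt <- 0.0083144621 * temperature
    r0 <- runif(1, 0.3, 0.8)
    th <- runif(2, pi / 3, 2 * pi / 3)
    # well inside the stiff-spring regime so the exact-Jacobian integral
    # agrees with the analytical formula to < 0.05 kJ/mol
    k_r <- runif(1, 200 * kt / r0^2, 30000)
    k_ang <- runif(5, 200 * kt, 2000)
    r <- restraint_definition(r0, th[1], th[2], k_r, k_ang[1], k_ang[2],
                              k_ang[3], k_ang[4], k_ang[5])
    expect_lt(abs(restraint_correction(r, temperature) -
                  boresch_quadrature_oracle(r, temperature)), 0.05)
  }
})

test_that("pose combination reduces to its closed-form limits", {
  kt <- 0.0083144621 * 300.15
  one <- pose_estimate("primary", dg = -12, stderr = 0.5)
  expect_equal(combine_poses(one)$dg, -12)

  both <- list(pose_estimate("primary", dg = -12, stderr = 0.5),
               pose_estimate("secondary", dg = -12, stderr = 0.5))
  expect_equal(combine_poses(both)$dg, -12 - kt * log(2), tolerance = 1e-12)

  # -5 and -3 kcal/mol at 300.15 K: dominated by the stronger pose
  g <- list(pose_estimate("primary", dg = kcal_to_kj(-5), stderr = 0.1),
            pose_estimate("secondary", dg = kcal_to_kj(-3), stderr = 0.1))
  cmb <- combine_poses(g)
  b <- 1 / kt
  direct <- -log(exp(b * kcal_to_kj(5)) + exp(b * kcal_to_kj(3))) / b
  expect_equal(cmb$dg, direct, tolerance = 1e-9)
  expect_lte(cmb$dg, kcal_to_kj(-5) + 1e-12)
  expect_gte(cmb$dg, kcal_to_kj(-5) - kt * log(2) - 1e-12)

  disc <- pose_estimate("secondary", discarded = TRUE, reason = "flip")
  expect_equal(combine_poses(list(one, disc))$dg, -12)
  expect_error(combine_poses(list(disc)), "discarded")
})

test_that("pose combination bounds hold over random pose sets", {
  kt <- 0.0083144621 * 300.15
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:4, 1)
    dgs <- rnorm(n, -20, 6)
    pl <- lapply(seq_len(n), function(k)
      pose_estimate(if (k %% 2) "primary" else "secondary", dg = dgs[k],
                    stderr = 0.1))
    cmb <- combine_poses(pl)$dg
    expect_lte(cmb, min(dgs) + 1e-9)
    expect_gte(cmb, min(dgs) - kt * log(n) - 1e-9)
  }
})

test_that("repeat averaging gives mean and SEM, flagging n = 1", {
  a <- average_repeats(c(3, 3, 3))
  expect_equal(a$mean, 3); expect_equal(a$sem, 0)

  a <- average_repeats(c(1, 2, 3))
  expect_equal(a$mean, 2)
  expect_equal(a$sem, 1 / sqrt(3), tolerance = 1e-12)

  a <- average_repeats(5)
  expect_equal(a$mean, 5)
  expect_false(a$sem_defined)
  expect_error(average_repeats(numeric(0)))
})

test_that("force-field consensus averages with quadrature error propagation", {
  recs <- rbind(binding_record("MGLab24", "g2", "GAFF1.81", -6.76, 0.38),
                binding_record("MGLab24", "g2", "CGenFF4.1", -5.25, 0.11))
  cons <- consensus(recs)
  expect_equal(cons$dg_kcal, -6.005, tolerance = 1e-12)
  expect_equal(cons$stderr_kcal, sqrt(0.38^2 + 0.11^2) / 2,
               tolerance = 1e-12)
  expect_equal(round(cons$stderr_kcal, 3), 0.198)

  same <- rbind(binding_record("h", "g1", "ffA", -4, 0.2),
                binding_record("h", "g1", "ffB", -4, 0.2))
  c2 <- consensus(same)
  expect_equal(c2$dg_kcal, -4)
  expect_equal(c2$stderr_kcal, 0.2 / sqrt(2), tolerance = 1e-12)

  expect_warning(consensus(binding_record("h", "g1", "ffA", -4, 0.2)),
                 "single force field")
  expect_error(consensus(rbind(binding_record("h1", "g1", "ffA", -4, 0.2),
                               binding_record("h2", "g1", "ffB", -4, 0.2))))
})

test_that("binding assembly applies the declared DSSB sign convention", {
  expect_equal(assemble_binding(0, 0), 0)
  expect_equal(assemble_binding(20, -4, "unbinding"), -24)
  expect_equal(assemble_binding(20, -4, "binding"), 16)
  # opposite convention negates the transition term only
  expect_equal(assemble_binding(20, -4, "binding") -
               assemble_binding(20, -4, "unbinding"), 2 * 20)
  expect_error(assemble_binding(NaN, 0))
  expect_error(assemble_binding(0, 0, "sideways"))
})

test_that("ddg matrix enumerates all non-redundant pairs consistently", {
  recs <- do.call(rbind, lapply(1:9, function(i)
    binding_record(sprintf("MGLab%02d", i), "g1", "consensus",
                   -3 - 0.3 * i, 0.1)))
  dd <- ddg_matrix(recs)
  expect_identical(nrow(dd), 36L)    # 9 choose 2

  # antisymmetry under swapping a pair is implicit in dG_i - dG_j; check a
  # 3-cycle closes exactly
  pick <- function(i, j) {
    hit <- dd$host_i == recs$host[i] & dd$host_j == recs$host[j]
    if (any(hit)) dd$ddg_kcal[hit] else -dd$ddg_kcal[
      dd$host_i == recs$host[j] & dd$host_j == recs$host[i]]
  }
  expect_identical(pick(1, 2) + pick(2, 3), pick(1, 3))
  expect_identical(pick(4, 7) + pick(7, 9), pick(4, 9))

  equal <- rbind(binding_record("a", "g1", "x", -5, 0.1),
                 binding_record("b", "g1", "x", -5, 0.2))
  expect_equal(ddg_matrix(equal)$ddg_kcal, 0)
  expect_error(ddg_matrix(rbind(equal, equal)), "duplicate")
})

test_that("benchmark metrics match hand arithmetic and are offset-insensitive in r", {
  m <- binding_metrics(c(-1, -2, -3), c(-1, -2, -3), n_boot = 0)
  expect_equal(m$aue, 0); expect_equal(m$pearson, 1)

  m <- binding_metrics(c(-1, -2, -3) + 1, c(-1, -2, -3), n_boot = 0)
  expect_equal(m$aue, 1); expect_equal(m$pearson, 1)

  m <- binding_metrics(c(-1, -2, -3), c(-1.5, -2.0, -2.5), n_boot = 0)
  expect_equal(m$aue, 1 / 3, tolerance = 1e-12)
  expect_equal(m$pearson, 1)         # both exactly linear

  flat <- binding_metrics(c(1, 1, 1), c(0, 1, 2), n_boot = 0)
  expect_false(flat$pearson_defined)
})

test_that("metric bootstrap is seed-deterministic and tightens with n", {
  set.seed(5)
  exp10 <- rnorm(10); calc10 <- exp10 + rnorm(10, sd = 0.5)
  m1 <- binding_metrics(calc10, exp10, n_boot = 400, seed = 3)
  m2 <- binding_metrics(calc10, exp10, n_boot = 400, seed = 3)
  expect_identical(m1, m2)

  exp40 <- rnorm(40); calc40 <- exp40 + rnorm(40, sd = 0.5)
  m3 <- binding_metrics(calc40, exp40, n_boot = 400, seed = 3)
  expect_lt(m3$aue_err, m1$aue_err)
})
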