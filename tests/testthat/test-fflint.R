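test_that("dihedral parsing handles all three dialects with unit conversion", {
  expect_identical(nrow(parse_dihedral_params("", "amber-dat")), 0L)

  amber <- c("c3-c3-os-c3    1    0.16000      0.000  3.0",
             "hc-c3-c3-hc    1    0.15000      0.000 -3.0",
             "hc-c3-c3-hc    1    0.25000    180.000  2.0",
             "X -c3-os-X     3    1.15000      0.000  3.0")
  p <- parse_dihedral_params(amber, "amber-dat")
  expect_identical(nrow(p), 4L)
  expect_equal(p$barrier_kj[1], 0.16 * 4.184, tolerance = 1e-12)
  expect_identical(p$canonical[1], "c3-c3-os-c3")
  # continuation line joins its predecessor's parameter set
  expect_identical(p$set_id[2], p$set_id[3])
  expect_true(p$continuation[2]); expect_false(p$continuation[3])
  expect_true(p$wildcard[4])

  frc <- c("remark", "", "DIHE", amber[1], "", "NONBON")
  pf <- parse_dihedral_params(frc, "amber-frcmod")
  expect_identical(nrow(pf), 1L)
  expect_equal(pf$barrier_kj, p$barrier_kj[1])

  gmx <- c("[ dihedraltypes ]",
           "; i j k l funct phase kd pn",
           "c3 c3 os c3 9 0.000 0.66944 3",
           "[ bonds ]", "ignored 1 2")
  pg <- parse_dihedral_params(gmx, "gromacs-itp")
  expect_identical(nrow(pg), 1L)
  expect_equal(pg$barrier_kj, 0.66944)   # already kJ
  expect_identical(pg$canonical, "c3-c3-os-c3")

  expect_error(parse_dihedral_params("c3-c3-os 1 0.1 0 3", "amber-dat"),
               "malformed")
})

test_that("quadruple canonicalization is reversal-invariant", {
  a <- parse_dihedral_params("os-c3-c3-hc 1 0.1 0 3", "amber-dat")
  b <- parse_dihedral_params("hc-c3-c3-os 1 0.1 0 3", "amber-dat")
  expect_identical(a$canonical, b$canonical)
})

test_that("over-definition detection needs all three conditions", {
  base <- c("c3-c3-os-c3    1    0.16000      0.000  3.0",
            "hc-c3-c3-hc    1    0.15000      0.000  3.0",
            "c3-c3-os-c3    1    1.40000      0.000  3.0")
  # non-sequential duplicate with shared periodicity and different barrier
  g <- detect_overdefined(parse_dihedral_params(base, "amber-dat"))
  expect_identical(nrow(g), 1L)
  expect_identical(g$canonical, "c3-c3-os-c3")
  expect_identical(g$n_variants, 2L)

  # adjacent duplicates (sequential) are not flagged
  seq_dup <- base[c(1, 3, 2)]
  expect_identical(
    nrow(detect_overdefined(parse_dihedral_params(seq_dup, "amber-dat"))), 0L)

  # disjoint periodicities = legitimate multi-term dihedral, not flagged
  multi <- c("c3-c3-os-c3    1    0.16000      0.000  3.0",
             "hc-c3-c3-hc    1    0.15000      0.000  3.0",
             "c3-c3-os-c3    1    1.40000      0.000  2.0")
  expect_identical(
    nrow(detect_overdefined(parse_dihedral_params(multi, "amber-dat"))), 0L)

  # wildcard-containing duplicates are excluded by the rule
  wild <- c("X -c3-os-X     3    0.16000      0.000  3.0",
            "hc-c3-c3-hc    1    0.15000      0.000  3.0",
            "X -c3-os-X     3    1.40000      0.000  3.0")
  expect_identical(
    nrow(detect_overdefined(parse_dihedral_params(wild, "amber-dat"))), 0L)

  # reversed atom order still groups together
  revd <- c("c3-c3-os-c3    1    0.16000      0.000  3.0",
            "hc-c3-c3-hc    1    0.15000      0.000  3.0",
            "c3-os-c3-c3    1    1.40000      0.000  3.0")
  expect_identical(
    nrow(detect_overdefined(parse_dihedral_params(revd, "amber-dat"))), 1L)
})

test_that("generated fixtures are detected with exact recall and no false positives", {
  for (seed in 1:50) {
    n_dup <- seed %% 4L
    dups <- lapply(seq_len(n_dup), function(i)
      list(quad = paste(sample(c("c3", "os", "oh", "n3", "ca"), 4,
                               replace = TRUE), collapse = "-"),
           periodicity = sample(1:3, 1),
           barriers = round(runif(2, 0.1, 3), 4)))
    dups <- Filter(function(d) length(unique(d$barriers)) == 2L, dups)
    fx <- gen_ff_fixture(30, dups, seed = seed)
    found <- detect_overdefined(parse_dihedral_params(fx$text, "amber-dat"))
    expect_identical(sort(found$canonical), fx$truth,
                     label = sprintf("seed %d", seed))
  }
})

test_that("dihedral policies transform topologies idempotently", {
  params_txt <- c("c3-c3-os-c3    1    0.16000      0.000  3.0",
                  "hc-c3-c3-hc    1    0.15000      0.000  3.0",
                  "c3-c3-os-c3    1    1.40000      0.000  3.0")
  params <- parse_dihedral_params(params_txt, "amber-dat")
  groups <- detect_overdefined(params)

  atoms <- data.frame(index = 1:4, type = c("c3", "c3", "os", "c3"),
                      name = c("C1", "C2", "O1", "C3"),
                      charge = c(0.1, 0.1, -0.4, 0.2),
                      mass = c(12.01, 12.01, 16, 12.01),
                      residue = "SUG")
  dihs <- data.frame(ai = 1L, aj = 2L, ak = 3L, al = 4L,
                     barrier_kj = NA_real_, phase_deg = NA_real_,
                     periodicity = NA_integer_)
  topo <- topology(atoms, dihs)

  first <- apply_dihedral_policy(topo, params, groups, "first-match")
  expect_identical(nrow(first$dihedrals), 1L)
  expect_equal(first$dihedrals$barrier_kj, 0.16 * 4.184, tolerance = 1e-9)

  pref <- apply_dihedral_policy(topo, params, groups, "preferred-variant")
  expect_equal(pref$dihedrals$barrier_kj, 1.40 * 4.184, tolerance = 1e-9)

  all_v <- apply_dihedral_policy(topo, params, groups, "all-variants")
  expect_identical(nrow(all_v$dihedrals), 2L)   # 2 variants x 1 term

  for (pol in list(first, pref, all_v)) {
    again <- apply_dihedral_policy(pol, params, groups,
      if (identical(pol, first)) "first-match"
      else if (identical(pol, pref)) "preferred-variant" else "all-variants")
    expect_equal(again$dihedrals[order(again$dihedrals$barrier_kj), ],
                 pol$dihedrals[order(pol$dihedrals$barrier_kj), ],
                 ignore_attr = TRUE)
  }

  # explicit-index preference and invalid preference
  pref2 <- apply_dihedral_policy(topo, params, groups, "preferred-variant",
                                 preference = 1L)
  expect_equal(pref2$dihedrals$barrier_kj, 0.16 * 4.184, tolerance = 1e-9)
  expect_error(apply_dihedral_policy(topo, params, groups,
                                     "preferred-variant", preference = 5L),
               "exactly one")
})

test_that("sugar-preference policy selects the stiffer c3-c3-os-c3 set on its fixture", {
  fx <- gen_ff_fixture(8, duplicates = list(
    list(quad = "c3-c3-os-c3", periodicity = 3, barriers = c(0.16, 1.4))),
    seed = 12)
  params <- parse_dihedral_params(fx$text, "amber-dat")
  groups <- detect_overdefined(params)
  expect_identical(groups$canonical, "c3-c3-os-c3")

  atoms <- data.frame(index = 1:4, type = c("c3", "c3", "os", "c3"),
                      name = paste0("A", 1:4), charge = 0,
                      mass = c(12, 12, 16, 12), residue = "SUG")
  topo <- topology(atoms, data.frame(ai = 1L, aj = 2L, ak = 3L, al = 4L,
                                     barrier_kj = NA_real_,
                                     phase_deg = NA_real_,
                                     periodicity = NA_integer_))
  fixed <- apply_dihedral_policy(topo, params, groups, "preferred-variant")
  expect_equal(fixed$dihedrals$barrier_kj, 1.4 * 4.184, tolerance = 1e-9)
})

test_that("charge scaling is linear, selective and reports the net change", {
  atoms <- data.frame(index = 1:3, type = c("c3", "os", "hc"),
                      name = c("C", "O", "H"),
                      charge = c(0.2, -0.5, 0.3),
                      mass = c(12, 16, 1), residue = "LIG")
  topo <- topology(atoms)

  ident <- scale_charges(topo, 1:3, 1)
  expect_equal(ident$atoms$charge, atoms$charge)
  expect_equal(attr(ident, "net_charge_delta"), 0)

  scaled <- scale_charges(topo, c(1, 3), 0.81)
  expect_equal(scaled$atoms$charge, c(0.162, -0.5, 0.243), tolerance = 1e-12)
  expect_equal(attr(scaled, "net_charge_delta"),
               (0.81 - 1) * (0.2 + 0.3), tolerance = 1e-12)

  expect_warning(empty <- scale_charges(topo, integer(0), 0.81), "empty")
  expect_equal(empty$atoms$charge, atoms$charge)
})

test_that("gromacs topology sections round-trip", {
  txt <- c("[ atoms ]",
           ";  nr type resnr res atom cgnr charge mass",
           "1 c3 1 SUG C1 1 0.1170 12.0100",
           "2 os 1 SUG O1 2 -0.3890 16.0000",
           "3 c3 1 SUG C2 3 0.1170 12.0100",
           "4 hc 1 SUG H1 4 0.0550 1.0080",
           "",
           "[ dihedrals ]",
           "1 2 3 4 9 0.000 0.66944 3",
           "1 2 3 4 9 180.000 1.04600 2")
  topo <- parse_gromacs_topology(txt)
  expect_identical(nrow(topo$atoms), 4L)
  expect_identical(nrow(topo$dihedrals), 2L)
  expect_equal(sum(topo$atoms$charge), -0.1, tolerance = 1e-9)

  rt <- parse_gromacs_topology(write_gromacs_topology(topo))
  expect_equal(rt$atoms$charge, topo$atoms$charge, tolerance = 1e-9)
  expect_equal(rt$dihedrals$barrier_kj, topo$dihedrals$barrier_kj,
               tolerance = 1e-9)
})
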