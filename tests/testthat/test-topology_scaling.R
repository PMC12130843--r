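# Charge scaling in both force-field conventions, ion sigma
# interpolation, and the Born/Eyring analytic utilities.

test_that("group scaling multiplies charged-group charges and preserves q x formal", {
  f <- tempfile(fileext = ".itp")
  residues <- data.frame(residue = c("ASP", "GLU", "LYS", "ARG"),
                         formal = c(-1L, -1L, 1L, 1L))
  groups <- write_test_topology(f, residues)
  top <- read_topology(f)
  for (q in c(1.0, 0.78, 0.65)) {
    scaled <- scale_group_charges(top, groups, q)
    net <- residue_net_charges(scaled)
    expect_equal(net$net_charge, q * residues$formal, tolerance = 1e-10)
    # non-group atoms untouched
    bb <- scaled$atoms$atom %in% c("BB1", "BB2")
    expect_identical(scaled$atoms$charge[bb], top$atoms$charge[bb])
  }
  # q = 1 is the identity
  expect_identical(scale_group_charges(top, groups, 1.0)$atoms$charge,
                   top$atoms$charge)
})

test_that("a monatomic ion is scaled by q and the ASP example sums to -0.78", {
  top <- read_topology(system.file("extdata", "example_topology.itp",
                                   package = "eccperm"))
  scaled <- scale_group_charges(top, default_charged_groups(top), q = 0.78)
  net <- residue_net_charges(scaled)
  expect_equal(net$net_charge[net$residue == "ASP"], -0.78, tolerance = 1e-9)
  expect_equal(scaled$atoms$charge[scaled$atoms$residue == "POT"], 0.78,
               tolerance = 1e-12)
  # water untouched, whole system scales as q * 0 = 0
  expect_equal(net$net_charge[net$residue == "SOL"], 0, tolerance = 1e-12)
  expect_equal(sum(scaled$atoms$charge), 0, tolerance = 39 * 1e-6)
})

test_that("charge conservation: scaled net charge is q x original net, neutral stays neutral", {
  f <- tempfile(fileext = ".itp")
  # net +2 system: 2 LYS, 1 ASP, 1 GLU -> +2 -2 = 0; add 2 extra LYS
  residues <- data.frame(residue = c("LYS", "LYS2", "ASP", "GLU", "HISP"),
                         formal = c(1L, 1L, -1L, -1L, 1L))
  groups <- write_test_topology(f, residues, group_n = 4)
  top <- read_topology(f)
  Q0 <- sum(top$atoms$charge)
  for (q in seq(0.65, 1.0, by = 0.05)) {
    scaled <- scale_group_charges(top, groups, q)
    expect_equal(sum(scaled$atoms$charge), q * Q0,
                 tolerance = nrow(top$atoms) * 1e-6)
  }
})

test_that("scaling with q then 1/q recovers the original charges", {
  top <- read_topology(system.file("extdata", "example_topology.itp",
                                   package = "eccperm"))
  groups <- default_charged_groups(top)
  scaled <- scale_group_charges(top, groups, 0.73)
  # undo by scaling the scaled groups with the reciprocal weight
  back <- scaled
  back$atoms$charge[scaled$modified] <-
    scaled$atoms$charge[scaled$modified] / 0.73
  expect_true(all(abs(back$atoms$charge - top$atoms$charge) < 1e-9))
})

test_that("group scaling rejects non-integral groups and unknown residues", {
  f <- tempfile(fileext = ".itp")
  groups <- write_test_topology(f, data.frame(residue = "ASP", formal = -1L))
  top <- read_topology(f)
  expect_error(scale_group_charges(top, c(groups, list(GLU = "G1")), 0.8),
               "absent from the topology")
  # corrupt one group charge so the sum is not integral
  bad <- top
  bad$atoms$charge[bad$atoms$atom == "G1"] <-
    bad$atoms$charge[bad$atoms$atom == "G1"] + 0.01
  expect_error(scale_group_charges(bad, groups, 0.8), "not integral")
  expect_error(scale_group_charges(top, groups, 0), "scaling factor")
  expect_error(scale_group_charges(top, groups, 1.2), "scaling factor")
})

test_that("weighted scaling averages charged and neutral states with weight q", {
  charged <- c(CB = -0.28, CG = 0.62, OD1 = -0.80, OD2 = -0.76, HD = 0.22)
  charged <- charged / sum(charged) * -1  # normalize to exactly -1
  neutral <- c(CB = -0.21, CG = 0.75, OD1 = -0.60, OD2 = -0.55, HD = 0.61)
  neutral <- neutral - sum(neutral) / length(neutral)  # exactly 0
  q <- 0.75
  out <- scale_weighted_charges(charged, neutral, q)
  expect_equal(unname(out), unname(q * charged + (1 - q) * neutral))
  expect_equal(sum(out), q * -1, tolerance = 1e-12)
  # hand arithmetic: charged -0.80, neutral -0.60, q = 0.75 -> -0.75
  out2 <- scale_weighted_charges(c(OD1 = -0.80, X = -0.20),
                                 c(OD1 = -0.60, X = 0.60), 0.75)
  expect_equal(unname(out2[["OD1"]]), -0.75, tolerance = 1e-12)
  # q = 1 returns the charged state unchanged
  expect_equal(scale_weighted_charges(charged, neutral, 1), charged)
})

test_that("weighted scaling rejects mismatched atoms and non-neutral reference", {
  charged <- c(A = 0.6, B = 0.4)
  neutral <- c(A = 0.1, B = -0.1)
  expect_error(scale_weighted_charges(charged, c(A = 0.1, C = -0.1), 0.8),
               "mismatch")
  expect_error(scale_weighted_charges(charged, c(A = 0.2, B = -0.1), 0.8),
               "sum to 0")
  expect_error(scale_weighted_charges(c(A = 0.3, B = 0.4), neutral, 0.8),
               "sum to \\+-1")
  # weighted equals group mode when the states differ only inside the group
  expect_equal(unname(scale_weighted_charges(charged, c(A = 0, B = 0), 0.8)),
               0.8 * unname(charged))
})

test_that("ion sigma interpolation is exact at anchors and linear between them", {
  tab <- data.frame(q_anchor = seq(1.00, 0.65, by = -0.05),
                    sigma = 0.3 - 0.1 * (1 - seq(1.00, 0.65, by = -0.05)))
  # closed form is itself linear: interpolation reproduces it everywhere
  qs <- seq(0.65, 1.00, by = 0.013)
  expect_equal(interpolate_ion_sigma(tab, qs), 0.3 - 0.1 * (1 - qs),
               tolerance = 1e-12)
  # exact at anchors
  expect_identical(interpolate_ion_sigma(tab, 0.80), tab$sigma[tab$q_anchor == 0.80])
  # midpoint of two anchors
  tab2 <- data.frame(q_anchor = c(0.80, 0.75), sigma = c(0.30, 0.28))
  expect_equal(interpolate_ion_sigma(tab2, 0.775), 0.29, tolerance = 1e-12)
  expect_error(interpolate_ion_sigma(tab, 0.60), "anchor range")
  expect_error(interpolate_ion_sigma(tab, 1.05), "anchor range")
})

test_that("shipped example anchor table reads and interpolates", {
  tab <- read_sigma_anchors(system.file("extdata", "sigma_anchors_example.csv",
                                        package = "eccperm"), ion = "K")
  expect_equal(nrow(tab), 8)
  s <- interpolate_ion_sigma(tab, 0.78)
  expect_true(s > min(tab$sigma) && s < max(tab$sigma))
  expect_equal(interpolate_ion_sigma(tab, 0.75),
               tab$sigma[tab$q_anchor == 0.75])
})

test_that("Born-model target scales as q^2 and is monotone in q for dG < 0", {
  expect_equal(born_scaled_solvation_target(-80, 1.0), -80)
  expect_equal(born_scaled_solvation_target(-80, 0.0), 0)
  expect_equal(born_scaled_solvation_target(-80, 0.78), -48.672, tolerance = 1e-12)
  qs <- seq(0, 1, by = 0.05)
  vals <- born_scaled_solvation_target(-80, qs)
  expect_true(all(diff(vals) < 0))  # increasing q -> more negative, toward dG
  expect_error(born_scaled_solvation_target(-80, 1.2), "\\[0, 1\\]")
})

test_that("Born electronic term matches direct evaluation with CODATA constants", {
  expect_equal(born_electronic_term(z = 1, r0 = 0.2, q = 1), 0)
  expect_equal(born_electronic_term(z = 0, r0 = 0.2, q = 0.5), 0)
  cc <- ecc_constants()
  expected <- -cc$N_A * cc$e_C^2 / (8 * pi * cc$eps0 * 0.2e-9) / cc$J_per_kcal
  expect_equal(born_electronic_term(z = 1, r0 = 0.2, q = 0), expected)
  # consistency: dG_exp - dG_ele recovers the q^2 target when dG_exp is
  # itself the Born expression at full charge
  dG_exp <- born_electronic_term(z = 1, r0 = 0.2, q = 0)
  q <- 0.78
  expect_equal(dG_exp - born_electronic_term(z = 1, r0 = 0.2, q = q),
               born_scaled_solvation_target(dG_exp, q), tolerance = 1e-10)
  expect_error(born_electronic_term(z = 1, r0 = -0.1, q = 0.5), "positive")
})

test_that("Eyring barrier differences reproduce the printed benchmark values", {
  expect_equal(round(eyring_barrier_difference(10, 310), 1), 1.4)
  expect_equal(round(eyring_barrier_difference(2.5, 310), 1), 0.6)
  expect_equal(eyring_barrier_difference(1, 310), 0)
  expect_error(eyring_barrier_difference(-1, 310), "positive")
  # log additivity over random ratio pairs
  set.seed(7)
  for (k in 1:20) {
    r1 <- runif(1, 0.1, 20); r2 <- runif(1, 0.1, 20)
    expect_equal(eyring_barrier_difference(r1 * r2, 310),
                 eyring_barrier_difference(r1, 310) +
                   eyring_barrier_difference(r2, 310),
                 tolerance = 1e-12)
  }
})

test_that("dielectric-to-scaling-factor relation is sqrt(1/eps)", {
  expect_equal(round(scaling_factor_from_dielectric(2), 1), 0.7)
  expect_equal(scaling_factor_from_dielectric(1), 1)
  expect_equal(scaling_factor_from_dielectric(4), 0.5)
  expect_error(scaling_factor_from_dielectric(0.5), ">= 1")
})
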