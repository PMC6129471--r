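# Screened electrostatics: grids, effective charges, energies, forces,
# excluded volume.

test_that("DH grid of a unit charge matches the closed form beyond 2 spacings", {
  sol <- point_solute(c(0, 0, 0), 1)
  g <- debye_huckel_grid(sol, spacing = 1, padding = 12)
  ax <- lapply(1:3, function(k) g$origin[k] + (seq_len(g$dims[k]) - 1) * g$spacing)
  nodes <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  r <- sqrt(rowSums(nodes^2))
  keep <- r > 2 * g$spacing
  exact <- dh_exact(nodes[keep, ], c(0, 0, 0), 1)
  vals <- as.vector(g$values)[keep]
  expect_lt(max(abs(vals - exact) / abs(exact)), 0.005)
})

test_that("kappa -> 0 limit reduces to plain Coulomb in the solvent dielectric", {
  sol <- point_solute(c(0, 0, 0), 1)
  g <- debye_huckel_grid(sol, spacing = 1, padding = 10, ionic_strength = 0)
  p <- c(4, 3, 0)
  expect_equal(grid_values_at(g, p), (1.67087e5 / 298.15) / 78.54 / 5,
               tolerance = 1e-6)
})

test_that("opposite charges at the same point superpose to zero", {
  sol <- point_solute(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, -1))
  g <- debye_huckel_grid(sol, spacing = 1, padding = 8)
  expect_equal(max(abs(g$values)), 0)
})

test_that("OpenDX grids round-trip and the hand-written fixture parses", {
  g0 <- read_dx_grid(system.file("extdata", "tiny.dx", package = "chromadock"))
  expect_equal(g0$dims, c(2L, 2L, 2L))
  # file order is z-fastest: value 2 belongs to node (1,1,2)
  expect_equal(g0$values[1, 1, 1], 1)
  expect_equal(g0$values[1, 1, 2], 2)
  expect_equal(g0$values[1, 2, 1], 3)
  expect_equal(g0$values[2, 1, 1], 5)
  expect_equal(g0$values[2, 2, 2], 8)

  sol <- point_solute(rbind(c(0, 0, 0), c(3, 1, -2)), c(1, -1))
  g <- debye_huckel_grid(sol, spacing = 1.5, padding = 6)
  tmp <- tempfile(fileext = ".dx")
  write_dx_grid(g, tmp)
  back <- read_dx_grid(tmp)
  expect_equal(back$dims, g$dims)
  expect_equal(back$origin, g$origin, tolerance = 1e-5)
  expect_equal(as.vector(back$values), as.vector(g$values), tolerance = 1e-5)
})

test_that("an APBS-style header variant is accepted", {
  tmp <- tempfile(fileext = ".dx")
  writeLines(c(
    "# Data from APBS 1.4",
    "# POTENTIAL (kT/e)",
    "object 1 class gridpositions counts 2 2 2",
    "origin -1.0e+00 -1.0e+00 0.0e+00",
    "delta 5.0e-01 0.0e+00 0.0e+00",
    "delta 0.0e+00 5.0e-01 0.0e+00",
    "delta 0.0e+00 0.0e+00 5.0e-01",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    "1.0e+00 -1.0e+00 2.0e+00",
    "-2.0e+00 3.0e+00 -3.0e+00",
    "4.0e+00 -4.0e+00",
    "attribute \"dep\" string \"positions\""), tmp)
  g <- read_dx_grid(tmp)
  expect_equal(g$spacing, 0.5)
  expect_equal(g$origin, c(-1, -1, 0))
  expect_equal(g$values[1, 1, 2], -1)
})

test_that("effective-charge fit recovers point charges placed on the sites", {
  set.seed(31)
  xyz <- matrix(runif(15, -5, 5), ncol = 3)
  q <- c(1, 1, -1, 1, -1)
  sol <- point_solute(xyz, q)
  g <- debye_huckel_grid(sol, spacing = 1, padding = 12)
  fit <- fit_effective_charges(sol, g,
                               sites = data.frame(x = xyz[, 1], y = xyz[, 2],
                                                  z = xyz[, 3], label = "q"))
  expect_equal(fit$charges, q, tolerance = 2e-2)
  expect_lt(fit$residual, 0.02)
  # net fitted charge tracks the formal net charge within 5 percent
  expect_lt(abs(fit$net_charge - sum(q)) / abs(sum(q)), 0.05)
})

test_that("effective-charge fit of the toy LH reproduces the exterior field", {
  lh <- fx_lh()
  g <- debye_huckel_grid(lh$solute, spacing = 1, padding = 12)
  fit <- fit_effective_charges(lh$solute, g)
  expect_lte(length(fit$charges), nrow(lh$solute$atoms))
  expect_lt(fit$residual, 0.2)
  expect_lt(abs(fit$net_charge - 11) / 11, 0.05)
  expect_error(fit_effective_charges(lh$solute, g, shell = c(6, 3)),
               "no points")
})

test_that("interaction energy matches the closed form and is frame-invariant", {
  src <- point_solute(c(0, 0, 0), 1)
  g <- debye_huckel_grid(src, spacing = 1, padding = 15)
  probe <- formal_effective_charges(point_solute(c(0, 0, 0), 1))
  for (t in list(c(6.3, 1.1, -2.7), c(0.4, -8.6, 3.3))) {
    E <- interaction_energy(g, probe, pose(c(1, 0, 0, 0), t))
    expect_equal(E, dh_exact(t, c(0, 0, 0), 1), tolerance = 0.01)
  }
  # zero-charge probe
  null_probe <- probe
  null_probe$charges <- 0
  expect_equal(interaction_energy(g, null_probe, pose(c(1, 0, 0, 0), c(5, 0, 0))), 0)
  # rotating the probe about its own center leaves a monopole energy fixed
  e1 <- interaction_energy(g, probe, pose(c(1, 0, 0, 0), c(5, 2, 1)))
  e2 <- interaction_energy(g, probe, pose(quat_random(), c(5, 2, 1)))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("symmetrized energy is symmetric under solute exchange", {
  a <- point_solute(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1))
  b <- point_solute(rbind(c(0, 0, 0), c(0, 2, 0)), c(-1, 1))
  ga <- debye_huckel_grid(a, spacing = 1, padding = 10)
  gb <- debye_huckel_grid(b, spacing = 1, padding = 10)
  ca <- formal_effective_charges(a)
  cb <- formal_effective_charges(b)
  pb <- pose(c(1, 0, 0, 0), c(7, 1, 0))
  e_ab <- interaction_energy(ga, cb, pb, grid_B = gb, charges_A = ca)
  # exchange roles: hold B fixed at its placed coordinates, move A's frame
  b_placed <- transform_solute(b, pb)
  gb2 <- debye_huckel_grid(b_placed, spacing = 1, padding = 10)
  cb2 <- formal_effective_charges(b_placed)
  e_ba <- interaction_energy(gb2, ca, pose(c(1, 0, 0, 0), geometric_center(a)),
                             grid_B = ga, charges_A = cb2)
  expect_equal(e_ab, e_ba, tolerance = 0.02)
})

test_that("forces and torques agree with central differences", {
  set.seed(7)
  src <- point_solute(rbind(c(0, 0, 0), c(3, -1, 2)), c(1, -0.5))
  g <- debye_huckel_grid(src, spacing = 1, padding = 14)
  probe_sol <- point_solute(rbind(c(1.2, 0.3, -0.4), c(-0.8, 0.9, 0.6)),
                            c(0.7, -0.2))
  probe <- formal_effective_charges(probe_sol)
  p <- pose(quat_random(), c(6.37, 2.61, -1.93))
  ft <- force_and_torque(g, probe, p)
  h <- 1e-5
  for (ax in 1:3) {
    dt <- numeric(3); dt[ax] <- h
    num <- -(interaction_energy(g, probe, pose(p$q, p$t + dt)) -
               interaction_energy(g, probe, pose(p$q, p$t - dt))) / (2 * h)
    expect_equal(ft$force[ax], num, tolerance = 1e-4)
  }
  for (ax in 1:3) {
    dq <- quat_from_axis_angle(diag(3)[, ax], h)
    num <- -(interaction_energy(g, probe, pose(quat_multiply(dq, p$q), p$t)) -
               interaction_energy(g, probe,
                                  pose(quat_multiply(quat_from_axis_angle(
                                    diag(3)[, ax], -h), p$q), p$t))) / (2 * h)
    expect_equal(ft$torque[ax], num, tolerance = 1e-4)
  }
  # zero charges give zero wrench
  z <- probe; z$charges <- c(0, 0)
  fz <- force_and_torque(g, z, p)
  expect_equal(fz$force, c(0, 0, 0))
  expect_equal(fz$torque, c(0, 0, 0))
  # opposite charges attract: radial force toward a single positive source
  g1 <- debye_huckel_grid(point_solute(c(0, 0, 0), 1), spacing = 1,
                          padding = 14)
  att <- formal_effective_charges(point_solute(c(0, 0, 0), -1))
  fa <- force_and_torque(g1, att, pose(c(1, 0, 0, 0), c(8.2, 0.3, 0.1)))
  expect_lt(fa$force[1], 0)
})

test_that("exclusion grid agrees with a brute-force pairwise check", {
  nuc <- fx_nucleosome()
  lh <- fx_lh()
  excl <- fx_exclusion()
  # far away: no overlap; centered on the core: overlap
  expect_false(check_overlap(excl, lh, pose(c(1, 0, 0, 0), c(500, 0, 0))))
  expect_true(check_overlap(excl, lh, pose(c(1, 0, 0, 0), c(0, 0, 0))))

  nxyz <- as.matrix(nuc$solute$atoms[, c("x", "y", "z")])
  reach <- nuc$solute$atoms$radius + excl$margin
  brute <- function(p) {
    xyz <- atoms_at_pose(lh$solute, p)
    d2 <- outer(rowSums(xyz^2), rowSums(nxyz^2), `+`) - 2 * xyz %*% t(nxyz)
    min(sweep(sqrt(pmax(d2, 0)), 2, reach)) < 0
  }
  set.seed(99)
  half_diag <- excl$spacing * sqrt(3) / 2
  n_checked <- 0
  for (i in 1:300) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- pose(quat_random(), geometric_center(nuc$solute) +
                runif(1, 40, 95) * u)
    g_says <- check_overlap(excl, lh, p)
    b_says <- brute(p)
    if (b_says) {
      # no false negatives beyond one cell diagonal of slack: recheck with
      # the diagonal tolerance
      xyz <- atoms_at_pose(lh$solute, p)
      d2 <- outer(rowSums(xyz^2), rowSums(nxyz^2), `+`) - 2 * xyz %*% t(nxyz)
      depth <- -min(sweep(sqrt(pmax(d2, 0)), 2, reach))
      if (depth > half_diag) expect_true(g_says)
    } else {
      # false positives allowed only within one cell diagonal of the surface
      if (g_says) {
        xyz <- atoms_at_pose(lh$solute, p)
        d2 <- outer(rowSums(xyz^2), rowSums(nxyz^2), `+`) - 2 * xyz %*% t(nxyz)
        clearance <- min(sweep(sqrt(pmax(d2, 0)), 2, reach))
        expect_lt(clearance, half_diag)
      }
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
})
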