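# Brownian propagator, encounter criteria, recorded-set maintenance, and
# the trajectory drivers.

test_that("configuration invariants are enforced", {
  expect_error(bd_config(start_radius = 200, stop_radius = 190), "exceed")
  expect_error(bd_config(start_radius = 90, encounter_c2c_max = 98), "exceed")
  expect_error(bd_config(capacity = 0), "positive")
  expect_error(bd_config(max_steps = 1e9), "hard limit")
  expect_s3_class(bd_config(), "bd_config")
})

test_that("bd_step is exact for zero force and zero noise", {
  cfg <- bd_config(D_trans = 0.02, D_rot = 1e-4)
  p <- pose(quat_random(), c(10, 20, 30))
  p2 <- bd_step(p, c(0, 0, 0), c(0, 0, 0), cfg, noise = rep(0, 6))
  expect_equal(p2$t, p$t)
  expect_equal(p2$q, p$q)
  # deterministic drift: displacement = D F dt
  p3 <- bd_step(p, c(1, 0, 0), c(0, 0, 0), cfg, noise = rep(0, 6))
  expect_equal(p3$t - p$t, c(0.02, 0, 0))
  # oversized step aborts
  expect_error(bd_step(p, c(1e5, 0, 0), c(0, 0, 0), cfg, noise = rep(0, 6)),
               "timestep too large")
})

test_that("free diffusion recovers D_trans through the Einstein relation", {
  set.seed(101)
  D <- 0.0175
  n_steps <- 10000
  fin <- chromadock:::bd_diffusion_cpp(1000, n_steps, 1, D, 0)
  msd <- rowSums(fin^2)
  Dhat <- mean(msd) / (6 * n_steps)
  se <- sd(msd) / (6 * n_steps) / sqrt(length(msd))
  expect_lt(abs(Dhat - D), 3 * se)
})

test_that("harmonic-field sampling matches the Boltzmann density", {
  set.seed(102)
  k <- 0.5
  # theta = D k dt = 0.01 keeps the Euler discretization bias far below
  # the KS resolution at this sample size
  fin <- chromadock:::bd_diffusion_cpp(100000, 1000, 1, 0.02, k)
  ks <- suppressWarnings(ks.test(as.vector(fin), "pnorm", 0, sqrt(1 / k)))
  expect_gt(ks$p.value, 0.01)
})

test_that("encounter criteria require both distance conditions", {
  nuc <- fx_nucleosome()
  lh <- fx_lh()
  cfg <- bd_config()
  nc <- geometric_center(nuc$solute)
  # LH center at the dyad point: both criteria hold
  expect_true(is_encounter(pose(c(1, 0, 0, 0), nuc$dyad_point), lh, nuc, cfg))
  # c2c inside 98 but dyad distance beyond 40
  dir_t <- nuc$dyad_axis
  perp <- c(-dir_t[2], dir_t[1], 0)
  p1 <- pose(c(1, 0, 0, 0), nuc$dyad_point + 45 * perp / sqrt(sum(perp^2)))
  expect_lt(sqrt(sum((p1$t - nc)^2)), 98)
  expect_false(is_encounter(p1, lh, nuc, cfg))
  # dyad distance inside the limit but c2c beyond it: on this fixture the
  # dyad sits ~50 A from the center, so exercise the c2c branch with a
  # tighter custom threshold
  cfg2 <- bd_config(encounter_c2c_max = 60)
  p2 <- pose(c(1, 0, 0, 0), nc + (nuc$dyad_point - nc) * 61 /
               sqrt(sum((nuc$dyad_point - nc)^2)))
  expect_lt(sqrt(sum((p2$t - nuc$dyad_point)^2)), 40)
  expect_false(is_encounter(p2, lh, nuc, cfg2))
  expect_true(is_encounter(pose(c(1, 0, 0, 0), nuc$dyad_point), lh, nuc, cfg2))
})

test_that("single events follow the recording and substitution rules", {
  lh <- fx_lh()
  cfg <- bd_config(capacity = 10)
  rs <- new_recorded_set(lh, cfg)
  e1 <- list(pose = pose(c(1, 0, 0, 0), c(50, 0, 0)), energy = -5)
  rs <- update_recorded_set(rs, e1)
  expect_equal(rs$n, 1L)
  expect_equal(rs$count, 1)
  expect_equal(attr(rs, "action"), "new")
  # 0.5 A away, lower energy: substitution inheriting count + 1
  e2 <- list(pose = pose(c(1, 0, 0, 0), c(50.5, 0, 0)), energy = -7)
  rs <- update_recorded_set(rs, e2)
  expect_equal(rs$n, 1L)
  expect_equal(rs$E, -7)
  expect_equal(rs$count, 2)
  expect_equal(attr(rs, "action"), "substituted")
  # nearby but higher energy: count of the existing record grows
  e3 <- list(pose = pose(c(1, 0, 0, 0), c(50.6, 0, 0)), energy = -6)
  rs <- update_recorded_set(rs, e3)
  expect_equal(rs$n, 1L)
  expect_equal(rs$count, 3)
  expect_equal(attr(rs, "action"), "counted")
  # far away: a second record
  e4 <- list(pose = pose(c(1, 0, 0, 0), c(80, 0, 0)), energy = -1)
  rs <- update_recorded_set(rs, e4)
  expect_equal(rs$n, 2L)
  expect_equal(rs$seen, 4)
})

test_that("the maintained archive equals the brute-force oracle on 10k events", {
  lh <- fx_lh()
  cfg <- bd_config(capacity = 80)
  ev <- synthetic_event_stream(10000, seed = 17, planted_clusters = 8,
                               spread = 1.3, center_sep = 15)
  rs <- new_recorded_set(lh, cfg)
  for (e in ev) rs <- update_recorded_set(rs, e)
  orc <- recorder_oracle(ev, lh, capacity = 80)
  expect_equal(rs$n, length(orc$E))
  expect_equal(sort(rs$E), sort(orc$E))
  expect_equal(rs$count[order(rs$E)], orc$count[order(orc$E)])
  expect_equal(rs$seen, orc$seen)
})

test_that("archive invariants hold under random event streams", {
  lh <- fx_lh()
  cfg <- bd_config(capacity = 25)
  meta <- chromadock:::.rmsd_meta(lh)
  for (seed in c(3, 4)) {
    ev <- synthetic_event_stream(2000, seed = seed, planted_clusters = 5,
                                 spread = 2.0, center_sep = 10)
    rs <- new_recorded_set(lh, cfg)
    for (e in ev) rs <- update_recorded_set(rs, e)
    expect_lte(rs$n, cfg$capacity)
    expect_true(all(rs$count >= 1))
    expect_equal(rs$seen, 2000)
    # energy-ranked retention: every retained energy is finite
    expect_true(all(is.finite(rs$E)))
  }
})

test_that("zero-spread streams collapse onto the planted centers", {
  lh <- fx_lh()
  cfg <- bd_config(capacity = 100)
  ev <- synthetic_event_stream(300, seed = 5, planted_clusters = 3, spread = 0)
  rs <- new_recorded_set(lh, cfg)
  for (e in ev) rs <- update_recorded_set(rs, e)
  expect_equal(rs$n, 3L)
  expect_equal(sum(rs$count), 300)
  expect_equal(as.numeric(sort(rs$count)), c(100, 100, 100))
})

test_that("trajectories are reproducible and respect the stop sphere", {
  lh <- fx_lh()
  nuc <- fx_nucleosome()
  grids <- fx_grids()
  cfg <- fx_bd_config(max_steps = 3e4)
  r1 <- run_trajectory(lh, nuc, grids, cfg, seed = 11)
  r2 <- run_trajectory(lh, nuc, grids, cfg, seed = 11)
  expect_identical(r1$steps, r2$steps)
  expect_identical(r1$events, r2$events)
  expect_true(r1$exit_reason %in% c("stopped", "max_steps"))
  # different seed gives a different trajectory (step counts can tie at
  # the cap, so compare the full trajectory summaries)
  r3 <- run_trajectory(lh, nuc, grids, cfg, seed = 12)
  expect_false(identical(list(r1$steps, r1$rejections, r1$events),
                         list(r3$steps, r3$rejections, r3$events)))
})

test_that("the engine recorder agrees with event replay through the rules", {
  lh <- fx_lh()
  nuc <- fx_nucleosome()
  grids <- fx_grids()
  cfg <- fx_bd_config(max_steps = 6e4, capacity = 200)
  found <- FALSE
  for (seed in 21:60) {
    r <- run_trajectory(lh, nuc, grids, cfg, seed = seed, collect_events = TRUE)
    if (r$n_events > 10) { found <- TRUE; break }
  }
  expect_true(found)
  # replay the raw event log through the single-event updater
  rs <- new_recorded_set(lh, cfg)
  for (i in seq_len(nrow(r$events))) {
    ev <- r$events[i, ]
    rs <- update_recorded_set(rs, list(
      pose = pose(c(ev$qw, ev$qx, ev$qy, ev$qz), c(ev$tx, ev$ty, ev$tz)),
      energy = ev$energy, traj = 1L, step = as.integer(ev$step)))
  }
  expect_equal(rs$n, r$recorded$n)
  expect_equal(sort(rs$E), sort(r$recorded$E))
  expect_equal(rs$count[order(rs$E)], r$recorded$count[order(r$recorded$E)])
})

test_that("run_docking aggregates deterministically and zero trajectories give an empty set", {
  lh <- fx_lh()
  nuc <- fx_nucleosome()
  grids <- fx_grids()
  cfg0 <- fx_bd_config(n_trajectories = 0)
  rs0 <- run_docking(lh, nuc, grids, cfg0)
  expect_equal(rs0$n, 0L)
  cfg <- fx_bd_config(n_trajectories = 8, rng_seed = 5, max_steps = 4e4)
  rs1 <- run_docking(lh, nuc, grids, cfg)
  rs2 <- run_docking(lh, nuc, grids, cfg)
  expect_identical(rs1$E, rs2$E)
  expect_identical(rs1$count, rs2$count)
  expect_identical(rs1$seen, rs2$seen)
})

test_that("recorded poses never overlap the exclusion grid", {
  lh <- fx_lh()
  nuc <- fx_nucleosome()
  grids <- fx_grids()
  cfg <- fx_bd_config(n_trajectories = 6, rng_seed = 9, max_steps = 4e4)
  rs <- run_docking(lh, nuc, grids, cfg)
  if (rs$n > 0) {
    df <- as.data.frame(rs)
    for (i in seq_len(min(nrow(df), 50))) {
      p <- pose(as.numeric(df[i, c("qw", "qx", "qy", "qz")]),
                as.numeric(df[i, c("tx", "ty", "tz")]))
      expect_false(check_overlap(grids$exclusion, lh, p))
    }
  }
})
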