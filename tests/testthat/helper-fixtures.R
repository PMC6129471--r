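# Shared fixtures (built once per test run) and independent brute-force
# oracles used to cross-check the implementation.

.fx <- new.env(parent = emptyenv())

fx_nucleosome <- function() {
  if (is.null(.fx$nuc)) .fx$nuc <- build_ideal_nucleosome(fixture_spec())
  .fx$nuc
}

fx_lh <- function() {
  if (is.null(.fx$lh)) .fx$lh <- build_toy_lh(fixture_spec())
  .fx$lh
}

fx_sites <- function() {
  if (is.null(.fx$sites)) {
    .fx$sites <- groove_site_coords(enumerate_groove_sites(fx_nucleosome()),
                                    fx_nucleosome())
  }
  .fx$sites
}

fx_exclusion <- function() {
  if (is.null(.fx$excl)) .fx$excl <- build_exclusion_grid(fx_nucleosome())
  .fx$excl
}

# coarse docking bundle for engine unit tests (2 A grid keeps it light)
fx_grids <- function() {
  if (is.null(.fx$grids)) {
    .fx$grids <- prepare_docking(fx_lh(), fx_nucleosome(),
                                 bd_config(auto_scale = TRUE), spacing = 2)
  }
  .fx$grids
}

fx_bd_config <- function(...) {
  scale_bd_config(bd_config(..., auto_scale = TRUE), fx_nucleosome())
}

# a tiny point-charge solute for electrostatics oracles
point_solute <- function(xyz, q, radius = 0, names = "X") {
  xyz <- rbind(xyz)
  solute(data.frame(atom_id = seq_len(nrow(xyz)), atom_name = names,
                    residue_name = "ION", residue_index = seq_len(nrow(xyz)),
                    chain_id = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    charge = q, radius = radius, stringsAsFactors = FALSE),
         label = "points")
}

# closed-form screened Coulomb of point charges (independent oracle)
dh_exact <- function(points, src_xyz, src_q, src_a = 0,
                     ionic_strength = 0.1, temperature = 298.15,
                     eps = 78.54) {
  kappa <- debye_kappa(ionic_strength, temperature, eps)
  pref <- 1.67087e5 / temperature / eps
  points <- rbind(points); src_xyz <- rbind(src_xyz)
  if (length(src_a) == 1) src_a <- rep(src_a, nrow(src_xyz))
  vapply(seq_len(nrow(points)), function(i) {
    r <- sqrt(rowSums(sweep(src_xyz, 2, points[i, ])^2))
    sum(pref * src_q * exp(-kappa * (r - src_a)) / ((1 + kappa * src_a) * r))
  }, numeric(1))
}

# literal brute-force implementation of the recording / substitution /
# counting rules, with direct coordinate RMSDs (quadratic-time oracle)
recorder_oracle <- function(events, lh, capacity, dedup = 1) {
  rows <- lh$solute$atoms$atom_name == "CA"
  if (!any(rows)) rows <- rep(TRUE, nrow(lh$solute$atoms))
  Y <- sweep(as.matrix(lh$solute$atoms[rows, c("x", "y", "z")]), 2,
             geometric_center(lh$solute))
  coords <- function(p) sweep(Y %*% t(quat_to_matrix(p$q)), 2, p$t, `+`)
  E <- numeric(0); cnt <- numeric(0); cc <- list(); seen <- 0
  for (e in events) {
    seen <- seen + 1
    pc <- coords(e$pose)
    rms <- if (length(E) == 0) numeric(0) else {
      vapply(cc, function(z) sqrt(mean(rowSums((pc - z)^2))), numeric(1))
    }
    nb <- which(rms <= dedup)
    if (length(nb) == 0) {
      if (length(E) < capacity) {
        E <- c(E, e$energy); cnt <- c(cnt, 1); cc[[length(E)]] <- pc
      } else if (e$energy < max(E)) {
        w <- which.max(E)
        E[w] <- e$energy; cnt[w] <- 1; cc[[w]] <- pc
      }
    } else {
      lower <- nb[E[nb] < e$energy]
      if (length(lower) > 0) {
        j <- lower[which.min(rms[lower])]
        cnt[j] <- cnt[j] + 1
      } else {
        j <- nb[which.min(rms[nb])]
        E[j] <- e$energy; cnt[j] <- cnt[j] + 1; cc[[j]] <- pc
      }
    }
  }
  list(E = E, count = cnt, seen = seen)
}

# all-pairs element-to-phosphate contact scan (grid-free oracle)
contacts_oracle <- function(lh, pose, nuc, sites, cutoff = 5.0) {
  a <- lh$solute$atoms
  xyz <- atoms_at_pose(lh$solute, pose)
  out <- list()
  for (el in c("alpha3", "beta1", "l1")) {
    rng <- lh$elements[[el]]
    rows <- a$residue_index >= rng[1] & a$residue_index <= rng[2]
    exyz <- xyz[rows, , drop = FALSE]
    hits <- integer(0)
    for (s in sites) {
      found <- FALSE
      for (i in seq_len(nrow(exyz))) {
        d <- sqrt(rowSums(sweep(s$phos_xyz, 2, exyz[i, ])^2))
        if (any(d <= cutoff)) { found <- TRUE; break }
      }
      if (found) hits <- c(hits, s$index)
    }
    out[[el]] <- sort(hits)
  }
  out
}

# all-pairs H-bond window scan (independent oracle)
hbond_oracle <- function(lh, pose, nuc, d_min = 3.2, d_max = 3.6) {
  la <- lh$solute$atoms
  na_ <- nuc$solute$atoms
  lrows <- grep("^[NO]", la$atom_name)
  drows <- which(na_$atom_name %in% c("P", "OP1", "OP2", "O1P", "O2P",
                                      "O3'", "O5'") &
                   !(na_$atom_id %in% nuc$core_atom_ids))
  lxyz <- atoms_at_pose(lh$solute, pose)[lrows, , drop = FALSE]
  n <- 0
  for (i in seq_along(lrows)) {
    for (j in drows) {
      d <- sqrt(sum((lxyz[i, ] - c(na_$x[j], na_$y[j], na_$z[j]))^2))
      if (d >= d_min && d <= d_max) n <- n + 1
    }
  }
  n
}

# random non-overlapping pose near the nucleosome (for property tests)
random_near_pose <- function(nuc, lh, radius_range = c(55, 90)) {
  repeat {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    r <- stats::runif(1, radius_range[1], radius_range[2])
    p <- pose(quat_random(), geometric_center(nuc$solute) + r * u)
    if (!check_overlap(fx_exclusion(), lh, p)) return(p)
  }
}

# the fixture's dyad twofold applied to a pose
twofold_pose <- function(p, nuc) {
  q2 <- quat_from_axis_angle(nuc$dyad_axis, pi)
  R2 <- quat_to_matrix(q2)
  pose(quat_multiply(q2, p$q),
       as.numeric(R2 %*% (p$t - nuc$dyad_point)) + nuc$dyad_point)
}
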