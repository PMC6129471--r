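## Rigid-body Brownian dynamics of the LH globular domain around a fixed
## nucleosome: configuration, the Ermak-McCammon step, encounter detection,
## the recorded encounter archive, and trajectory/docking drivers.

#' Brownian dynamics simulation configuration
#'
#' Defaults follow the docking protocol: 1 ps time step, trajectories
#' started on a 185 A sphere and stopped at 204 A, encounter criteria of
#' 98 A (center-to-center) and 40 A (dyad-to-LH-center), a 1 A RMSD
#' deduplication threshold, a 5000-complex archive, 10 clusters and 20000
#' trajectories. Diffusion coefficients default to Stokes-Einstein values
#' from an effective hydrodynamic radius (1.29 x radius of gyration),
#' assigned wholly to the mobile LH; water viscosity 0.89 mPa s.
#'
#' @param timestep ps.
#' @param start_radius,stop_radius start/stop sphere radii, Angstrom.
#' @param n_trajectories number of BD trajectories.
#' @param encounter_c2c_max,encounter_dyad_max encounter criteria, Angstrom.
#' @param dedup_rmsd archive deduplication RMSD, Angstrom.
#' @param capacity archive capacity (most favorable energies kept).
#' @param n_clusters number of pose clusters.
#' @param D_trans,D_rot diffusion coefficients (A^2/ps, rad^2/ps); `NULL`
#'   means Stokes-Einstein from the LH geometry at run time.
#' @param rng_seed master seed; per-trajectory seeds are derived from it.
#' @param max_steps cap on steps per trajectory.
#' @param max_step_displacement single-step displacement abort threshold,
#'   Angstrom.
#' @param energy_mode `"one_sided"` (LH charges in the nucleosome grid) or
#'   `"symmetrized"` (average of both one-sided evaluations).
#' @param auto_scale if TRUE, rescale start/stop spheres to the system
#'   size: start = nucleosome bounding radius + 30 A, stop = start + 19 A.
#' @return object of class `bd_config`.
#' @export
bd_config <- function(timestep = 1, start_radius = 185, stop_radius = 204,
                      n_trajectories = 20000, encounter_c2c_max = 98,
                      encounter_dyad_max = 40, dedup_rmsd = 1, capacity = 5000,
                      n_clusters = 10, D_trans = NULL, D_rot = NULL,
                      rng_seed = 1, max_steps = 2.5e5,
                      max_step_displacement = 10,
                      energy_mode = c("one_sided", "symmetrized"),
                      auto_scale = FALSE) {
  energy_mode <- match.arg(energy_mode)
  cfg <- structure(list(timestep = timestep, start_radius = start_radius,
                        stop_radius = stop_radius, n_trajectories = n_trajectories,
                        encounter_c2c_max = encounter_c2c_max,
                        encounter_dyad_max = encounter_dyad_max,
                        dedup_rmsd = dedup_rmsd, capacity = capacity,
                        n_clusters = n_clusters, D_trans = D_trans, D_rot = D_rot,
                        rng_seed = rng_seed, max_steps = max_steps,
                        max_step_displacement = max_step_displacement,
                        energy_mode = energy_mode, auto_scale = auto_scale),
                   class = "bd_config")
  validate_bd_config(cfg)
  cfg
}

#' @rdname bd_config
#' @param config a `bd_config` to validate.
#' @export
validate_bd_config <- function(config) {
  if (config$stop_radius <= config$start_radius) {
    stop("stop_radius must exceed start_radius")
  }
  if (config$start_radius <= config$encounter_c2c_max) {
    stop("start_radius must exceed encounter_c2c_max")
  }
  if (config$capacity <= 0) stop("capacity must be positive")
  if (config$timestep <= 0) stop("timestep must be positive")
  if (config$max_steps > 1e8) stop("max_steps above the 1e8 hard limit")
  invisible(config)
}

## Stokes-Einstein diffusion coefficients from an effective hydrodynamic
## radius R_h = 1.29 * Rg; kB T/(6 pi eta R_h) in A^2/ps units with water
## viscosity 0.89 mPa s at 298.15 K.
.stokes_einstein <- function(solute) {
  xyz <- as.matrix(solute$atoms[, c("x", "y", "z")])
  y <- sweep(xyz, 2, colMeans(xyz))
  rg <- sqrt(mean(rowSums(y^2)))
  rh <- 1.29 * rg
  list(D_trans = 0.2454 / rh, D_rot = 0.18403 / rh^3, R_h = rh)
}

## RMSD bookkeeping of the mobile solute: second-moment matrix and centroid
## of the C-alpha (or bead) positions in the body frame (centered at the
## geometric center of all atoms), used by the closed-form fixed-frame
## pose RMSD.
.rmsd_meta <- function(lh) {
  sol <- if (inherits(lh, "lh_model")) lh$solute else lh
  a <- sol$atoms
  rows <- which(a$atom_name == "CA")
  if (length(rows) == 0) rows <- seq_len(nrow(a))
  ctr <- geometric_center(sol)
  y <- sweep(as.matrix(a[rows, c("x", "y", "z")]), 2, ctr)
  list(M = crossprod(y), ybar = colMeans(y), n_atoms = length(rows))
}

#' One Ermak-McCammon step
#'
#' Overdamped rigid-body update: displacement
#' `D_trans * F * dt + R` with Gaussian noise of per-axis variance
#' `2 D_trans dt`, and an angular increment `D_rot * T * dt + R_rot`
#' applied as a quaternion increment and renormalized (energies in kT, so
#' kT = 1 in these units).
#'
#' @param pose current [pose].
#' @param force numeric(3), kT/Angstrom.
#' @param torque numeric(3), kT.
#' @param config a [bd_config] with `D_trans` and `D_rot` set.
#' @param noise optional numeric(6) standard-normal draws (translation,
#'   rotation); defaults to `rnorm(6)` from the current RNG stream.
#' @return the new [pose].
#' @export
bd_step <- function(pose, force, torque, config, noise = NULL) {
  stopifnot(all(is.finite(force)), all(is.finite(torque)))
  if (is.null(noise)) noise <- stats::rnorm(6)
  dt <- config$timestep
  dx <- config$D_trans * force * dt + sqrt(2 * config$D_trans * dt) * noise[1:3]
  if (sqrt(sum(dx^2)) > config$max_step_displacement) {
    stop("step displacement exceeds ", config$max_step_displacement,
         " A: timestep too large for the field")
  }
  dphi <- config$D_rot * torque * dt + sqrt(2 * config$D_rot * dt) * noise[4:6]
  ang <- sqrt(sum(dphi^2))
  q_new <- if (ang > 1e-14) {
    quat_multiply(quat_from_axis_angle(dphi, ang), pose$q)
  } else pose$q
  pose(q_new, pose$t + dx)
}

#' Encounter-complex criterion
#'
#' TRUE iff both geometric conditions hold: LH-to-nucleosome
#' center-to-center distance below `encounter_c2c_max` and LH center to
#' dyad point distance below `encounter_dyad_max`.
#'
#' @param pose LH [pose] (its translation is the LH geometric center).
#' @param lh an `lh_model` (unused beyond the center convention; kept for
#'   interface symmetry).
#' @param nuc a `nucleosome_model`.
#' @param config a [bd_config].
#' @return logical.
#' @export
is_encounter <- function(pose, lh, nuc, config) {
  nc <- geometric_center(nuc$solute)
  c2c <- sqrt(sum((pose$t - nc)^2))
  dd <- sqrt(sum((pose$t - nuc$dyad_point)^2))
  c2c < config$encounter_c2c_max && dd < config$encounter_dyad_max
}

#' Create an empty recorded encounter set
#'
#' The capacity-limited, energy-ranked, RMSD-deduplicated archive of
#' encounter complexes.
#'
#' @param lh the mobile `lh_model` (fixes the RMSD bookkeeping).
#' @param config a [bd_config] (capacity and deduplication RMSD).
#' @return object of class `recorded_set`.
#' @export
new_recorded_set <- function(lh, config) {
  meta <- .rmsd_meta(lh)
  structure(list(n = 0L, Q = matrix(numeric(0), 0, 4), T = matrix(numeric(0), 0, 3),
                 E = numeric(0), count = numeric(0), traj = integer(0),
                 step = integer(0), seen = 0,
                 meta = c(meta, list(dedup_rmsd = config$dedup_rmsd,
                                     capacity = config$capacity))),
            class = "recorded_set")
}

## recorder parameter list for the C++ side
.rec_params <- function(rs) {
  list(capacity = as.integer(rs$meta$capacity), dedup_rmsd = rs$meta$dedup_rmsd,
       M = rs$meta$M, ybar = rs$meta$ybar, n_atoms = as.integer(rs$meta$n_atoms))
}

.state_of <- function(rs) {
  list(n = rs$n, Q = rs$Q, T = rs$T, E = rs$E, count = rs$count,
       traj = rs$traj, step = rs$step, seen = rs$seen)
}

.set_state <- function(rs, st) {
  rs$n <- st$n; rs$Q <- st$Q; rs$T <- st$T; rs$E <- st$E
  rs$count <- st$count; rs$traj <- st$traj; rs$step <- st$step
  rs$seen <- st$seen
  rs
}

#' Apply one encounter event to the recorded set
#'
#' Implements the recording rules: a candidate farther than the
#' deduplication RMSD from every record is recorded as new if its energy
#' is within the `capacity` most favorable (evicting the worst when full);
#' a candidate within the deduplication RMSD of a record with lower energy
#' adds to that record's occurrence count (closest such record); a
#' candidate with lower energy than all its neighbors substitutes the
#' closest one, inheriting its count plus one.
#'
#' @param rs a [new_recorded_set()] archive.
#' @param candidate list with `pose` ([pose]), `energy` (kT), and
#'   optionally `traj`, `step`.
#' @param config unused (rules are fixed by the archive's own metadata);
#'   kept for interface stability.
#' @return the updated `recorded_set`; the applied action is attached as
#'   attribute `"action"` (`"new"`, `"substituted"`, `"counted"`,
#'   `"dropped"`).
#' @export
update_recorded_set <- function(rs, candidate, config = NULL) {
  st <- recorder_update_cpp(.state_of(rs), candidate$pose$q, candidate$pose$t,
                            candidate$energy,
                            as.integer(candidate$traj %||% 0L),
                            as.integer(candidate$step %||% 0L),
                            .rec_params(rs))
  out <- .set_state(rs, st)
  attr(out, "action") <- c("dropped", "new", "substituted", "counted")[st$action + 1]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recorded_set <- function(x, ...) {
  cat(sprintf("<recorded_set> %d records (capacity %d), %.0f encounters seen\n",
              x$n, x$meta$capacity, x$seen))
  if (x$n > 0) {
    cat(sprintf("  energy range [%.2f, %.2f] kT, total count %.0f\n",
                min(x$E), max(x$E), sum(x$count)))
  }
  invisible(x)
}

#' Recorded set as a flat table
#'
#' @param x a `recorded_set`.
#' @param ... unused.
#' @param row.names,optional unused (data.frame method signature).
#' @return data.frame sorted by energy with quaternion, translation,
#'   energy, count, trajectory and step columns.
#' @export
as.data.frame.recorded_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (x$n == 0) {
    return(data.frame(qw = numeric(0), qx = numeric(0), qy = numeric(0),
                      qz = numeric(0), tx = numeric(0), ty = numeric(0),
                      tz = numeric(0), energy = numeric(0), count = numeric(0),
                      traj = integer(0), step = integer(0)))
  }
  ord <- order(x$E)
  data.frame(qw = x$Q[ord, 1], qx = x$Q[ord, 2], qy = x$Q[ord, 3],
             qz = x$Q[ord, 4], tx = x$T[ord, 1], ty = x$T[ord, 2],
             tz = x$T[ord, 3], energy = x$E[ord], count = x$count[ord],
             traj = x$traj[ord], step = x$step[ord])
}

#' Prepare docking inputs (grids and charge sets)
#'
#' Convenience builder for the grid/charge bundle consumed by
#' [run_trajectory()] and [run_docking()]: the nucleosome potential grid,
#' the exclusion grid, the LH effective charges, and (for the symmetrized
#' energy mode) the LH grid and nucleosome charges.
#'
#' @param lh an `lh_model`.
#' @param nuc a `nucleosome_model`.
#' @param config a [bd_config].
#' @param spacing potential-grid spacing, Angstrom.
#' @param fit_charges if TRUE fit effective charges against the grids;
#'   if FALSE (default) use the solutes' own point charges directly.
#' @param cutoff per-atom cutoff passed to [debye_huckel_grid()].
#' @return list with elements `nuc_grid`, `exclusion`, `lh_charges`, and
#'   optionally `lh_grid`, `nuc_charges`.
#' @export
prepare_docking <- function(lh, nuc, config = bd_config(), spacing = 1.0,
                            fit_charges = FALSE, cutoff = Inf) {
  nuc_grid <- debye_huckel_grid(nuc$solute, spacing = spacing, cutoff = cutoff)
  excl <- build_exclusion_grid(nuc)
  lh_charges <- if (fit_charges) {
    lh_grid_tmp <- debye_huckel_grid(lh$solute, spacing = spacing)
    fit_effective_charges(lh$solute, lh_grid_tmp)
  } else formal_effective_charges(lh$solute)
  out <- list(nuc_grid = nuc_grid, exclusion = excl, lh_charges = lh_charges)
  if (config$energy_mode == "symmetrized") {
    out$lh_grid <- debye_huckel_grid(lh$solute, spacing = spacing)
    out$nuc_charges <- if (fit_charges) {
      fit_effective_charges(nuc$solute, nuc_grid)
    } else formal_effective_charges(nuc$solute)
  }
  out
}

## assemble the parameter list for the C++ trajectory kernel
.traj_params <- function(lh, nuc, grids, config, traj_id, collect_events, rs) {
  lh_sol <- lh$solute
  ctr <- geometric_center(lh_sol)
  lh_body <- sweep(as.matrix(lh_sol$atoms[, c("x", "y", "z")]), 2, ctr)
  site_body <- sweep(grids$lh_charges$positions, 2, ctr)
  nc <- geometric_center(nuc$solute)
  de <- if (is.null(config$D_trans) || is.null(config$D_rot)) {
    .stokes_einstein(lh_sol)
  } else list(D_trans = config$D_trans, D_rot = config$D_rot)
  sym <- config$energy_mode == "symmetrized"
  p <- list(nuc_grid = grids$nuc_grid,
            lh_sites = site_body, lh_site_q = grids$lh_charges$charges,
            lh_atoms = lh_body, exclusion = grids$exclusion,
            nuc_center = nc, dyad_point = nuc$dyad_point,
            nuc_Q = grids$nuc_grid$tail_Q,
            lh_Q = sum(grids$lh_charges$charges),
            kappa = grids$nuc_grid$kappa, pref = grids$nuc_grid$pref,
            symmetrized = sym,
            timestep = config$timestep,
            D_trans = config$D_trans %||% de$D_trans,
            D_rot = config$D_rot %||% de$D_rot,
            start_radius = config$start_radius, stop_radius = config$stop_radius,
            encounter_c2c_max = config$encounter_c2c_max,
            encounter_dyad_max = config$encounter_dyad_max,
            max_steps = config$max_steps,
            max_step_displacement = config$max_step_displacement,
            traj_id = as.integer(traj_id), collect_events = collect_events,
            recorder = .rec_params(rs))
  if (sym) {
    ## LH grid in body-frame coordinates (centered at the geometric center)
    g <- grids$lh_grid
    g$origin <- g$origin - ctr
    g$tail_center <- g$tail_center - ctr
    p$lh_grid <- g
    p$nuc_sites <- grids$nuc_charges$positions
    p$nuc_site_q <- grids$nuc_charges$charges
  }
  p
}

## derived per-trajectory seed, kept below 2^31
.traj_seed <- function(master, traj) {
  as.integer((as.numeric(master) * 48271 + as.numeric(traj) * 16807) %% 2147483399 + 1)
}

#' Run a single BD trajectory
#'
#' Starts the LH at a uniformly random point on the start sphere with a
#' uniformly random orientation, propagates it in the electrostatic field
#' of the nucleosome with excluded-volume rejection, records every
#' encounter-complex time step into the archive, and terminates at the
#' stop sphere (or at the step cap).
#'
#' @param lh an `lh_model`.
#' @param nuc a `nucleosome_model`.
#' @param grids a [prepare_docking()] bundle.
#' @param config a [bd_config].
#' @param seed integer seed for this trajectory.
#' @param recorded an existing `recorded_set` to update; a fresh one by
#'   default.
#' @param collect_events if TRUE (default) return the per-step encounter
#'   event log.
#' @return list with `recorded` (the updated archive), `events`
#'   (data.frame of recorded encounter events when collected),
#'   `exit_reason`, `steps`, `rejections`.
#' @export
run_trajectory <- function(lh, nuc, grids, config, seed = config$rng_seed,
                           recorded = NULL, collect_events = TRUE) {
  validate_bd_config(config)
  if (is.null(recorded)) recorded <- new_recorded_set(lh, config)
  params <- .traj_params(lh, nuc, grids, config, traj_id = 1L,
                         collect_events = collect_events, rs = recorded)
  set.seed(seed)
  st <- bd_traj_cpp(.state_of(recorded), params)
  out <- list(recorded = .set_state(recorded, st),
              exit_reason = st$exit_reason, steps = st$steps,
              rejections = st$rejections, n_events = st$events)
  if (collect_events) {
    em <- st$event_log
    out$events <- data.frame(qw = em[, 1], qx = em[, 2], qy = em[, 3],
                             qz = em[, 4], tx = em[, 5], ty = em[, 6],
                             tz = em[, 7], energy = em[, 8], step = em[, 9])
  }
  out
}

#' Run the full docking simulation
#'
#' Generates `config$n_trajectories` independent trajectories (seeds
#' derived deterministically from the master seed) and aggregates all
#' encounter events through the recorded-set rules in trajectory order.
#'
#' @inheritParams run_trajectory
#' @param progress print a progress line every 100 trajectories.
#' @return the final `recorded_set`, with a `stats` attribute
#'   (data.frame of per-trajectory steps, rejections, events, exit reason).
#' @export
run_docking <- function(lh, nuc, grids, config, progress = FALSE) {
  validate_bd_config(config)
  rs <- new_recorded_set(lh, config)
  n <- config$n_trajectories
  stats_df <- data.frame(traj = integer(n), steps = numeric(n),
                         rejections = numeric(n), events = numeric(n),
                         exit_reason = character(n), stringsAsFactors = FALSE)
  if (n > 0) {
    params <- .traj_params(lh, nuc, grids, config, traj_id = 1L,
                           collect_events = FALSE, rs = rs)
    for (i in seq_len(n)) {
      params$traj_id <- as.integer(i)
      set.seed(.traj_seed(config$rng_seed, i))
      st <- bd_traj_cpp(.state_of(rs), params)
      rs <- .set_state(rs, st)
      stats_df[i, ] <- list(i, st$steps, st$rejections, st$events, st$exit_reason)
      if (progress && i %% 100 == 0) {
        message(sprintf("trajectory %d/%d: %d records, %.0f encounters seen",
                        i, n, rs$n, rs$seen))
      }
    }
  }
  attr(rs, "stats") <- stats_df
  rs
}
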