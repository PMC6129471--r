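## Screened electrostatics: potential grids, effective-charge fitting,
## interaction energies/forces, and the excluded-volume grid.
##
## Units: lengths in Angstrom, charges in e, energies in kT, potentials in
## kT/e. The Coulomb constant e^2/(4 pi eps0 kB) = 1.67087e5 K*Angstrom, so
## in kT*Angstrom/e^2 units it is 1.67087e5 / T.

.coulomb_kT_A <- function(temperature) 1.67087e5 / temperature

#' Inverse Debye screening length
#'
#' For a 1:1 electrolyte of given ionic strength in a solvent of relative
#' dielectric constant `eps_solvent` at temperature `temperature`.
#'
#' @param ionic_strength mol/L.
#' @param temperature Kelvin.
#' @param eps_solvent relative dielectric constant of the solvent.
#' @return kappa in 1/Angstrom.
#' @export
debye_kappa <- function(ionic_strength = 0.100, temperature = 298.15,
                        eps_solvent = 78.54) {
  lb <- .coulomb_kT_A(temperature) / eps_solvent  # Bjerrum length, Angstrom
  sqrt(8 * pi * lb * 6.02214e-4 * ionic_strength)
}

#' Construct a potential grid object
#'
#' Regular scalar grid of electrostatic potential in kT/e. `values` is a
#' 3D array indexed `[ix, iy, iz]`; grid node (i, j, k) sits at
#' `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param origin numeric(3), Angstrom.
#' @param spacing grid spacing, Angstrom (> 0).
#' @param values 3D numeric array of potentials, kT/e.
#' @param temperature,ionic_strength,eps_solvent,eps_solute model metadata.
#' @param tail_center,tail_Q center (Angstrom) and net charge (e) of the
#'   source solute, used for the analytic screened-monopole continuation
#'   outside the grid.
#' @return object of class `potential_grid`.
#' @export
potential_grid <- function(origin, spacing, values,
                           temperature = 298.15, ionic_strength = 0.100,
                           eps_solvent = 78.54, eps_solute = 2,
                           tail_center = c(0, 0, 0), tail_Q = 0) {
  stopifnot(spacing > 0, length(dim(values)) == 3)
  if (!all(is.finite(values))) stop("non-finite grid values")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dim(values)), values = values,
                 temperature = temperature, ionic_strength = ionic_strength,
                 eps_solvent = eps_solvent, eps_solute = eps_solute,
                 tail_center = as.numeric(tail_center), tail_Q = tail_Q,
                 kappa = debye_kappa(ionic_strength, temperature, eps_solvent),
                 pref = .coulomb_kT_A(temperature) / eps_solvent),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("<potential_grid> %dx%dx%d @ %.2f A, origin (%.1f, %.1f, %.1f); I = %g M, T = %g K\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3],
              x$ionic_strength, x$temperature))
  invisible(x)
}

#' Debye-Hueckel potential grid of a solute
#'
#' Uniform-dielectric screened-Coulomb superposition over all charged
#' atoms:
#' \deqn{\phi(r) = \frac{C}{\epsilon_s}\sum_i
#'   \frac{q_i\, e^{-\kappa(|r-r_i|-a_i)}}{(1+\kappa a_i)\,|r-r_i|}}
#' with C the Coulomb constant in kT Angstrom/e^2. Grid points falling
#' inside an atom are clamped at the atom radius. Grids computed by an
#' external Poisson-Boltzmann solver can be imported with [read_dx_grid()]
#' instead; the interface downstream is identical.
#'
#' @param solute a [solute] with charges populated.
#' @param spacing grid spacing, Angstrom (default 1.0).
#' @param padding margin beyond the solute extent; default 3 Debye lengths.
#' @param box optional list(origin, dims) overriding the automatic box.
#' @param temperature,ionic_strength,eps_solvent,eps_solute model
#'   parameters (defaults 298.15 K, 0.100 M, 78.54, 2).
#' @param cutoff per-atom distance beyond which an atom's contribution is
#'   dropped (Angstrom); `Inf` (default) disables the cutoff.
#' @return a [potential_grid].
#' @export
debye_huckel_grid <- function(solute, spacing = 1.0, padding = NULL, box = NULL,
                              temperature = 298.15, ionic_strength = 0.100,
                              eps_solvent = 78.54, eps_solute = 2,
                              cutoff = Inf) {
  kappa <- debye_kappa(ionic_strength, temperature, eps_solvent)
  pref <- .coulomb_kT_A(temperature) / eps_solvent
  xyz <- atoms_at_pose(solute, solute$frame)
  if (is.null(box)) {
    if (is.null(padding)) padding <- 3 / max(kappa, 1e-6)
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  } else {
    origin <- as.numeric(box$origin)
    dims <- as.integer(box$dims)
  }
  res <- dh_grid_cpp(xyz, solute$atoms$charge, solute$atoms$radius,
                     origin, spacing, dims, kappa, pref, cutoff)
  if (res$n_clamped > 0) {
    message(sprintf("debye_huckel_grid: clamped %d grid point(s) inside atom radii",
                    res$n_clamped))
  }
  vals <- array(res$values, dim = dims)
  potential_grid(origin, spacing, vals,
                 temperature = temperature, ionic_strength = ionic_strength,
                 eps_solvent = eps_solvent, eps_solute = eps_solute,
                 tail_center = colMeans(xyz), tail_Q = sum(solute$atoms$charge))
}

#' Read an OpenDX scalar grid
#'
#' Accepts the APBS-style OpenDX dialect (`object 1 class gridpositions`,
#' three `delta` rows, `object 3 class array ... data follows`). Data
#' values are stored z-fastest in the file and are permuted to this
#' package's x-fastest layout.
#'
#' @param path file path.
#' @param ... metadata passed to [potential_grid()] (temperature etc.).
#' @return a [potential_grid].
#' @export
read_dx_grid <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(gp) == 0) stop("not an OpenDX grid: missing gridpositions object")
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", gp[1])), "\\s+")[[1]])
  if (length(counts) != 3) stop("malformed gridpositions counts")
  org_line <- grep("^\\s*origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("origin", "", org_line)), "\\s+")[[1]])
  deltas <- grep("^\\s*delta", lines, value = TRUE)
  if (length(deltas) < 3) stop("malformed OpenDX: need three delta rows")
  dmat <- t(vapply(deltas[1:3], function(s) {
    as.numeric(strsplit(trimws(sub("delta", "", s)), "\\s+")[[1]])
  }, numeric(3)))
  if (any(abs(dmat - diag(diag(dmat))) > 1e-9)) {
    stop("only axis-aligned OpenDX grids are supported")
  }
  sp <- diag(dmat)
  if (max(abs(sp - sp[1])) > 1e-9) stop("anisotropic grid spacing not supported")
  di <- grep("class array", lines)
  if (length(di) == 0) stop("malformed OpenDX: missing data array object")
  n_items <- prod(counts)
  data_lines <- lines[(di[1] + 1):length(lines)]
  data_lines <- data_lines[!grepl("^(attribute|object|component|end)", trimws(data_lines))]
  vals <- as.numeric(unlist(strsplit(trimws(paste(data_lines, collapse = " ")), "\\s+")))
  if (length(vals) < n_items) {
    stop(sprintf("OpenDX data has %d values, expected %d", length(vals), n_items))
  }
  vals <- vals[seq_len(n_items)]
  ## file order is z-fastest; our layout is x-fastest
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  potential_grid(origin, sp[1], arr, ...)
}

#' Write a potential grid as an OpenDX file
#'
#' APBS-compatible header subset; values written z-fastest, three per
#' line, `%.6e`. [read_dx_grid()] round-trips the file at that precision.
#'
#' @param grid a [potential_grid].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dx_grid <- function(grid, path) {
  d <- grid$dims
  hdr <- c(
    "# OpenDX scalar grid (electrostatic potential, kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(d)))
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z-fastest on disk
  n <- length(vals)
  pad <- (3 - n %% 3) %% 3
  vm <- matrix(c(sprintf("%.6e", vals), rep("", pad)), nrow = 3)
  body <- apply(vm, 2, function(r) trimws(paste(r, collapse = " ")))
  ftr <- c("attribute \"dep\" string \"positions\"",
           "object \"regular positions regular connections\" class field",
           "component \"positions\" value 1",
           "component \"connections\" value 2",
           "component \"data\" value 3")
  writeLines(c(hdr, body, ftr), path)
  invisible(path)
}

## internal: run an expression with a private RNG seed, restoring the
## caller's stream afterwards
.with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## internal: default effective-charge site table of a solute.
## DNA mode (any P atoms): one site per P atom. Protein mode: side-chain
## centroids of charged residues plus the chain termini.
.default_sites <- function(solute) {
  a <- solute$atoms
  p_rows <- which(a$atom_name == "P")
  if (length(p_rows) > 0) {
    return(data.frame(x = a$x[p_rows], y = a$y[p_rows], z = a$z[p_rows],
                      label = sprintf("P:%d", a$residue_index[p_rows])))
  }
  charged <- c("ASP", "GLU", "LYS", "ARG")
  backbone <- c("N", "CA", "C", "O", "H", "HA", "OXT")
  rows_list <- list()
  for (ri in unique(a$residue_index[a$residue_name %in% charged])) {
    rr <- which(a$residue_index == ri)
    sc <- rr[!(a$atom_name[rr] %in% backbone)]
    if (length(sc) == 0) sc <- rr
    rows_list[[length(rows_list) + 1]] <- data.frame(
      x = mean(a$x[sc]), y = mean(a$y[sc]), z = mean(a$z[sc]),
      label = sprintf("%s%d", a$residue_name[rr[1]], ri))
  }
  ## chain termini
  for (ch in unique(a$chain_id)) {
    rr <- which(a$chain_id == ch)
    for (ri in c(a$residue_index[rr[1]], a$residue_index[rr[length(rr)]])) {
      sub <- rr[a$residue_index[rr] == ri]
      lab <- sprintf("ter%d", ri)
      rows_list[[length(rows_list) + 1]] <- data.frame(
        x = mean(a$x[sub]), y = mean(a$y[sub]), z = mean(a$z[sub]), label = lab)
    }
  }
  out <- do.call(rbind, rows_list)
  out[!duplicated(round(as.matrix(out[, 1:3]), 3)), , drop = FALSE]
}

#' Fit effective charges to reproduce a potential grid
#'
#' Point charges at a reduced site set (charged-residue centroids and
#' termini for proteins, P atoms for DNA) are fitted by least squares so
#' that their screened-Coulomb potential reproduces the grid over a shell
#' of sample points outside the solute surface. The fitted set is what the
#' docking engine evaluates at every time step.
#'
#' @param solute the source [solute].
#' @param grid its [potential_grid].
#' @param shell numeric(2): inner and outer distance of the sampling shell
#'   from the atom-radius surface, Angstrom (default `c(3, 6)`).
#' @param n_samples number of shell sample points (default 2000; drawn
#'   with a fixed internal seed so the fit is deterministic).
#' @param sites optional data.frame(x, y, z, label) overriding the default
#'   site set.
#' @return object of class `effective_charges` with fields `sites`,
#'   `charges`, `residual` (relative RMS), `center`, `net_charge`.
#' @export
fit_effective_charges <- function(solute, grid, shell = c(3, 6),
                                  n_samples = 2000, sites = NULL) {
  if (is.null(sites)) sites <- .default_sites(solute)
  if (is.null(sites) || nrow(sites) == 0) stop("empty effective-charge site list")
  xyz <- atoms_at_pose(solute, solute$frame)
  rad <- solute$atoms$radius
  lo <- apply(xyz, 2, min) - max(rad) - shell[2]
  hi <- apply(xyz, 2, max) + max(rad) + shell[2]
  ## rejection-sample the shell with a private fixed seed
  pts <- .with_private_seed(20011L, {
    acc <- matrix(numeric(0), ncol = 3)
    tries <- 0
    while (nrow(acc) < n_samples && tries < 200) {
      cand <- cbind(stats::runif(4 * n_samples, lo[1], hi[1]),
                    stats::runif(4 * n_samples, lo[2], hi[2]),
                    stats::runif(4 * n_samples, lo[3], hi[3]))
      ## distance from each candidate to the nearest atom surface
      dmin <- rep(Inf, nrow(cand))
      for (i in seq_len(nrow(xyz))) {
        di <- sqrt((cand[, 1] - xyz[i, 1])^2 + (cand[, 2] - xyz[i, 2])^2 +
                   (cand[, 3] - xyz[i, 3])^2) - rad[i]
        dmin <- pmin(dmin, di)
      }
      acc <- rbind(acc, cand[dmin >= shell[1] & dmin <= shell[2], , drop = FALSE])
      tries <- tries + 1
    }
    acc
  })
  if (nrow(pts) == 0) stop("sampling shell contains no points")
  pts <- pts[seq_len(min(nrow(pts), n_samples)), , drop = FALSE]
  ## target potentials from the grid (inside-grid points only, by construction)
  phi <- grid_values_at(grid, pts)
  ## kernel matrix: screened Coulomb of a bare point charge at each site
  sp <- as.matrix(sites[, c("x", "y", "z")])
  K <- matrix(0, nrow(pts), nrow(sp))
  for (s in seq_len(nrow(sp))) {
    r <- sqrt((pts[, 1] - sp[s, 1])^2 + (pts[, 2] - sp[s, 2])^2 +
              (pts[, 3] - sp[s, 3])^2)
    r <- pmax(r, 1e-3)
    K[, s] <- grid$pref * exp(-grid$kappa * r) / r
  }
  fit <- tryCatch(qr.solve(crossprod(K), crossprod(K, phi)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular normal equations; using ridge-regularized solve")
    A <- crossprod(K)
    fit <- solve(A + diag(1e-8 * mean(diag(A)), ncol(K)), crossprod(K, phi))
  }
  q <- as.numeric(fit)
  resid <- sqrt(mean((K %*% q - phi)^2)) / max(sqrt(mean(phi^2)), 1e-12)
  structure(list(sites = sites, positions = sp, charges = q, residual = resid,
                 center = geometric_center(solute),
                 net_charge = sum(q),
                 kappa = grid$kappa, pref = grid$pref),
            class = "effective_charges")
}

#' Exact point charges of a solute as an effective-charge set
#'
#' Bypasses fitting: uses every atom with nonzero charge as a site with
#' its formal partial charge. Useful for bead models whose charges are
#' already point charges.
#'
#' @param solute a [solute].
#' @param temperature,ionic_strength,eps_solvent screening parameters for
#'   the kernel metadata.
#' @return an `effective_charges` object (residual 0 by construction).
#' @export
formal_effective_charges <- function(solute, temperature = 298.15,
                                     ionic_strength = 0.100, eps_solvent = 78.54) {
  a <- solute$atoms
  rows <- which(a$charge != 0)
  if (length(rows) == 0) stop("solute has no charged atoms")
  sp <- cbind(a$x[rows], a$y[rows], a$z[rows])
  colnames(sp) <- c("x", "y", "z")
  structure(list(sites = data.frame(sp, label = sprintf("%s%d", a$residue_name[rows],
                                                        a$residue_index[rows])),
                 positions = sp, charges = a$charge[rows], residual = 0,
                 center = geometric_center(solute), net_charge = sum(a$charge[rows]),
                 kappa = debye_kappa(ionic_strength, temperature, eps_solvent),
                 pref = .coulomb_kT_A(temperature) / eps_solvent),
            class = "effective_charges")
}

#' @export
print.effective_charges <- function(x, ...) {
  cat(sprintf("<effective_charges> %d sites, net %.3f e, relative RMS residual %.3g\n",
              length(x$charges), x$net_charge, x$residual))
  invisible(x)
}

#' Potential values at arbitrary points (trilinear interpolation)
#'
#' Out-of-grid points use the grid's analytic screened-monopole tail.
#'
#' @param grid a [potential_grid].
#' @param points n x 3 matrix, Angstrom.
#' @return numeric(n) potentials, kT/e.
#' @export
grid_values_at <- function(grid, points) {
  points <- rbind(points)
  vapply(seq_len(nrow(points)), function(i) {
    r <- grid_field_cpp(grid, points[i, , drop = FALSE], 1.0,
                        grid$tail_center, grid$tail_Q, grid$kappa, grid$pref,
                        c(0, 0, 0))
    r$energy
  }, numeric(1))
}

## internal: world-frame site positions of an effective-charge set under a
## pose (rotation about the source solute's geometric center)
.sites_at_pose <- function(charges, pose = NULL) {
  if (is.null(pose)) return(charges$positions)
  sweep(rotate_rows(sweep(charges$positions, 2, charges$center), pose$q), 2,
        pose$t, `+`)
}

#' Electrostatic interaction energy of a charge set in a potential grid
#'
#' One-sided energy: the effective charges of the mobile solute B, placed
#' at `pose`, are evaluated by trilinear interpolation in the grid of
#' solute A (analytic monopole tail outside the grid). With `grid_B` and
#' `charges_A` supplied the symmetrized energy (the average of the two
#' one-sided evaluations) is returned, which is symmetric under exchange
#' of the two solutes by construction.
#'
#' @param grid_A [potential_grid] of the fixed solute A (world frame).
#' @param charges_B `effective_charges` of the mobile solute B.
#' @param pose [pose] of solute B (default: reference placement).
#' @param grid_B optional [potential_grid] of solute B in B's reference
#'   frame; enables the symmetrized variant.
#' @param charges_A optional `effective_charges` of solute A (world frame).
#' @return energy in kT.
#' @export
interaction_energy <- function(grid_A, charges_B, pose = NULL,
                               grid_B = NULL, charges_A = NULL) {
  if (is.null(pose)) pose <- pose(c(1, 0, 0, 0), charges_B$center)
  sites <- .sites_at_pose(charges_B, pose)
  e_ab <- grid_field_cpp(grid_A, sites, charges_B$charges,
                         grid_A$tail_center, grid_A$tail_Q,
                         grid_A$kappa, grid_A$pref, pose$t)$energy
  if (is.null(grid_B)) return(e_ab)
  if (is.null(charges_A)) stop("symmetrized energy needs charges_A")
  ## body-frame coordinates of A's sites: y = R^T (r - t) + center_B
  R <- quat_to_matrix(pose$q)
  yb <- sweep(sweep(charges_A$positions, 2, pose$t) %*% R, 2, charges_B$center, `+`)
  e_ba <- grid_field_cpp(grid_B, yb, charges_A$charges,
                         grid_B$tail_center, grid_B$tail_Q,
                         grid_B$kappa, grid_B$pref, charges_B$center)$energy
  (e_ab + e_ba) / 2
}

#' Force and torque on the mobile solute
#'
#' Analytic gradient of the trilinear interpolant (one-sided) or the
#' average of both one-sided wrenches (symmetrized). Torque is taken about
#' the mobile solute's geometric center (`pose$t`), in kT (dimensionless
#' angle).
#'
#' @inheritParams interaction_energy
#' @return list(force = numeric(3) kT/Angstrom, torque = numeric(3) kT).
#' @export
force_and_torque <- function(grid_A, charges_B, pose = NULL,
                             grid_B = NULL, charges_A = NULL) {
  if (is.null(pose)) pose <- pose(c(1, 0, 0, 0), charges_B$center)
  sites <- .sites_at_pose(charges_B, pose)
  ab <- grid_field_cpp(grid_A, sites, charges_B$charges,
                       grid_A$tail_center, grid_A$tail_Q,
                       grid_A$kappa, grid_A$pref, pose$t)
  if (is.null(grid_B)) {
    return(list(force = ab$force, torque = ab$torque))
  }
  if (is.null(charges_A)) stop("symmetrized wrench needs charges_A")
  R <- quat_to_matrix(pose$q)
  yb <- sweep(sweep(charges_A$positions, 2, pose$t) %*% R, 2, charges_B$center, `+`)
  ba <- grid_field_cpp(grid_B, yb, charges_A$charges,
                       grid_B$tail_center, grid_B$tail_Q,
                       grid_B$kappa, grid_B$pref, charges_B$center)
  ## reaction of the B-grid term on the mobile solute, mapped to world frame
  f_ba <- -as.numeric(R %*% ba$force)
  t_ba <- -as.numeric(R %*% ba$torque)
  list(force = (ab$force + f_ba) / 2, torque = (ab$torque + t_ba) / 2)
}

#' Build the excluded-volume grid of a nucleosome
#'
#' Boolean occupancy grid: a cell is occupied when its center lies within
#' `atom radius + margin` of any nucleosome atom. A pose overlaps when any
#' LH atom center falls in an occupied cell.
#'
#' @param nuc a `nucleosome_model` (or bare [solute]).
#' @param margin probe margin, Angstrom (default 0.5, the excluded-volume
#'   criterion of the docking protocol).
#' @param spacing grid spacing, Angstrom.
#' @return object of class `exclusion_grid`.
#' @export
build_exclusion_grid <- function(nuc, margin = 0.5, spacing = 1.0) {
  sol <- if (inherits(nuc, "nucleosome_model")) nuc$solute else nuc
  xyz <- atoms_at_pose(sol, sol$frame)
  rad <- sol$atoms$radius
  lo <- apply(xyz, 2, min) - max(rad) - margin - spacing
  hi <- apply(xyz, 2, max) + max(rad) + margin + spacing
  ## symmetric box about the y = 0 and z = 0 planes: a model with exact
  ## twofold symmetry about the x axis then gets exactly symmetric
  ## occupancy (cell centers map onto cell centers under the twofold)
  hi[2:3] <- pmax(abs(lo[2:3]), abs(hi[2:3]))
  lo[2:3] <- -hi[2:3]
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  lo[2:3] <- -(dims[2:3] - 1L) * spacing / 2
  occ <- array(0L, dim = dims)
  for (i in seq_len(nrow(xyz))) {
    reach <- rad[i] + margin
    idx_lo <- pmax(floor((xyz[i, ] - reach - lo) / spacing) + 1, 1)
    idx_hi <- pmin(ceiling((xyz[i, ] + reach - lo) / spacing) + 1, dims)
    ii <- seq(idx_lo[1], idx_hi[1]); jj <- seq(idx_lo[2], idx_hi[2])
    kk <- seq(idx_lo[3], idx_hi[3])
    gx <- lo[1] + (ii - 1) * spacing - xyz[i, 1]
    gy <- lo[2] + (jj - 1) * spacing - xyz[i, 2]
    gz <- lo[3] + (kk - 1) * spacing - xyz[i, 3]
    d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
    occ[ii, jj, kk] <- occ[ii, jj, kk] | (d2 <= reach^2)
  }
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 occupancy = as.integer(occ), margin = margin),
            class = "exclusion_grid")
}

#' Test a pose for excluded-volume overlap
#'
#' @param excl an [build_exclusion_grid()] grid.
#' @param lh an `lh_model` or [solute].
#' @param pose a [pose] (default: reference placement).
#' @return logical: TRUE when any LH atom center lies in an occupied cell.
#' @export
check_overlap <- function(excl, lh, pose = NULL) {
  sol <- if (inherits(lh, "lh_model")) lh$solute else lh
  xyz <- atoms_at_pose(sol, pose)
  idx <- floor(sweep(xyz, 2, excl$origin) / excl$spacing + 0.5)
  inside <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
    idx[, 1] < excl$dims[1] & idx[, 2] < excl$dims[2] & idx[, 3] < excl$dims[3]
  if (!any(inside)) return(FALSE)
  idx <- idx[inside, , drop = FALSE]
  lin <- idx[, 1] + excl$dims[1] * (idx[, 2] + excl$dims[2] * idx[, 3]) + 1
  any(excl$occupancy[lin] == 1L)
}
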