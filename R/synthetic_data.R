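## Synthetic idealized structures: a nucleosome-shaped polyanion and a
## small cationic winged-helix-like LH globular domain, built so that the
## docking, clustering, classification and H-bond stages all run without
## any external structure file.
##
## Nucleosome geometry: standard values (left-handed superhelix of radius
## 41.9 A and pitch 25.9 A, ~1.65 turns for 147 bp, 10.4 bp per helical
## turn, phosphates on a 9 A double helix with a 139 degree strand phase
## offset). In the closed reference conformation the straight L-DNA arms
## are aimed so that they converge toward a stem near the dyad axis, as in
## closed chromatosome conformations; the opening angles rotate each arm
## outward from that reference.

#' Synthetic fixture specification
#'
#' @param core_bp base pairs of nucleosomal (wrapped) DNA (default 147).
#' @param l_dna_bp linker DNA base pairs per arm (default 18, which gives
#'   each arm the two major-groove sites of the configuration notation).
#' @param opening_angle_1,opening_angle_2 outward splay of the L-DNA1 /
#'   L-DNA2 arms relative to the closed reference, degrees in [0, 90].
#' @param lh_size number of LH residues (default 80).
#' @param lh_net_charge net formal charge of the LH, e (default +11).
#' @param seed integer seed for any stochastic fixture element.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(core_bp = 147, l_dna_bp = 18,
                         opening_angle_1 = 0, opening_angle_2 = 0,
                         lh_size = 80, lh_net_charge = 11, seed = 1) {
  if (opening_angle_1 < 0 || opening_angle_1 > 90 ||
      opening_angle_2 < 0 || opening_angle_2 > 90) {
    stop("opening angles must lie in [0, 90] degrees")
  }
  if (core_bp < 21 || core_bp %% 2 == 0) {
    stop("core_bp must be odd (a central dyad base pair) and >= 21")
  }
  if (l_dna_bp < 0) stop("l_dna_bp must be non-negative")
  structure(list(core_bp = core_bp, l_dna_bp = l_dna_bp,
                 opening_angle_1 = opening_angle_1,
                 opening_angle_2 = opening_angle_2,
                 lh_size = lh_size, lh_net_charge = lh_net_charge,
                 seed = seed),
            class = "fixture_spec")
}

## fixed geometry constants of the idealized nucleosome
.nuc_geom <- list(sh_radius = 41.9, sh_pitch = 25.9, sh_turns_147 = 1.65,
                  helix_radius = 9.0, phase_offset = 139 * pi / 180 / 2,
                  bp_per_turn = 10.4, arm_rise = 3.4,
                  p_charge = -1, p_radius = 2.1,
                  core_radius = 28, core_spacing = 5.5, core_atom_radius = 3.2)

## superhelical path and local frame at (possibly fractional) bp index i
.sh_frame <- function(i, g, core_bp) {
  dtheta <- g$sh_turns_147 * 2 * pi / 146 # radians per bp, 147 bp reference
  th <- i * dtheta
  pprime <- g$sh_pitch / (2 * pi)
  path <- c(g$sh_radius * cos(th), g$sh_radius * sin(th), -pprime * th)
  tang <- c(-g$sh_radius * sin(th), g$sh_radius * cos(th), -pprime)
  tang <- tang / sqrt(sum(tang^2))
  nr <- c(cos(th), sin(th), 0)
  b2 <- c(tang[2] * nr[3] - tang[3] * nr[2],
          tang[3] * nr[1] - tang[1] * nr[3],
          tang[1] * nr[2] - tang[2] * nr[1])
  list(path = path, tangent = tang, normal = nr, binormal = b2, theta = th)
}

## the 2-fold (dyad) symmetry operation of the closed fixture
.dyad_twofold <- function(p) c(p[1], -p[2], -p[3])

#' Build the idealized nucleosome fixture
#'
#' Two phosphate strands (one P pseudo-atom per strand per bp, charge -1 e)
#' wound as a double helix along a left-handed superhelical path, straight
#' L-DNA arms splayed outward by the opening angles, and a neutral core
#' sphere of packed pseudo-atoms for excluded volume. Fully annotated
#' (base-pair table, dyad geometry, arm labels); with equal opening angles
#' the model is exactly twofold-symmetric about the dyad axis.
#'
#' Arm sign convention: L-DNA1 extends from the negative base-pair end and
#' L-DNA2 from the positive end.
#'
#' @param spec a [fixture_spec()].
#' @return a `nucleosome_model`.
#' @export
build_ideal_nucleosome <- function(spec = fixture_spec()) {
  g <- .nuc_geom
  half <- (spec$core_bp - 1) / 2
  omega <- 2 * pi / g$bp_per_turn
  phi <- g$phase_offset

  ## --- positive-side construction (bp 0 .. half, then arm 2) ---
  p_of <- function(i, strand_sign) {
    fr <- .sh_frame(i, g, spec$core_bp)
    psi <- omega * i + strand_sign * phi
    fr$path + g$helix_radius * (cos(psi) * fr$normal + sin(psi) * fr$binormal)
  }
  core_bp_idx <- 0:half
  core_p1_pos <- t(vapply(core_bp_idx, p_of, numeric(3), strand_sign = +1))
  core_p2_pos <- t(vapply(core_bp_idx, p_of, numeric(3), strand_sign = -1))

  ## closed-reference arm direction: from the attachment toward a stem
  ## point just outside the dyad, so the arm sweeps past the dyad region
  end_fr <- .sh_frame(half, g, spec$core_bp)
  dyad_guess <- c(g$sh_radius + g$helix_radius * cos(phi), 0, 0)
  stem_target <- dyad_guess + c(12, -17, -11)
  d0 <- stem_target - end_fr$path
  d0 <- d0 / sqrt(sum(d0^2))

  arm_points <- function(opening_deg) {
    ## rotate the closed direction outward (away from the dyad axis line)
    d <- d0
    if (opening_deg != 0) {
      w <- c(0, end_fr$path[2], end_fr$path[3])   # away from the x (dyad) axis
      w <- w / sqrt(sum(w^2))
      wp <- w - sum(w * d) * d
      wp <- wp / sqrt(sum(wp^2))
      a <- opening_deg * pi / 180
      d <- cos(a) * d + sin(a) * wp
    }
    ## arm frame transported from the superhelix end
    n1 <- end_fr$normal - sum(end_fr$normal * d) * d
    n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(d[2] * n1[3] - d[3] * n1[2],
            d[3] * n1[1] - d[1] * n1[3],
            d[1] * n1[2] - d[2] * n1[1])
    lapply(seq_len(spec$l_dna_bp), function(j) {
      i <- half + j
      base <- end_fr$path + j * g$arm_rise * d
      psi1 <- omega * i + phi
      psi2 <- omega * i - phi
      list(bp = i,
           p1 = base + g$helix_radius * (cos(psi1) * n1 + sin(psi1) * n2),
           p2 = base + g$helix_radius * (cos(psi2) * n1 + sin(psi2) * n2))
    })
  }
  arm2 <- arm_points(spec$opening_angle_2)           # positive side, L-DNA2
  arm1_mirror <- arm_points(spec$opening_angle_1)    # built on +side, mirrored below

  ## --- assemble both strands; the negative side is the exact twofold
  ##     image of the positive side (strands swap under the dyad 2-fold) ---
  n_total <- spec$core_bp + 2 * spec$l_dna_bp
  bp_idx <- integer(0); s1 <- list(); s2 <- list()
  add_bp <- function(i, p1, p2) {
    bp_idx[[length(bp_idx) + 1]] <<- i
    s1[[length(s1) + 1]] <<- p1
    s2[[length(s2) + 1]] <<- p2
  }
  for (k in seq_along(core_bp_idx)) {
    i <- core_bp_idx[k]
    add_bp(i, core_p1_pos[k, ], core_p2_pos[k, ])
    if (i > 0) add_bp(-i, .dyad_twofold(core_p2_pos[k, ]),
                      .dyad_twofold(core_p1_pos[k, ]))
  }
  for (a in arm2) add_bp(a$bp, a$p1, a$p2)
  for (a in arm1_mirror) add_bp(-a$bp, .dyad_twofold(a$p2), .dyad_twofold(a$p1))

  ord <- order(unlist(bp_idx))
  bp_idx <- unlist(bp_idx)[ord]; s1 <- s1[ord]; s2 <- s2[ord]
  stopifnot(length(bp_idx) == n_total)

  seg <- ifelse(abs(bp_idx) <= half, "N-DNA",
                ifelse(bp_idx < 0, "L-DNA1", "L-DNA2"))

  ## atom table: strand I then strand J, one P per bp, then the core
  mk_strand <- function(positions, chain, res_offset, id_offset) {
    pos <- do.call(rbind, positions)
    data.frame(atom_id = id_offset + seq_len(nrow(pos)), atom_name = "P",
               residue_name = "DNA", residue_index = res_offset + seq_len(nrow(pos)),
               chain_id = chain, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               charge = g$p_charge, radius = g$p_radius,
               stringsAsFactors = FALSE)
  }
  a1 <- mk_strand(s1, "I", 0, 0)
  a2 <- mk_strand(s2, "J", n_total, n_total)

  ## neutral core: pseudo-atoms on a cubic lattice inside a sphere,
  ## trimmed to stay clear of the wrapped DNA
  cs <- g$core_spacing
  grid1 <- seq(-g$core_radius, g$core_radius, by = cs)
  lat <- as.matrix(expand.grid(x = grid1, y = grid1, z = grid1))
  lat <- lat[rowSums(lat^2) <= g$core_radius^2, , drop = FALSE]
  nc <- nrow(lat)
  a3 <- data.frame(atom_id = 2 * n_total + seq_len(nc), atom_name = "C",
                   residue_name = "COR", residue_index = 2 * n_total + seq_len(nc),
                   chain_id = "C", x = lat[, 1], y = lat[, 2], z = lat[, 3],
                   charge = 0, radius = g$core_atom_radius,
                   stringsAsFactors = FALSE)
  sol <- solute(rbind(a1, a2, a3), label = sprintf(
    "ideal nucleosome %d+2x%d bp (open %g/%g deg)", spec$core_bp, spec$l_dna_bp,
    spec$opening_angle_1, spec$opening_angle_2))

  ## strand atom tables are already in bp order (rows were sorted above)
  bp_map <- data.frame(bp = bp_idx, segment = seg,
                       p1 = a1$atom_id, p2 = a2$atom_id,
                       stringsAsFactors = FALSE)
  annotate_nucleosome(sol, bp_map, dyad_bp = 0, core_atom_ids = a3$atom_id)
}

## toy LH bead layout helpers -------------------------------------------

.seg_beads <- function(from, to, n) {
  t(vapply(seq_len(n), function(i) {
    f <- if (n == 1) 0 else (i - 1) / (n - 1)
    from + f * (to - from)
  }, numeric(3)))
}

#' Build the toy winged-helix linker-histone fixture
#'
#' One bead per residue (radius 3 A), arranged as three idealized helices,
#' an l1 loop and a beta-hairpin wing, with the DNA-binding face toward
#' -x in the body frame. Residues are numbered 30-109 so that the named
#' mutable sites carry their conventional identities: the beta1-wing
#' quartet V80/K82/K85/V87, the alpha3 quartet K102/I104/K107/K109, and
#' the PTM sites K58 (alpha1), S66/S67/K72 (alpha2). Charge sites (+1 e
#' lysines/arginines, -1 e glutamates, pseudo-atom names NZ/NH1/OE1) are
#' placed so the net charge equals `lh_net_charge` (+11 by default: 13
#' positive and 2 negative sites).
#'
#' @param spec a [fixture_spec()].
#' @return an `lh_model` with elements and alpha3 termini annotated.
#' @export
build_toy_lh <- function(spec = fixture_spec()) {
  if (spec$lh_size != 80) {
    stop("the toy LH layout is defined for lh_size = 80")
  }
  coords <- rbind(
    .seg_beads(c(8, -6, 5),   c(8, 6, 5), 10),     # 30-39 filler slab
    .seg_beads(c(10, 6, 1),   c(10, -6, 1), 10),   # 40-49 filler slab
    .seg_beads(c(6, -8, 9),   c(6, 9, 9), 11),     # 50-60 alpha1
    matrix(c(5, 11, 5), 1),                        # 61 linker
    .seg_beads(c(6, 12, 1),   c(6, -10, 1), 14),   # 62-75 alpha2
    rbind(c(0, -9, -2), c(-1, -10.5, -3),
          c(-3, -11.5, -4), c(-5, -13, -5)),       # 76-79 l1 loop
    rbind(.seg_beads(c(-6.5, -2, -4), c(-14, -1, -3), 5), # 80-84 beta1 out
          c(-16, 0, -2),                                  # 85 turn
          .seg_beads(c(-14, 1, -1), c(-6.5, 2, -2), 5)),  # 86-90 beta1 back
    rbind(c(3, 4, 3), c(2, 6, 6),
          c(2, 8, 8), c(1, 10, 10)),               # 91-94 linker
    .seg_beads(c(-4, 11.5, 11), c(-4, 11.5, -10), 15)   # 95-109 alpha3
  )
  stopifnot(nrow(coords) == 80)
  res_idx <- 30:109
  res_name <- rep("ALA", 80)
  atom_name <- rep("CA", 80)
  names(res_idx) <- NULL
  set_res <- function(idx, name) res_name[match(idx, res_idx)] <<- name
  positive <- c(47, 52, 58, 69, 72, 82, 85, 92, 94, 95, 102, 107, 109)
  arginines <- c(47, 94)
  negative <- c(31, 61)
  for (r in positive) set_res(r, if (r %in% arginines) "ARG" else "LYS")
  for (r in negative) set_res(r, "GLU")
  set_res(80, "VAL"); set_res(87, "VAL"); set_res(104, "ILE")
  set_res(66, "SER"); set_res(67, "SER")
  charge <- rep(0, 80)
  charge[res_name %in% c("LYS", "ARG")] <- 1
  charge[res_name == "GLU"] <- -1
  ## polar pseudo-atom names on the charge sites (H-bond donor/acceptor set)
  atom_name[res_name == "LYS"] <- "NZ"
  atom_name[res_name == "ARG"] <- "NH1"
  atom_name[res_name == "GLU"] <- "OE1"
  net <- sum(charge)
  if (net != spec$lh_net_charge) {
    ## adjust with extra unit sites on filler residues (kept off the
    ## binding face); only small adjustments are supported
    delta <- spec$lh_net_charge - net
    filler <- which(res_idx %in% c(32:46) & charge == 0)
    if (abs(delta) > length(filler)) stop("net charge unrealizable by +/-1 sites")
    take <- utils::head(filler, abs(delta))
    charge[take] <- sign(delta)
    res_name[take] <- if (delta > 0) "LYS" else "GLU"
    atom_name[take] <- if (delta > 0) "NZ" else "OE1"
  }
  atoms <- data.frame(atom_id = seq_len(80), atom_name = atom_name,
                      residue_name = res_name, residue_index = res_idx,
                      chain_id = "A", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], charge = charge, radius = 3.0,
                      stringsAsFactors = FALSE)
  sol <- solute(atoms, label = sprintf("toy LH GD (%+d e)", spec$lh_net_charge))
  annotate_lh_elements(sol,
                       elements = list(alpha1 = c(50, 60), alpha2 = c(62, 75),
                                       l1 = c(76, 79), beta1 = c(80, 90),
                                       alpha3 = c(95, 109)),
                       alpha3_n_terminus = 95, alpha3_c_terminus = 109)
}

## Kabsch superposition: rotation + translation mapping body points B
## onto world points W (least squares)
.kabsch_pose <- function(B, W, center_body) {
  cb <- colMeans(B); cw <- colMeans(W)
  H <- crossprod(sweep(B, 2, cb), sweep(W, 2, cw))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  ## convert R to a quaternion
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  ## translation of the geometric center: world = R (x - cb') + t with the
  ## pose convention rotating about center_body
  t_vec <- cw + as.numeric(R %*% (center_body - cb))
  pose(q, t_vec)
}

#' Place the toy LH in a reference binding mode
#'
#' Constructs a pose whose classification reproduces the target
#' configuration of the requested binding mode on the closed synthetic
#' nucleosome: `"on-dyad"` gives the (−3↑, 0, +3) on-dyad configuration
#' (beta1 at the dyad minor groove, alpha3 and l1 on the distal grooves of
#' the two arms), `"off-dyad-L1"` the all-negative off-dyad configuration
#' on the L-DNA1 arm, `"off-dyad-L2"` its mirror image. The pose is built
#' by superposing element anchor beads onto groove-site anchor points,
#' backed off along the dyad axis until free of excluded-volume overlap,
#' and verified by [classify()]; an error is raised if the target
#' configuration is unreachable.
#'
#' @param lh a [build_toy_lh()] model.
#' @param nuc a [build_ideal_nucleosome()] model (closed reference).
#' @param mode `"on-dyad"`, `"off-dyad-L1"` or `"off-dyad-L2"`.
#' @param cutoff contact cutoff used for verification, Angstrom.
#' @return a [pose].
#' @export
place_reference_pose <- function(lh, nuc, mode = c("on-dyad", "off-dyad-L1",
                                                   "off-dyad-L2"),
                                 cutoff = 5.0, use_twofold = TRUE) {
  mode <- match.arg(mode)
  sites <- groove_site_coords(enumerate_groove_sites(nuc), nuc)
  idx <- vapply(sites, `[[`, numeric(1), "index")
  site_of <- function(k) {
    if (!k %in% idx) stop("groove site ", k, " absent: geometry unreachable")
    sites[[which(idx == k)]]
  }
  fr <- .viewing_frame(nuc)
  arrow_dir <- function(azimuth_deg) {
    a <- azimuth_deg * pi / 180
    cos(a) * fr$e1 + sin(a) * fr$e2
  }
  a <- lh$solute$atoms
  bead <- function(ri) as.numeric(a[match(ri, a$residue_index), c("x", "y", "z")])
  ctr <- geometric_center(lh$solute)
  ## anchor target: offset from the member phosphate nearest the binding
  ## pocket, so the anchor sits inside the contact cutoff but outside the
  ## excluded volume
  anchor <- function(s, pocket, dist = 3.8) {
    d2 <- rowSums(sweep(s$phos_xyz, 2, pocket)^2)
    pp <- s$phos_xyz[which.min(d2), ]
    d <- pocket - pp
    pp + dist * d / sqrt(sum(d^2))
  }

  if (mode == "on-dyad") {
    s0 <- site_of(0); sm3 <- site_of(-3); sp3 <- site_of(3)
    up <- arrow_dir(90)
    pocket <- nuc$dyad_point + 12 * fr$n
    a3a <- anchor(sm3, pocket, dist = 4.5)
    B <- rbind(bead(85), bead(78), bead(95), bead(109))
    W <- rbind(anchor(s0, pocket, dist = 4.2), anchor(sp3, pocket, dist = 4.3),
               a3a - 9 * up, a3a + 9 * up)
    target <- list(alpha3 = -3L, beta1 = 0L, l1 = 3L, mode = "on-dyad",
                   arrow = "\u2191")
  } else {
    mirror <- mode == "off-dyad-L2"
    sgn <- if (mirror) 1L else -1L
    s1 <- site_of(sgn * 1L); s2 <- site_of(sgn * 2L)
    mid <- (s1$center + s2$center) / 2
    away <- (mid - geometric_center(nuc$solute))
    away <- away / sqrt(sum(away^2))
    ## anchor on the closest member pair bridging the two grooves: the
    ## beta1 tip reaches back to the dyad-adjacent groove while the wing
    ## (beta1 start and l1) sits on the arm groove; alpha3 lies along the
    ## dyad-adjacent groove
    P1 <- s1$phos_xyz; P2 <- s2$phos_xyz
    D <- outer(rowSums(P1^2), rowSums(P2^2), `+`) - 2 * P1 %*% t(P2)
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    m1 <- P1[ij[1], ]; m2 <- P2[ij[2], ]
    pick_at <- function(P, ref, target_d) {
      P[which.min(abs(sqrt(rowSums(sweep(P, 2, ref)^2)) - target_d)), ]
    }
    m2q <- pick_at(P2, m2, sqrt(sum((bead(77) - bead(80))^2)))
    m1r <- pick_at(P1, m1, sqrt(sum((bead(106) - bead(85))^2)))
    B <- rbind(bead(85), bead(80), bead(77), bead(106))
    W <- rbind(m1 + 3.6 * away, m2 + 3.6 * away,
               m2q + 3.6 * away, m1r + 4.2 * away)
    target <- list(alpha3 = sgn * 1L, beta1 = sort(c(sgn * 1L, sgn * 2L)),
                   l1 = sgn * 2L,
                   mode = if (mirror) "off-dyad-L-DNA2" else "off-dyad-L-DNA1",
                   arrow = NULL)
  }
  p0 <- .kabsch_pose(B, W, ctr)
  excl <- build_exclusion_grid(nuc)

  ## deterministic hill-climb from a few rotational starts: contacts
  ## toward the target configuration, overlap-free (overlap graded by the
  ## number of beads in occupied exclusion cells so the climb can slide
  ## out of marginal clashes)
  n_intruding <- function(p) {
    xyz <- atoms_at_pose(lh$solute, p)
    ii <- floor(sweep(xyz, 2, excl$origin) / excl$spacing + 0.5)
    inside <- ii[, 1] >= 0 & ii[, 2] >= 0 & ii[, 3] >= 0 &
      ii[, 1] < excl$dims[1] & ii[, 2] < excl$dims[2] & ii[, 3] < excl$dims[3]
    if (!any(inside)) return(0L)
    ii <- ii[inside, , drop = FALSE]
    lin <- ii[, 1] + excl$dims[1] * (ii[, 2] + excl$dims[2] * ii[, 3]) + 1
    sum(excl$occupancy[lin] == 1L)
  }
  ## continuous score: each contact mismatch costs 1 plus a distance
  ## guidance term (how far past the cutoff the offending distance is),
  ## each clash costs its grid count plus the true penetration depth, so
  ## the hill-climb keeps a gradient on the discrete plateaus
  nuc_xyz <- as.matrix(nuc$solute$atoms[, c("x", "y", "z")])
  nuc_reach <- nuc$solute$atoms$radius + excl$margin
  site_idx <- vapply(sites, `[[`, numeric(1), "index")
  mk_score <- function(w_contact, w_overlap) function(p) {
    pen <- 0
    for (el in c("alpha3", "beta1", "l1")) {
      exyz <- .element_atoms(lh, p, el)
      dmin <- vapply(sites, function(s) {
        sqrt(min(.min_cross_dist2(exyz, s$phos_xyz)))
      }, numeric(1))
      tgt <- as.integer(target[[el]])
      got <- site_idx[dmin <= cutoff]
      for (k in setdiff(tgt, got)) {
        pen <- pen + 1 + 0.1 * (dmin[site_idx == k] - cutoff)
      }
      for (k in setdiff(got, tgt)) {
        pen <- pen + 1 + 0.1 * (cutoff - dmin[site_idx == k])
      }
    }
    if (!is.null(target$arrow)) {
      if (alpha3_symbol(lh, p, nuc) != target$arrow) pen <- pen + 1
    }
    xyz <- atoms_at_pose(lh$solute, p)
    d2 <- outer(rowSums(xyz^2), rowSums(nuc_xyz^2), `+`) - 2 * xyz %*% t(nuc_xyz)
    depth <- pmax(-sweep(sqrt(pmax(d2, 0)), 2, nuc_reach), 0)
    -w_contact * pen - w_overlap * (n_intruding(p) + 2 * sum(apply(depth, 1, max)))
  }
  climb <- function(p, score_of) {
    best <- p
    best_s <- score_of(p)
    for (step in c(1.0, 0.5, 0.25, 0.1)) {
      improved <- TRUE
      iter <- 0
      while (improved && best_s < 0 && iter < 60) {
        improved <- FALSE
        iter <- iter + 1
        for (ax in 1:3) for (sg in c(-1, 1)) {
          dt <- numeric(3); dt[ax] <- sg * step
          for (m in list(pose(best$q, best$t + dt),
                         pose(quat_multiply(
                           quat_from_axis_angle(diag(3)[, ax],
                                                sg * 4 * step * pi / 180),
                           best$q), best$t))) {
            s <- score_of(m)
            if (s > best_s) { best <- m; best_s <- s; improved <- TRUE }
          }
        }
      }
      if (best_s >= 0) break
    }
    list(pose = best, score = best_s)
  }
  score_of <- mk_score(1, 2)
  spin_axis <- if (mode == "on-dyad") fr$n else {
    v <- p0$t - geometric_center(nuc$solute); v / sqrt(sum(v^2))
  }
  best <- NULL
  for (spin in c(0, -10, 10, -20, 20)) {
    p_start <- if (spin == 0) p0 else {
      pose(quat_multiply(quat_from_axis_angle(spin_axis, spin * pi / 180),
                         p0$q), p0$t)
    }
    res <- climb(p_start, score_of)
    if (is.null(best) || res$score > best$score) best <- res
    if (best$score >= 0) break
  }
  ## an off-dyad pose that stalls on one arm can be solved on the other
  ## arm and mapped back through the nucleosome's twofold, provided the
  ## model is dyad-symmetric (equal opening angles)
  if (best$score < 0 && use_twofold &&
      mode %in% c("off-dyad-L1", "off-dyad-L2") &&
      .is_twofold_symmetric(nuc)) {
    other <- if (mode == "off-dyad-L1") "off-dyad-L2" else "off-dyad-L1"
    alt <- tryCatch(place_reference_pose(lh, nuc, other, cutoff = cutoff,
                                         use_twofold = FALSE),
                    error = function(e) NULL)
    if (!is.null(alt)) {
      q2 <- quat_from_axis_angle(nuc$dyad_axis, pi)
      R2 <- quat_to_matrix(q2)
      p_m <- pose(quat_multiply(q2, alt$q),
                  as.numeric(R2 %*% (alt$t - nuc$dyad_point)) + nuc$dyad_point)
      ## polish away grid-discretization overlap with contacts locked in
      ## (contact mismatches weighted above any clash relief)
      res_m <- climb(p_m, mk_score(4, 1))
      res_m$score <- score_of(res_m$pose)
      if (res_m$score > best$score) best <- res_m
    }
  }
  if (best$score < 0 || check_overlap(excl, lh, best$pose)) {
    cfg <- classify(lh, best$pose, nuc, sites = sites, cutoff = cutoff)
    stop(sprintf("reference pose unreachable: best candidate %s [%s]%s",
                 cfg$string, cfg$dyad_mode,
                 if (check_overlap(excl, lh, best$pose)) ", overlapping" else ""))
  }
  best$pose
}

## exact twofold symmetry of the phosphate strands about the dyad axis
.is_twofold_symmetric <- function(nuc, tol = 1e-6) {
  a <- nuc$solute$atoms
  bp <- nuc$bp_table
  i <- match(-bp$bp, bp$bp)
  if (any(is.na(i))) return(FALSE)
  p1 <- as.matrix(a[match(bp$p1, a$atom_id), c("x", "y", "z")])
  p2 <- as.matrix(a[match(bp$p2, a$atom_id), c("x", "y", "z")])
  ## twofold about the x axis of the fixture frame: (x, y, z) -> (x, -y, -z)
  m <- cbind(p1[, 1], -p1[, 2], -p1[, 3])
  max(abs(m - p2[i, , drop = FALSE])) < tol
}

#' Synthetic encounter-event stream with planted pose clusters
#'
#' Draws poses around `k` planted centers with Gaussian positional spread
#' and correspondingly small orientational jitter; energies are lower near
#' the centers. Deterministic given the seed (the caller's RNG state is
#' preserved).
#'
#' @param n number of events.
#' @param seed integer seed.
#' @param planted_clusters number of planted centers `k`.
#' @param spread positional standard deviation around a center, Angstrom.
#' @param center_sep typical separation scale of the centers, Angstrom.
#' @return list of events, each `list(pose, energy, cluster)`; the planted
#'   assignment is included for oracle checks.
#' @export
synthetic_event_stream <- function(n, seed = 1, planted_clusters = 2,
                                   spread = 0.3, center_sep = 30) {
  stopifnot(n > 0, planted_clusters >= 1)
  .with_private_seed(seed, {
    centers <- lapply(seq_len(planted_clusters), function(i) {
      list(q = quat_random(),
           t = stats::runif(3, -center_sep, center_sep),
           e0 = -12 + 2 * i)
    })
    lapply(seq_len(n), function(i) {
      ci <- ((i - 1) %% planted_clusters) + 1
      cn <- centers[[ci]]
      dt <- stats::rnorm(3, 0, spread)
      ang <- stats::rnorm(1, 0, spread / 20)
      ax <- stats::rnorm(3)
      q <- if (abs(ang) > 1e-12 && sqrt(sum(ax^2)) > 1e-12) {
        quat_multiply(quat_from_axis_angle(ax, ang), cn$q)
      } else cn$q
      list(pose = pose(q, cn$t + dt),
           energy = cn$e0 + sqrt(sum(dt^2)) + abs(stats::rnorm(1, 0, 0.3)),
           cluster = ci)
    })
  })
}
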