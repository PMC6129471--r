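## Structure input/output and the annotated rigid-body data model for the
## linker-histone globular domain (LH GD) and the nucleosome.

#' Construct a solute (rigid atom set with charges and radii)
#'
#' A solute is the basic rigid-body unit: an ordered atom table with partial
#' charges (e) and radii (Angstrom) plus a rigid-body frame. Both the LH
#' globular domain and the nucleosome are solutes.
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`,
#'   `residue_name`, `residue_index`, `chain_id`, `x`, `y`, `z`, `charge`,
#'   `radius`.
#' @param label character tag for reporting.
#' @param frame a [pose] giving the placement of the solute relative to its
#'   stored (reference) coordinates; defaults to the identity placement.
#' @return object of class `solute`.
#' @export
solute <- function(atoms, label = "solute", frame = NULL) {
  req <- c("atom_id", "atom_name", "residue_name", "residue_index",
           "chain_id", "x", "y", "z", "charge", "radius")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("solute must contain at least one atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(!is.finite(atoms$charge)) || any(!is.finite(atoms$radius))) {
    stop("non-finite charge or radius")
  }
  if (any(atoms$radius < 0)) stop("negative atom radius")
  obj <- structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                        label = label, frame = frame),
                   class = "solute")
  if (is.null(frame)) obj$frame <- pose_identity(obj)
  obj
}

#' @export
print.solute <- function(x, ...) {
  cat(sprintf("<solute '%s'> %d atoms, %d residues, net charge %+d e (sum %.3f e)\n",
              x$label, nrow(x$atoms), length(unique(x$atoms$residue_index)),
              net_formal_charge(x), sum(x$atoms$charge)))
  invisible(x)
}

#' Geometric center of a solute
#'
#' Unweighted mean of the reference atom positions; all center-to-center
#' distances in the docking protocol use this definition.
#'
#' @param solute a [solute].
#' @return numeric(3), Angstroms.
#' @export
geometric_center <- function(solute) {
  colMeans(as.matrix(solute$atoms[, c("x", "y", "z")]))
}

#' Net formal charge of a solute
#'
#' Sum of partial charges rounded to the nearest integer. The unrounded sum
#' is attached as attribute `"sum"`.
#'
#' @param solute a [solute].
#' @return integer charge in e, with attribute `sum` (numeric).
#' @export
net_formal_charge <- function(solute) {
  s <- sum(solute$atoms$charge)
  structure(as.integer(round(s)), sum = s)
}

#' Bake a rigid transform into a solute's stored coordinates
#'
#' @param solute a [solute].
#' @param pose a [pose]; rotation acts about the solute's geometric center.
#' @return a new [solute] whose reference coordinates are the transformed
#'   ones (identity frame).
#' @export
transform_solute <- function(solute, pose) {
  xyz <- atoms_at_pose(solute, pose)
  out <- solute
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out$frame <- NULL
  out <- structure(out, class = "solute")
  out$frame <- pose_identity(out)
  out
}

#' Read a PQR structure file
#'
#' Whitespace-delimited PQR dialect: `ATOM`/`HETATM` records carrying
#' `atom_id name resname [chain] resid x y z charge radius`; the chain field
#' is optional and detected per line from the field count. Other record
#' types are ignored.
#'
#' @param path file path.
#' @param label solute label; defaults to the file name.
#' @return a [solute] with identity frame and atom order as in the file.
#' @export
read_pqr <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  if (!any(keep)) stop("no ATOM/HETATM records in ", path)
  idx <- which(keep)
  recs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    ## 10 fields without chain, 11 with chain (first field is the record tag)
    if (length(f) == 10) {
      chain <- ""
      rest <- f[2:10]
    } else if (length(f) >= 11) {
      chain <- f[5]
      rest <- f[c(2:4, 6:11)]
    } else {
      stop(sprintf("malformed PQR record at line %d of %s", ln, path))
    }
    num <- suppressWarnings(as.numeric(rest[c(1, 4:9)]))
    if (any(is.na(num))) {
      stop(sprintf("malformed PQR record at line %d of %s", ln, path))
    }
    recs[[k]] <- data.frame(
      atom_id = as.integer(num[1]), atom_name = rest[2],
      residue_name = rest[3], residue_index = as.integer(num[2]),
      chain_id = chain, x = num[3], y = num[4], z = num[5],
      charge = num[6], radius = num[7], stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, recs)
  solute(atoms, label = if (is.null(label)) basename(path) else label)
}

#' Write a solute as a PQR file
#'
#' Coordinates are written at the solute's current frame, so a
#' frame-transformed solute writes transformed coordinates. Fixed precision:
#' coordinates `%.3f`, charge and radius `%.4f`; `read_pqr()` round-trips
#' the file at that precision.
#'
#' @param solute a [solute].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pqr <- function(solute, path) {
  if (nrow(solute$atoms) == 0) stop("refusing to write a 0-atom solute")
  xyz <- atoms_at_pose(solute, solute$frame)
  a <- solute$atoms
  has_chain <- any(nzchar(a$chain_id))
  lines <- vapply(seq_len(nrow(a)), function(i) {
    if (has_chain) {
      sprintf("ATOM %6d %-4s %-4s %s %5d %11.3f %11.3f %11.3f %8.4f %8.4f",
              a$atom_id[i], a$atom_name[i], a$residue_name[i],
              ifelse(nzchar(a$chain_id[i]), a$chain_id[i], "X"),
              a$residue_index[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
              a$charge[i], a$radius[i])
    } else {
      sprintf("ATOM %6d %-4s %-4s %5d %11.3f %11.3f %11.3f %8.4f %8.4f",
              a$atom_id[i], a$atom_name[i], a$residue_name[i],
              a$residue_index[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
              a$charge[i], a$radius[i])
    }
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read ATOM records from a PDB file (minimal reader)
#'
#' Fixed-column PDB `ATOM`/`HETATM` parsing for annotation convenience.
#' Charges and radii are set to zero (PDB does not carry them).
#'
#' @param path file path.
#' @param label solute label.
#' @return a [solute].
#' @export
read_pdb_atoms <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(lines) == 0) stop("no ATOM/HETATM records in ", path)
  atoms <- data.frame(
    atom_id = as.integer(substr(lines, 7, 11)),
    atom_name = trimws(substr(lines, 13, 16)),
    residue_name = trimws(substr(lines, 18, 20)),
    residue_index = as.integer(substr(lines, 23, 26)),
    chain_id = trimws(substr(lines, 22, 22)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    charge = 0, radius = 0, stringsAsFactors = FALSE)
  solute(atoms, label = if (is.null(label)) basename(path) else label)
}

#' Annotate a linker-histone solute with its structural elements
#'
#' Marks the residue ranges of the winged-helix elements (three alpha
#' helices, the beta1 wing and the l1 loop) and the N/C termini of the
#' alpha3 helix, which define the direction arrow used in configuration
#' classification.
#'
#' @param solute a [solute].
#' @param elements named list of integer ranges `c(first, last)` (residue
#'   indices, 1-based as in the input file) with names among `alpha1`,
#'   `alpha2`, `alpha3`, `beta1`, `l1`. `alpha3` is required for the
#'   direction symbol.
#' @param alpha3_n_terminus,alpha3_c_terminus residue indices of the alpha3
#'   helix termini; default to the ends of the `alpha3` range.
#' @return object of class `lh_model`.
#' @export
annotate_lh_elements <- function(solute, elements,
                                 alpha3_n_terminus = NULL,
                                 alpha3_c_terminus = NULL) {
  allowed <- c("alpha1", "alpha2", "alpha3", "beta1", "l1")
  bad <- setdiff(names(elements), allowed)
  if (length(bad) > 0) stop("unknown element name(s): ", paste(bad, collapse = ", "))
  span <- range(solute$atoms$residue_index)
  covered <- integer(0)
  for (nm in names(elements)) {
    r <- elements[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("element ", nm, " range must be c(first, last)")
    if (r[1] < span[1] || r[2] > span[2]) {
      stop("element ", nm, " range outside the residue span of the solute")
    }
    ids <- seq(r[1], r[2])
    if (length(intersect(covered, ids)) > 0) stop("element ranges overlap at ", nm)
    covered <- c(covered, ids)
  }
  if (!"alpha3" %in% names(elements)) stop("an alpha3 range is required")
  a3 <- elements[["alpha3"]]
  if (is.null(alpha3_n_terminus)) alpha3_n_terminus <- a3[1]
  if (is.null(alpha3_c_terminus)) alpha3_c_terminus <- a3[2]
  if (alpha3_n_terminus < a3[1] || alpha3_n_terminus > a3[2] ||
      alpha3_c_terminus < a3[1] || alpha3_c_terminus > a3[2]) {
    stop("alpha3 terminus indices must lie inside the alpha3 range")
  }
  structure(list(solute = solute, elements = elements,
                 alpha3_n_terminus = alpha3_n_terminus,
                 alpha3_c_terminus = alpha3_c_terminus,
                 ptms = character(0)),
            class = "lh_model")
}

#' @export
print.lh_model <- function(x, ...) {
  cat(sprintf("<lh_model '%s'> %d residues, net charge %+d e; elements: %s\n",
              x$solute$label, length(unique(x$solute$atoms$residue_index)),
              net_formal_charge(x$solute),
              paste(names(x$elements), collapse = ", ")))
  if (length(x$ptms)) cat("  PTMs:", paste(x$ptms, collapse = ", "), "\n")
  invisible(x)
}

#' Annotate a nucleosome solute with dyad geometry and base-pair bookkeeping
#'
#' Builds the `nucleosome_model` used by the docking and classification
#' stages. The dyad point is the midpoint of the two phosphate positions of
#' the dyad base pair; the dyad axis is the unit vector from the superhelix
#' center (centroid of the N-DNA phosphates) through the dyad point, which
#' fixes the viewing plane of the groove-labeling convention.
#'
#' @param solute a [solute] holding DNA (phosphates) and histone-core atoms.
#' @param bp_map data.frame with one row per base pair and columns `bp`
#'   (integer index), `segment` (one of `"N-DNA"`, `"L-DNA1"`, `"L-DNA2"`),
#'   `p1`, `p2` (phosphate `atom_id` on each strand).
#' @param dyad_bp value of `bp` in `bp_map` that is the dyad base pair;
#'   indices are re-centered so the dyad is 0.
#' @param core_atom_ids atom ids of the histone-core region (excluded from
#'   DNA coverage checks and groove geometry).
#' @return object of class `nucleosome_model`.
#' @export
annotate_nucleosome <- function(solute, bp_map, dyad_bp = 0,
                                core_atom_ids = integer(0)) {
  req <- c("bp", "segment", "p1", "p2")
  if (!all(req %in% names(bp_map))) {
    stop("bp_map needs columns: ", paste(req, collapse = ", "))
  }
  if (!dyad_bp %in% bp_map$bp) stop("dyad base pair ", dyad_bp, " missing from bp_map")
  if (anyDuplicated(bp_map$bp)) stop("duplicate bp indices in bp_map")
  if (!all(bp_map$segment %in% c("N-DNA", "L-DNA1", "L-DNA2"))) {
    stop("segment labels must be N-DNA, L-DNA1 or L-DNA2")
  }
  a <- solute$atoms
  id2row <- match(c(bp_map$p1, bp_map$p2), a$atom_id)
  if (any(is.na(id2row))) stop("bp_map refers to unknown atom ids")
  ## every DNA atom (non-core) must belong to a base pair listed in bp_map
  dna_rows <- !(a$atom_id %in% core_atom_ids)
  bp_res <- unique(a$residue_index[id2row])
  uncovered <- setdiff(unique(a$residue_index[dna_rows]), bp_res)
  if (length(uncovered) > 0) {
    stop("bp_map does not cover DNA residue(s): ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  }
  bp_map <- bp_map[order(bp_map$bp), , drop = FALSE]
  bp_map$bp <- bp_map$bp - dyad_bp
  dy <- bp_map[bp_map$bp == 0, ]
  pos <- function(id) as.numeric(a[match(id, a$atom_id), c("x", "y", "z")])
  dyad_point <- (pos(dy$p1) + pos(dy$p2)) / 2
  ndna <- bp_map[bp_map$segment == "N-DNA", ]
  pcoords <- a[match(c(ndna$p1, ndna$p2), a$atom_id), c("x", "y", "z")]
  sh_center <- colMeans(as.matrix(pcoords))
  ax <- dyad_point - sh_center
  nax <- sqrt(sum(ax^2))
  if (nax < 1e-9) stop("degenerate dyad axis (dyad point at superhelix center)")
  structure(list(solute = solute, dyad_point = dyad_point,
                 dyad_axis = ax / nax, superhelix_center = sh_center,
                 bp_table = bp_map, core_atom_ids = core_atom_ids),
            class = "nucleosome_model")
}

#' @export
print.nucleosome_model <- function(x, ...) {
  segs <- table(x$bp_table$segment)
  cat(sprintf("<nucleosome_model '%s'> %d bp (%s), %d core atoms, net charge %+d e\n",
              x$solute$label, nrow(x$bp_table),
              paste(sprintf("%s: %d", names(segs), segs), collapse = ", "),
              length(x$core_atom_ids), net_formal_charge(x$solute)))
  invisible(x)
}
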