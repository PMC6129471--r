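## Groove-indexed configuration classification of docked LH poses.
##
## Groove labeling convention: with the nucleosome dyad axis perpendicular
## to the viewing plane, the minor groove at the dyad is labeled 0 and the
## major grooves are numbered outward every helical turn, negative toward
## the L-DNA1 arm and positive toward L-DNA2. A configuration is the
## triple of groove-contact lists of the alpha3, beta1 and l1 elements,
## the alpha3 helix N-to-C direction quantized to eight compass arrows in
## the viewing plane (X when nearly perpendicular to it), and the
## on-dyad / off-dyad binding-mode call.

.compass_arrows <- c("\u2192", "\u2197", "\u2191", "\u2196",
                     "\u2190", "\u2199", "\u2193", "\u2198")

#' Enumerate the DNA groove sites of a nucleosome
#'
#' Site 0 is the minor groove at the dyad base pair. Sites +1 and -1 are
#' the dyad-adjacent major grooves of the N-DNA (half a helical turn from
#' the dyad on either side along the contour); the label -1 goes to the
#' groove on the L-DNA1 side and +1 to the L-DNA2 side. Because the
#' nucleosomal wrap is about 1.65 turns, the arm attached at the negative
#' base-pair end emerges spatially on the positive base-pair side of the
#' dyad, so this side assignment is geometric (distance to the arm), not
#' a contour sign. Sites with |index| >= 2 are the successive major
#' grooves along each L-DNA arm, walking from the arm attachment to the
#' arm end (negative indices on L-DNA1, positive on L-DNA2). Each site's
#' member phosphates are the P atoms of both strands within a quarter
#' turn of the site's base-pair position; the center is their centroid.
#'
#' @param nuc a `nucleosome_model`.
#' @param helical_repeat base pairs per helical turn (default 10.4).
#' @return list of groove sites (class `groove_sites`), each with
#'   `index`, `center`, `phosphate_ids`, `segment`.
#' @export
enumerate_groove_sites <- function(nuc, helical_repeat = 10.4) {
  bp <- nuc$bp_table
  a <- nuc$solute$atoms
  hw <- helical_repeat / 4
  pos_of <- function(ids) {
    as.matrix(a[match(ids, a$atom_id), c("x", "y", "z"), drop = FALSE])
  }
  site_at <- function(bp_center, index) {
    rows <- which(bp$bp >= bp_center - hw & bp$bp <= bp_center + hw &
                    sign(bp$bp) != -sign(bp_center))
    if (length(rows) == 0) return(NULL)
    ids <- c(bp$p1[rows], bp$p2[rows])
    nearest <- rows[which.min(abs(bp$bp[rows] - bp_center))]
    list(index = index, center = colMeans(pos_of(ids)), phosphate_ids = ids,
         segment = bp$segment[nearest])
  }
  half <- max(bp$bp[bp$segment == "N-DNA"])
  if (half < helical_repeat / 2 + hw) {
    warning("N-DNA shorter than one helical turn: no dyad-adjacent grooves")
  }
  s0 <- site_at(0, 0L)
  g_plus <- site_at(helical_repeat / 2, NA_integer_)
  g_minus <- site_at(-helical_repeat / 2, NA_integer_)
  ## side assignment of the +/-1 labels: distance to the L-DNA1 arm
  arm1_rows <- bp$segment == "L-DNA1"
  if (any(arm1_rows) && !is.null(g_plus) && !is.null(g_minus)) {
    a1c <- colMeans(pos_of(c(bp$p1[arm1_rows], bp$p2[arm1_rows])))
    d_plus <- sum((g_plus$center - a1c)^2)
    d_minus <- sum((g_minus$center - a1c)^2)
    if (d_plus < d_minus) {
      g_plus$index <- -1L; g_minus$index <- 1L
    } else {
      g_plus$index <- 1L; g_minus$index <- -1L
    }
  } else {
    if (!is.null(g_plus)) g_plus$index <- 1L
    if (!is.null(g_minus)) g_minus$index <- -1L
  }
  ## arm grooves: every helical turn from the attachment outward; the
  ## label sign follows the segment name (L-DNA1 negative), while the
  ## base-pair window follows wherever that segment actually sits, so
  ## relabeling the arms flips the groove signs
  arm_sites <- function(segment, sign_k) {
    rows <- bp$segment == segment
    if (!any(rows)) return(list())
    sgn_bp <- sign(bp$bp[rows][which.max(abs(bp$bp[rows]))])
    arm_len <- max(abs(bp$bp[rows])) - half
    ks <- seq_len(max(0, floor(arm_len / helical_repeat + 0.5)))
    out <- list()
    for (i in ks) {
      ctr <- sgn_bp * (half + (i - 0.5) * helical_repeat)
      s <- site_at(ctr, sign_k * (i + 1L))
      if (!is.null(s)) out[[length(out) + 1]] <- s
    }
    out
  }
  sites <- c(arm_sites("L-DNA1", -1L), list(g_minus, s0, g_plus),
             arm_sites("L-DNA2", 1L))
  sites <- Filter(Negate(is.null), sites)
  ord <- order(vapply(sites, `[[`, numeric(1), "index"))
  structure(sites[ord], class = "groove_sites")
}

#' @export
print.groove_sites <- function(x, ...) {
  cat(sprintf("<groove_sites> %d sites, indices %d..%d\n", length(x),
              x[[1]]$index, x[[length(x)]]$index))
  invisible(x)
}

## world-frame coordinates of the atoms of one LH element
.element_atoms <- function(lh, pose, element) {
  rng <- lh$elements[[element]]
  if (is.null(rng)) return(NULL)
  xyz <- atoms_at_pose(lh$solute, pose)
  rows <- lh$solute$atoms$residue_index >= rng[1] &
    lh$solute$atoms$residue_index <= rng[2]
  xyz[rows, , drop = FALSE]
}

#' Groove contacts of the LH structural elements
#'
#' An element contacts groove k when any of its atoms lies within `cutoff`
#' of any member phosphate of site k.
#'
#' @param lh an `lh_model`.
#' @param pose the LH [pose].
#' @param sites an [enumerate_groove_sites()] list.
#' @param cutoff contact distance, Angstrom (default 5.0).
#' @param elements which elements to report (default alpha3, beta1, l1).
#' @return named list of sorted integer groove-index vectors (possibly
#'   empty).
#' @export
element_contacts <- function(lh, pose, sites, cutoff = 5.0,
                             elements = c("alpha3", "beta1", "l1")) {
  out <- stats::setNames(vector("list", length(elements)), elements)
  for (el in elements) {
    exyz <- .element_atoms(lh, pose, el)
    hits <- integer(0)
    if (!is.null(exyz) && nrow(exyz) > 0) {
      for (s in sites) {
        pp <- attr(s, "phos_xyz")
        if (is.null(pp)) pp <- s$phos_xyz
        if (is.null(pp)) stop("sites lack phosphate coordinates; rebuild with groove_site_coords()")
        d2min <- min(.min_cross_dist2(exyz, pp))
        if (d2min <= cutoff^2) hits <- c(hits, s$index)
      }
    }
    out[[el]] <- sort(hits)
  }
  out
}

## squared distances: for each row of A, min over rows of B
.min_cross_dist2 <- function(A, B) {
  ## full cross distance matrix (element atom counts are small)
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  apply(d2, 1, min)
}

#' Attach member-phosphate coordinates to groove sites
#'
#' Caches the phosphate coordinates on each site so repeated contact
#' evaluations avoid atom-table lookups.
#'
#' @param sites an [enumerate_groove_sites()] list.
#' @param nuc the `nucleosome_model` the sites were built from.
#' @return the sites with a `phos_xyz` matrix on each element.
#' @export
groove_site_coords <- function(sites, nuc) {
  a <- nuc$solute$atoms
  out <- lapply(sites, function(s) {
    s$phos_xyz <- as.matrix(a[match(s$phosphate_ids, a$atom_id),
                              c("x", "y", "z"), drop = FALSE])
    s
  })
  structure(out, class = "groove_sites")
}

## orthonormal in-plane reference frame of the groove labeling convention:
## e1 points from the dyad toward the L-DNA2 arm (projected into the
## viewing plane), e2 = dyad_axis x e1 (counterclockwise viewed down the
## dyad axis)
.viewing_frame <- function(nuc) {
  n <- nuc$dyad_axis
  a <- nuc$solute$atoms
  l2 <- nuc$bp_table[nuc$bp_table$segment == "L-DNA2", ]
  ref_rows <- if (nrow(l2) > 0) l2 else {
    nuc$bp_table[nuc$bp_table$bp >= max(nuc$bp_table$bp) - 5, ]
  }
  ids <- c(ref_rows$p1, ref_rows$p2)
  cen <- colMeans(as.matrix(a[match(ids, a$atom_id), c("x", "y", "z")]))
  v <- cen - nuc$dyad_point
  v <- v - sum(v * n) * n
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate viewing frame: L-DNA2 direction parallel to dyad axis")
  e1 <- v / nv
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(n = n, e1 = e1, e2 = e2)
}

#' Direction symbol of the alpha3 helix
#'
#' Projects the N-to-C vector of the alpha3 helix into the viewing plane
#' (perpendicular to the dyad axis) and quantizes its azimuth to the
#' nearest of eight compass arrows; returns `"X"` when the vector is
#' within `theta_x` degrees of the dyad axis (nearly perpendicular to the
#' viewing plane). Azimuth 0 is the dyad-to-L-DNA2 direction,
#' counterclockwise positive viewed down the dyad axis.
#'
#' @param lh an `lh_model` with alpha3 termini annotated.
#' @param pose the LH [pose].
#' @param nuc a `nucleosome_model`.
#' @param theta_x X-call half-angle, degrees (default 30).
#' @return single character: one of the eight arrows or `"X"`.
#' @export
alpha3_symbol <- function(lh, pose, nuc, theta_x = 30) {
  a <- lh$solute$atoms
  res_pos <- function(ri) {
    rows <- which(a$residue_index == ri)
    ca <- rows[a$atom_name[rows] == "CA"]
    rows <- if (length(ca) > 0) ca else rows
    colMeans(atoms_at_pose(lh$solute, pose)[rows, , drop = FALSE])
  }
  v <- res_pos(lh$alpha3_c_terminus) - res_pos(lh$alpha3_n_terminus)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("zero-length alpha3 vector")
  v <- v / nv
  fr <- .viewing_frame(nuc)
  if (abs(sum(v * fr$n)) > cos(theta_x * pi / 180)) return("X")
  az <- atan2(sum(v * fr$e2), sum(v * fr$e1))
  idx <- (round(az / (pi / 4)) %% 8) + 1
  .compass_arrows[idx]
}

#' Classify a docked pose into a groove-contact configuration
#'
#' @param lh an `lh_model`.
#' @param pose the LH [pose].
#' @param nuc a `nucleosome_model`.
#' @param sites optional precomputed [groove_site_coords()] sites.
#' @param cutoff contact distance, Angstrom.
#' @param theta_x X-call half-angle for the alpha3 symbol, degrees.
#' @return object of class `lh_configuration` with `contacts`,
#'   `alpha3_symbol`, `dyad_mode` and the rendered `string`.
#' @export
classify <- function(lh, pose, nuc, sites = NULL, cutoff = 5.0, theta_x = 30) {
  if (is.null(sites)) sites <- groove_site_coords(enumerate_groove_sites(nuc), nuc)
  contacts <- element_contacts(lh, pose, sites, cutoff = cutoff)
  sym <- alpha3_symbol(lh, pose, nuc, theta_x = theta_x)
  all_idx <- sort(unique(unlist(contacts)))
  dyad_mode <- if (length(all_idx) == 0) "none"
    else if (0 %in% all_idx) "on-dyad"
    else if (all(all_idx < 0)) "off-dyad-L-DNA1"
    else if (all(all_idx > 0)) "off-dyad-L-DNA2"
    else "mixed"
  cfg <- structure(list(contacts = contacts, alpha3_symbol = sym,
                        dyad_mode = dyad_mode),
                   class = "lh_configuration")
  cfg$string <- format(cfg)
  cfg
}

## render a groove index in the publication style (unicode minus)
.fmt_idx <- function(k) {
  if (k == 0) "0" else if (k > 0) paste0("+", k) else paste0("\u2212", abs(k))
}

#' @export
format.lh_configuration <- function(x, ...) {
  grp <- function(v, arrow = NULL) {
    s <- if (length(v) == 0) "no" else paste(vapply(v, .fmt_idx, character(1)),
                                             collapse = " ")
    if (!is.null(arrow) && s != "no") s <- paste0(s, arrow)
    s
  }
  sprintf("(%s, %s, %s)",
          grp(x$contacts$alpha3, x$alpha3_symbol),
          grp(x$contacts$beta1), grp(x$contacts$l1))
}

#' @export
print.lh_configuration <- function(x, ...) {
  cat(sprintf("<configuration> %s  [%s]\n", x$string, x$dyad_mode))
  invisible(x)
}

#' Compare a variant configuration with a reference
#'
#' Categories follow the match scheme of the docking analysis:
#' `"identical"` when the groove-contact lists of all three structural
#' elements agree, `"partial"` when one or two agree, `"different"` when
#' none do.
#'
#' @param variant,reference `lh_configuration` objects classified against
#'   the same groove-site set.
#' @return character: `"identical"`, `"partial"` or `"different"`.
#' @export
compare_configurations <- function(variant, reference) {
  els <- c("alpha3", "beta1", "l1")
  n_eq <- sum(vapply(els, function(e) {
    identical(as.integer(variant$contacts[[e]]),
              as.integer(reference$contacts[[e]]))
  }, logical(1)))
  if (n_eq == 3) "identical" else if (n_eq >= 1) "partial" else "different"
}

#' Variant-versus-reference configuration matrix
#'
#' One row per (variant, nucleosome-conformer) cell: the configuration
#' string and its match category against the reference variant (default
#' `"WT"`) on the same conformer. Per-variant shift counts (cells whose
#' category is not `"identical"`) are attached as attribute
#' `"shift_counts"`.
#'
#' @param runs nested named list: `runs[[variant]][[conformer]]` is an
#'   `lh_configuration`.
#' @param reference name of the reference variant row.
#' @return data.frame with columns `variant`, `conformer`,
#'   `configuration`, `dyad_mode`, `category`.
#' @export
build_match_matrix <- function(runs, reference = "WT") {
  if (!reference %in% names(runs)) stop("reference variant '", reference,
                                        "' missing from runs")
  conformers <- names(runs[[reference]])
  rows <- list()
  for (v in names(runs)) {
    for (cf in names(runs[[v]])) {
      cfg <- runs[[v]][[cf]]
      ref_cfg <- runs[[reference]][[cf]]
      cat_ <- if (v == reference) "reference"
        else if (is.null(ref_cfg)) NA_character_
        else compare_configurations(cfg, ref_cfg)
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, conformer = cf, configuration = cfg$string,
        dyad_mode = cfg$dyad_mode, category = cat_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(is.na(out$category))) {
    warning("conformers without a reference cell: category undefined")
  }
  shifts <- vapply(setdiff(names(runs), reference), function(v) {
    sub <- out[out$variant == v, ]
    sum(!is.na(sub$category) & sub$category != "identical")
  }, numeric(1))
  attr(out, "shift_counts") <- shifts
  out
}
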