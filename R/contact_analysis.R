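## Hydrogen-bond counting between the LH and the DNA phosphate backbone.
## The criterion is a distance window on donor/acceptor heavy atoms
## (default 3.2-3.6 A, both bounds enforced as the protocol states); a
## conventional 0-3.6 A mode is selectable because the lower bound is
## unusual. No angular criterion is applied.

.lh_polar_pattern <- "^[NO]"
.dna_acceptor_names <- c("P", "OP1", "OP2", "O1P", "O2P", "O3'", "O5'")

#' Find LH-DNA hydrogen bonds in a docked pose
#'
#' Candidate LH atoms are the polar (N/O) side-chain and backbone atoms;
#' DNA partners are the phosphate-backbone atoms (phosphate-group oxygens
#' and the phosphorus-adjacent O3'/O5'; bare P pseudo-atoms of
#' coarse-grained models are included). Every qualifying pair is listed
#' once, in deterministic order (LH atom, then DNA atom id).
#'
#' @param lh an `lh_model`.
#' @param pose the LH [pose].
#' @param nuc a `nucleosome_model`.
#' @param d_min,d_max distance window, Angstrom (defaults 3.2 and 3.6).
#' @param mode `"window"` enforces both bounds; `"max_only"` uses
#'   `[0, d_max]`.
#' @return data.frame with one row per bond: `lh_residue_index`,
#'   `lh_residue_name`, `lh_atom`, `dna_atom_id`, `dna_residue_index`,
#'   `distance`.
#' @export
find_hbonds <- function(lh, pose, nuc, d_min = 3.2, d_max = 3.6,
                        mode = c("window", "max_only")) {
  mode <- match.arg(mode)
  if (mode == "max_only") d_min <- 0
  la <- lh$solute$atoms
  lh_rows <- grep(.lh_polar_pattern, la$atom_name)
  na_ <- nuc$solute$atoms
  dna_rows <- which(na_$atom_name %in% .dna_acceptor_names &
                      !(na_$atom_id %in% nuc$core_atom_ids))
  empty <- data.frame(lh_residue_index = integer(0),
                      lh_residue_name = character(0), lh_atom = character(0),
                      dna_atom_id = integer(0), dna_residue_index = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (length(lh_rows) == 0 || length(dna_rows) == 0) return(empty)
  lxyz <- atoms_at_pose(lh$solute, pose)[lh_rows, , drop = FALSE]
  dxyz <- as.matrix(na_[dna_rows, c("x", "y", "z")])
  d2 <- outer(rowSums(lxyz^2), rowSums(dxyz^2), `+`) - 2 * lxyz %*% t(dxyz)
  hits <- which(d2 >= d_min^2 & d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  li <- lh_rows[hits[, 1]]; di <- dna_rows[hits[, 2]]
  data.frame(lh_residue_index = la$residue_index[li],
             lh_residue_name = la$residue_name[li],
             lh_atom = la$atom_name[li],
             dna_atom_id = na_$atom_id[di],
             dna_residue_index = na_$residue_index[di],
             distance = sqrt(d2[hits]), stringsAsFactors = FALSE)
}

#' Aggregate hydrogen-bond tables over runs and clusters
#'
#' Sums per-residue bond counts over a collection of [find_hbonds()]
#' tables (e.g. the top-two cluster representatives of several docking
#' runs) and flags residues that make more than one bond within any
#' single docked pose.
#'
#' @param tables named list of [find_hbonds()] data.frames; names label
#'   the runs/clusters.
#' @return list with `per_residue` (data.frame: `residue_index`,
#'   `residue_name`, `n_hbonds`, `multiple`), `detail` (per-table
#'   per-residue counts) and `total` (grand total bond count).
#' @export
aggregate_hbonds <- function(tables) {
  if (length(tables) == 0) {
    return(list(per_residue = data.frame(residue_index = integer(0),
                                         residue_name = character(0),
                                         n_hbonds = numeric(0),
                                         multiple = logical(0)),
                detail = data.frame(), total = 0))
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("run", seq_along(tables))
  }
  detail_rows <- list()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (nrow(tb) == 0) next
    cnt <- stats::aggregate(list(n = tb$distance),
                            by = list(residue_index = tb$lh_residue_index,
                                      residue_name = tb$lh_residue_name),
                            FUN = length)
    cnt$table <- nm
    detail_rows[[length(detail_rows) + 1]] <- cnt
  }
  if (length(detail_rows) == 0) {
    return(list(per_residue = data.frame(residue_index = integer(0),
                                         residue_name = character(0),
                                         n_hbonds = numeric(0),
                                         multiple = logical(0)),
                detail = data.frame(), total = 0))
  }
  detail <- do.call(rbind, detail_rows)
  ## consistency of residue labels across tables
  lab <- unique(detail[, c("residue_index", "residue_name")])
  if (anyDuplicated(lab$residue_index)) {
    stop("residue label mismatch across tables at residue ",
         lab$residue_index[duplicated(lab$residue_index)][1])
  }
  agg <- stats::aggregate(list(n_hbonds = detail$n),
                          by = list(residue_index = detail$residue_index,
                                    residue_name = detail$residue_name),
                          FUN = sum)
  multi <- stats::aggregate(list(multiple = detail$n > 1),
                            by = list(residue_index = detail$residue_index),
                            FUN = any)
  agg$multiple <- multi$multiple[match(agg$residue_index, multi$residue_index)]
  agg <- agg[order(agg$residue_index), ]
  rownames(agg) <- NULL
  list(per_residue = agg, detail = detail, total = sum(agg$n_hbonds))
}
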