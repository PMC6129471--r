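## Point mutations and posttranslational modifications as parameter-level
## edits (charge / radius / site identity) on a linker-histone model.
## Docking here is rigid-body and electrostatics-driven, so a variant is
## fully described by the charge and radius parameters of the edited site;
## no rotamer search or structure rebuilding is performed.

## formal side-chain charges of the standard residues (e)
.residue_formal_charge <- c(
  ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0, GLU = -1, GLY = 0,
  HIS = 0, ILE = 0, LEU = 0, LYS = 1, MET = 0, PHE = 0, PRO = 0, SER = 0,
  THR = 0, TRP = 0, TYR = 0, VAL = 0)

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Default PTM parameter table
#'
#' Charge and radius edits for the supported posttranslational
#' modifications. Phosphoserine carries the phosphate dianion (net charge
#' delta -2 e); dimethyl-lysine retains the +1 ammonium charge (delta 0 e).
#' The radius increments are package defaults standing in for
#' literature-derived all-atom parameter sets, and the whole table is
#' user-overridable.
#'
#' @return data.frame with columns `ptm`, `residue` (required residue
#'   type), `charge_delta` (e), `radius_delta` (Angstrom), `new_name`.
#' @export
ptm_parameter_table <- function() {
  data.frame(
    ptm = c("phosphoserine", "dimethyl-lysine"),
    residue = c("SER", "LYS"),
    charge_delta = c(-2, 0),
    radius_delta = c(0.5, 0.4),
    new_name = c("SEP", "MLY"),
    stringsAsFactors = FALSE)
}

#' Parse a variant string into a variant spec
#'
#' Accepts the compact notations used throughout the package: `"V80K"`
#' (point mutation), `"K72me2"` (lysine dimethylation) and `"S67ph"`
#' (serine phosphorylation).
#'
#' @param text variant string.
#' @return object of class `variant_spec` with fields `kind`
#'   (`"mutation"` or `"ptm"`), `residue_index`, `from_residue`, and
#'   `to_residue` or `ptm_name`.
#' @export
parse_variant <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^([A-Z])([0-9]+)(me2|ph|[A-Z])$", text))[[1]]
  if (length(m) == 0) stop("cannot parse variant string: ", text)
  from1 <- m[2]; idx <- as.integer(m[3]); tail <- m[4]
  if (!from1 %in% names(.aa1to3)) stop("unknown residue code in ", text)
  from3 <- .aa1to3[[from1]]
  if (tail == "me2") {
    if (from3 != "LYS") stop("dimethylation requires a lysine site: ", text)
    spec <- list(kind = "ptm", residue_index = idx, from_residue = from3,
                 ptm_name = "dimethyl-lysine")
  } else if (tail == "ph") {
    if (from3 != "SER") stop("phosphorylation requires a serine site: ", text)
    spec <- list(kind = "ptm", residue_index = idx, from_residue = from3,
                 ptm_name = "phosphoserine")
  } else {
    if (!tail %in% names(.aa1to3)) stop("unknown target residue in ", text)
    spec <- list(kind = "mutation", residue_index = idx, from_residue = from3,
                 to_residue = .aa1to3[[tail]])
  }
  spec$text <- text
  structure(spec, class = "variant_spec")
}

## internal: rows of the atom table belonging to a residue, plus the single
## "charge site" of the residue (the atom carrying the largest |charge|,
## ties broken by atom order).
.residue_site <- function(atoms, residue_index) {
  rows <- which(atoms$residue_index == residue_index)
  if (length(rows) == 0) stop("no residue with index ", residue_index)
  site <- rows[which.max(abs(atoms$charge[rows]) + 1e-9 * rev(seq_along(rows)))]
  list(rows = rows, site = rows[which.max(abs(atoms$charge[rows]))])
}

#' Apply a point mutation to a linker-histone model
#'
#' The mutation is a parameter edit at the residue's charge site: the
#' residue is renamed and its total charge shifted by the formal-charge
#' difference of the residue pair, so the model's net charge changes by
#' exactly that difference (e.g. a lysine-to-valine exchange removes +1 e).
#' Element annotation is preserved.
#'
#' @param model an [annotate_lh_elements()] model.
#' @param spec a [parse_variant()] spec (or a string, parsed on the fly)
#'   with `kind == "mutation"`.
#' @return the mutated `lh_model`.
#' @export
apply_mutation <- function(model, spec) {
  if (is.character(spec)) spec <- parse_variant(spec)
  if (spec$kind != "mutation") stop("spec is not a mutation")
  if (!spec$to_residue %in% names(.residue_formal_charge)) {
    stop("unsupported target residue: ", spec$to_residue)
  }
  atoms <- model$solute$atoms
  rs <- .residue_site(atoms, spec$residue_index)
  current <- unique(atoms$residue_name[rs$rows])[1]
  if (current != spec$from_residue) {
    stop(sprintf("residue %d is %s, not %s", spec$residue_index, current,
                 spec$from_residue))
  }
  dq <- .residue_formal_charge[[spec$to_residue]] -
    .residue_formal_charge[[spec$from_residue]]
  atoms$residue_name[rs$rows] <- spec$to_residue
  atoms$charge[rs$site] <- atoms$charge[rs$site] + dq
  model$solute$atoms <- atoms
  model$solute$label <- paste0(model$solute$label, "/", spec$text)
  model
}

#' Apply a posttranslational modification to a linker-histone model
#'
#' Charge and radius of the modified site are shifted by the PTM table
#' entries and the residue is renamed; the model records the PTM label.
#'
#' @param model an [annotate_lh_elements()] model.
#' @param spec a [parse_variant()] spec (or string) with `kind == "ptm"`.
#' @param table PTM parameter table, by default [ptm_parameter_table()].
#' @return the modified `lh_model`.
#' @export
apply_ptm <- function(model, spec, table = ptm_parameter_table()) {
  if (is.character(spec)) spec <- parse_variant(spec)
  if (spec$kind != "ptm") stop("spec is not a PTM")
  row <- table[table$ptm == spec$ptm_name, ]
  if (nrow(row) != 1) stop("unknown PTM: ", spec$ptm_name)
  atoms <- model$solute$atoms
  rs <- .residue_site(atoms, spec$residue_index)
  current <- unique(atoms$residue_name[rs$rows])[1]
  if (current != row$residue) {
    stop(sprintf("%s requires a %s residue; residue %d is %s",
                 spec$ptm_name, row$residue, spec$residue_index, current))
  }
  atoms$charge[rs$site] <- atoms$charge[rs$site] + row$charge_delta
  atoms$radius[rs$site] <- atoms$radius[rs$site] + row$radius_delta
  atoms$residue_name[rs$rows] <- row$new_name
  model$solute$atoms <- atoms
  model$solute$label <- paste0(model$solute$label, "/", spec$text)
  model$ptms <- c(model$ptms, spec$text)
  model
}

#' Apply a list of variants (mutations and/or PTMs)
#'
#' @param model an `lh_model`.
#' @param variants character vector of variant strings.
#' @param ptm_table PTM parameter table.
#' @return the edited `lh_model`.
#' @export
apply_variants <- function(model, variants, ptm_table = ptm_parameter_table()) {
  for (v in variants) {
    spec <- parse_variant(v)
    model <- if (spec$kind == "mutation") apply_mutation(model, spec)
             else apply_ptm(model, spec, ptm_table)
  }
  model
}
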