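# Covalent radii (Angstrom) for the elements that occur in sulfated
# carbohydrates, aromatic mimetics and proteins. Values are the standard
# single-bond radii used by crystallographic bond-perception heuristics.
.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  NA. = 1.66, MG = 1.41, P = 1.07, S = 1.05, CL = 1.02,
  K = 2.03, CA. = 1.76, FE = 1.32, ZN = 1.22, BR = 1.20, I = 1.39
)

.radius_for <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  r <- .covalent_radii[key]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop_gag("unknown_element",
             paste0("Unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  unname(r)
}

#' Build a molecular topology
#'
#' A topology is the static part of a conformational ensemble: an ordered
#' atom table plus an optional bond list. Atom order defines the meaning of
#' every coordinate array in the package.
#'
#' @param atoms A data frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_id`, and optionally `chain_id` (default `"A"`),
#'   `insertion_code` (default `""`) and `atom_index` (default row number).
#' @param bonds Optional two-column integer matrix (or data frame) of bonded
#'   atom-index pairs (1-based, referring to row order of `atoms`).
#'
#' @return An object of class `gag_topology`: a list with elements `atoms`
#'   (a tibble) and `bonds` (a two-column integer matrix, possibly 0-row).
#' @export
topology <- function(atoms, bonds = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("atom_name", "element", "residue_name", "residue_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop_gag("topology", paste0("atoms is missing column(s): ",
                                paste(missing_cols, collapse = ", ")))
  }
  if (!"chain_id" %in% names(atoms)) atoms$chain_id <- "A"
  if (!"insertion_code" %in% names(atoms)) atoms$insertion_code <- ""
  if (!"atom_index" %in% names(atoms)) atoms$atom_index <- seq_len(nrow(atoms))
  if (any(!nzchar(atoms$element)) || anyNA(atoms$element)) {
    stop_gag("topology", "every atom must carry a non-empty element symbol")
  }
  key <- paste(atoms$chain_id, atoms$residue_id, atoms$insertion_code,
               atoms$atom_name, sep = "|")
  if (anyDuplicated(key)) {
    stop_gag("topology", paste0(
      "duplicate atom identity (chain, residue, insertion code, atom name): ",
      key[duplicated(key)][1]))
  }
  atoms <- atoms[, union(c("atom_index", "atom_name", "element", "residue_name",
                           "residue_id", "chain_id", "insertion_code"),
                         names(atoms))]
  bonds <- normalize_bonds(bonds, nrow(atoms))
  structure(list(atoms = atoms, bonds = bonds), class = "gag_topology")
}

normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || (is.matrix(bonds) && nrow(bonds) == 0) ||
      (is.data.frame(bonds) && nrow(bonds) == 0)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  if (ncol(bonds) != 2) stop_gag("topology", "bonds must have two columns")
  if (any(bonds < 1 | bonds > n_atoms)) {
    stop_gag("topology", "bond indices out of range")
  }
  if (any(bonds[, 1] == bonds[, 2])) stop_gag("topology", "self-bonds are not allowed")
  bonds <- cbind(i = pmin(bonds[, 1], bonds[, 2]),
                 j = pmax(bonds[, 1], bonds[, 2]))
  unique(bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE])
}

#' @export
print.gag_topology <- function(x, ...) {
  cat("<gag_topology> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds, ",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_id))),
      " residues\n", sep = "")
  invisible(x)
}

n_atoms_topology <- function(topology) nrow(topology$atoms)

#' Infer covalent bonds from one frame of coordinates
#'
#' Adds a bond wherever the interatomic distance does not exceed the sum of
#' the two covalent radii plus a 0.4 Angstrom slack, the standard
#' crystallographic heuristic. A hydrogen is bonded to at most one heavy
#' atom; when several qualify the nearest wins.
#'
#' @param topology A [topology()].
#' @param frame An `n_atoms x 3` coordinate matrix (Angstrom).
#' @param tolerance Slack added to the covalent-radii sum (Angstrom).
#' @return The topology with its `bonds` element replaced by the inferred set.
#' @export
infer_bonds <- function(topology, frame, tolerance = 0.4) {
  frame <- as.matrix(frame)
  n <- n_atoms_topology(topology)
  if (nrow(frame) != n || ncol(frame) != 3) {
    stop_gag("topology", "frame must be an n_atoms x 3 coordinate matrix")
  }
  radii <- .radius_for(topology$atoms$element)
  d <- as.matrix(stats::dist(frame))
  cut <- outer(radii, radii, "+") + tolerance
  adj <- d <= cut
  diag(adj) <- FALSE
  is_h <- toupper(topology$atoms$element) == "H"
  # hydrogens: keep only the nearest heavy-atom partner
  for (h in which(is_h)) {
    partners <- which(adj[h, ] & !is_h)
    adj[h, is_h] <- adj[is_h, h] <- FALSE   # no H-H bonds
    if (length(partners) > 1) {
      keep <- partners[which.min(d[h, partners])]
      drop <- setdiff(partners, keep)
      adj[h, drop] <- adj[drop, h] <- FALSE
    }
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  topology$bonds <- normalize_bonds(idx, n)
  topology
}

# residue label in the field's conventional style, e.g. "Lys126"
residue_labels <- function(atoms) {
  rn <- atoms$residue_name
  pretty <- paste0(substr(rn, 1, 1), tolower(substr(rn, 2, nchar(rn))))
  paste0(pretty, atoms$residue_id)
}
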