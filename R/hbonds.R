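#' Geometric hydrogen-bond criteria
#'
#' The standard trajectory-analysis criterion: donor–acceptor distance at
#' most `donor_acceptor_cutoff` and an angular condition at most
#' `angle_cutoff`. Two angle conventions are common and give different
#' bond sets, so the convention in force is carried in every result:
#'
#' * `deviation_from_linearity_DHA` (default): the deviation of the
#'   donor–hydrogen–acceptor angle from 180 degrees must not exceed the
#'   cutoff (60 degrees means angle DHA >= 120 degrees);
#' * `theta_DH_DA`: the angle between the donor-to-hydrogen and
#'   donor-to-acceptor vectors must not exceed the cutoff.
#'
#' @param donor_acceptor_cutoff Distance cutoff in Angstrom (default 3.5).
#' @param angle_cutoff Angle cutoff in degrees (default 60).
#' @param angle_convention Which angular condition to apply.
#' @return A `gag_hbond_criteria` list.
#' @export
hbond_criteria <- function(donor_acceptor_cutoff = 3.5, angle_cutoff = 60,
                           angle_convention = c("deviation_from_linearity_DHA",
                                                "theta_DH_DA")) {
  if (donor_acceptor_cutoff <= 0) stop_gag("params", "distance cutoff must be > 0")
  if (angle_cutoff <= 0 || angle_cutoff > 180) {
    stop_gag("params", "angle cutoff must lie in (0, 180]")
  }
  structure(list(donor_acceptor_cutoff = donor_acceptor_cutoff,
                 angle_cutoff = angle_cutoff,
                 angle_convention = match.arg(angle_convention)),
            class = "gag_hbond_criteria")
}

#' Identify hydrogen-bond donors and acceptors in a topology
#'
#' Donors are N, O or S atoms with at least one bonded hydrogen; acceptors
#' are all N, O or S atoms (so sulfate and phenolate oxygens qualify). An
#' atom may be both. Bond information must be present — read from CONECT
#' records or produced by [infer_bonds()].
#'
#' @param topology A [topology()] with bonds.
#' @return A list: `donors` (tibble `donor`, `hydrogen` — one row per
#'   donor–hydrogen pair) and `acceptors` (integer atom indices).
#' @export
assign_donors_acceptors <- function(topology) {
  if (nrow(topology$bonds) == 0) {
    stop_gag("missing_bonds",
             "topology has no bonds; run infer_bonds() or supply CONECT records")
  }
  el <- toupper(topology$atoms$element)
  polar <- which(el %in% c("N", "O", "S"))
  b <- topology$bonds
  pairs <- rbind(b, b[, 2:1, drop = FALSE])
  is_h <- el[pairs[, 2]] == "H"
  dh <- pairs[is_h & pairs[, 1] %in% polar, , drop = FALSE]
  list(
    donors = tibble(donor = as.integer(dh[, 1]), hydrogen = as.integer(dh[, 2])),
    acceptors = polar
  )
}

#' Detect intermolecular hydrogen bonds in one frame
#'
#' Only bonds crossing the ligand/receptor partition are reported (donor on
#' one side, acceptor on the other); each (donor, hydrogen, acceptor)
#' triple appears at most once per frame.
#'
#' @param frame An `n_atoms x 3` coordinate matrix.
#' @param topology The matching [topology()] with bonds.
#' @param ligand,receptor Disjoint integer atom-index sets.
#' @param criteria A [hbond_criteria()].
#' @return A tibble: `donor`, `hydrogen`, `acceptor`, `distance` (Angstrom,
#'   donor–acceptor), `angle` (degrees, in the convention used),
#'   `donor_side`.
#' @export
detect_hbonds_frame <- function(frame, topology, ligand, receptor,
                                criteria = hbond_criteria()) {
  if (length(intersect(ligand, receptor)) > 0) {
    stop_gag("selection_overlap", "ligand and receptor atom sets overlap")
  }
  da <- assign_donors_acceptors(topology)
  if (nrow(da$donors) == 0) {
    stop_gag("no_hydrogens", paste0(
      "no donor hydrogens in the topology; the geometric criterion needs ",
      "explicit hydrogen positions"))
  }
  frame <- as.matrix(frame)
  side <- function(idx) ifelse(idx %in% ligand, "ligand",
                               ifelse(idx %in% receptor, "receptor", NA))
  out <- list()
  for (donor_side in c("ligand", "receptor")) {
    acc_side <- setdiff(c("ligand", "receptor"), donor_side)
    dn <- da$donors[side(da$donors$donor) %in% donor_side, , drop = FALSE]
    ac <- da$acceptors[side(da$acceptors) %in% acc_side]
    if (nrow(dn) == 0 || length(ac) == 0) next
    grid <- expand.grid(pair = seq_len(nrow(dn)), acceptor = ac)
    D <- dn$donor[grid$pair]; H <- dn$hydrogen[grid$pair]; A <- grid$acceptor
    keep <- D != A
    D <- D[keep]; H <- H[keep]; A <- A[keep]
    if (length(D) == 0) next
    dist_da <- sqrt(rowSums((frame[D, , drop = FALSE] - frame[A, , drop = FALSE])^2))
    near <- dist_da <= criteria$donor_acceptor_cutoff
    if (!any(near)) next
    D <- D[near]; H <- H[near]; A <- A[near]; dist_da <- dist_da[near]
    if (criteria$angle_convention == "deviation_from_linearity_DHA") {
      v1 <- frame[D, , drop = FALSE] - frame[H, , drop = FALSE]
      v2 <- frame[A, , drop = FALSE] - frame[H, , drop = FALSE]
      ang <- vector_angle(v1, v2)                 # angle DHA at the hydrogen
      pass <- (180 - ang) <= criteria$angle_cutoff
    } else {
      v1 <- frame[H, , drop = FALSE] - frame[D, , drop = FALSE]
      v2 <- frame[A, , drop = FALSE] - frame[D, , drop = FALSE]
      ang <- vector_angle(v1, v2)
      pass <- ang <= criteria$angle_cutoff
    }
    if (!any(pass)) next
    out[[length(out) + 1]] <- tibble(
      donor = D[pass], hydrogen = H[pass], acceptor = A[pass],
      distance = unname(dist_da[pass]), angle = unname(ang[pass]),
      donor_side = donor_side)
  }
  if (length(out) == 0) {
    return(tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
                  distance = numeric(), angle = numeric(), donor_side = character()))
  }
  res <- bind_rows(out)
  res[!duplicated(res[, c("donor", "hydrogen", "acceptor")]), , drop = FALSE]
}

vector_angle <- function(v1, v2) {
  num <- rowSums(v1 * v2)
  den <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  cosang <- pmin(1, pmax(-1, num / den))
  acos(cosang) * 180 / pi
}

#' Residue-level hydrogen-bond occupancy over an analysis window
#'
#' A receptor residue is "incident" in a frame when at least one
#' intermolecular hydrogen bond involves any of its atoms; its occupancy is
#' the percentage of window frames in which it is incident — the proportion
#' of time the residue is hydrogen-bonded to the ligand. Residues that are
#' never incident are omitted (no zero rows). The default window is the
#' final half of the trajectory, where a bound complex has typically
#' settled.
#'
#' @param ensemble A `gag_ensemble` of the complex.
#' @param ligand,receptor Disjoint atom-index sets; occupancies are
#'   aggregated over the residues of `receptor`.
#' @param criteria A [hbond_criteria()].
#' @param window A [frame_window()], or `NULL` for the final 50% of frames.
#' @return A `gag_occupancy` tibble: `residue`, `chain_id`, `residue_id`,
#'   `occupancy` (percent), `n_frames_observed`, `n_frames_window`; the
#'   per-frame residue incidence table (long form) is attached as attribute
#'   `incidence`, the criteria and window as attributes `criteria`,
#'   `window`.
#' @export
occupancy_table <- function(ensemble, ligand, receptor,
                            criteria = hbond_criteria(), window = NULL) {
  if (is.null(window)) {
    times <- ensemble$times
    halfway <- times[1] + (times[length(times)] - times[1]) / 2
    spacing <- if (length(times) > 1) min(diff(times)) else 1
    window <- frame_window(halfway, times[length(times)], spacing)
  }
  sub <- select_frames(ensemble, window)
  nf <- n_frames(sub)
  at <- sub$topology$atoms
  res_key <- paste(at$chain_id, at$residue_id, at$insertion_code, sep = "|")
  res_label <- residue_labels(at)
  incident <- list()
  for (i in seq_len(nf)) {
    hb <- detect_hbonds_frame(frame_coords(sub, i), sub$topology,
                              ligand, receptor, criteria)
    if (nrow(hb) == 0) next
    atoms_involved <- unique(c(hb$donor, hb$hydrogen, hb$acceptor))
    atoms_involved <- intersect(atoms_involved, receptor)
    if (length(atoms_involved) == 0) next
    incident[[length(incident) + 1]] <- tibble(
      frame = i, residue_key = unique(res_key[atoms_involved]))
  }
  inc <- if (length(incident) > 0) bind_rows(incident) else {
    tibble(frame = integer(), residue_key = character())
  }
  occ <- inc |>
    dplyr::count(.data$residue_key, name = "n_frames_observed") |>
    mutate(occupancy = 100 * .data$n_frames_observed / nf)
  meta <- tibble(residue_key = res_key, residue = res_label,
                 chain_id = at$chain_id, residue_id = at$residue_id)
  meta <- meta[!duplicated(meta$residue_key), , drop = FALSE]
  out <- occ |>
    left_join(meta, by = "residue_key") |>
    arrange(.data$chain_id, .data$residue_id) |>
    select("residue", "chain_id", "residue_id", "occupancy",
           "n_frames_observed")
  out$n_frames_window <- nf
  out <- as_tibble(out)
  class(out) <- c("gag_occupancy", class(out))
  attr(out, "incidence") <- inc |>
    left_join(meta, by = "residue_key") |>
    select("frame", "residue")
  attr(out, "criteria") <- criteria
  attr(out, "window") <- window
  out
}
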