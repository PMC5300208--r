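#' Build a conformational ensemble
#'
#' The universal container of the package: a topology plus a
#' `frames x atoms x 3` coordinate array in Angstrom, with a strictly
#' increasing per-frame time stamp in picoseconds. Time stamps default to
#' 0, 1, 2, ... ps, the 1 ps save cadence typical of explicit-solvent
#' production runs.
#'
#' @param topology A [topology()].
#' @param coords A `frames x atoms x 3` numeric array, or an `atoms x 3`
#'   matrix for a single frame.
#' @param times Optional numeric vector of frame times (ps), strictly
#'   increasing, one per frame.
#' @return An object of class `gag_ensemble`.
#' @export
conformer_ensemble <- function(topology, coords, times = NULL) {
  if (!inherits(topology, "gag_topology")) {
    stop_gag("ensemble", "topology must be a gag_topology")
  }
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop_gag("ensemble", "coords must be a frames x atoms x 3 array")
  }
  if (dim(coords)[2] != n_atoms_topology(topology)) {
    stop_gag("ensemble", sprintf(
      "coords has %d atoms but topology has %d",
      dim(coords)[2], n_atoms_topology(topology)))
  }
  if (!all(is.finite(coords))) stop_gag("ensemble", "non-finite coordinates")
  n_fr <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(n_fr) - 1)
  if (length(times) != n_fr) {
    stop_gag("ensemble", "length(times) must equal the number of frames")
  }
  if (n_fr > 1 && any(diff(times) <= 0)) {
    stop_gag("ensemble", "times must be strictly increasing")
  }
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "gag_ensemble")
}

#' @export
print.gag_ensemble <- function(x, ...) {
  cat("<gag_ensemble> ", n_frames(x), " frames x ", n_atoms(x), " atoms",
      sprintf(" | t = %g..%g ps\n", x$times[1], x$times[n_frames(x)]), sep = "")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble A `gag_ensemble`.
#' @return An integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[2]

#' Extract one frame as an atoms x 3 matrix
#' @param ensemble A `gag_ensemble`.
#' @param i Frame index (1-based).
#' @return An `n_atoms x 3` numeric matrix (Angstrom).
#' @export
frame_coords <- function(ensemble, i) {
  if (i < 1 || i > n_frames(ensemble)) stop_gag("index", "frame index out of range")
  matrix(ensemble$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Define a time window over a trajectory
#'
#' Frames are retained when their time lies in the half-open interval
#' `(start_time, end_time]` and falls on the stride grid anchored at
#' `start_time`. With this convention a 20 ns run saved every 1 ps,
#' windowed over (10 ns, 20 ns] at a 10 ps stride, keeps exactly 1000
#' frames.
#'
#' @param start_time,end_time Window bounds in ps, `start_time < end_time`.
#' @param stride Sampling interval in ps, `> 0`.
#' @return A `gag_frame_window` object.
#' @export
frame_window <- function(start_time, end_time, stride) {
  if (!(start_time < end_time)) stop_gag("window", "start_time must be < end_time")
  if (!(stride > 0)) stop_gag("window", "stride must be > 0")
  structure(list(start_time = start_time, end_time = end_time, stride = stride),
            class = "gag_frame_window")
}

#' Subsample frames of an ensemble by time window and stride
#'
#' @param ensemble A `gag_ensemble`.
#' @param window A [frame_window()].
#' @return A `gag_ensemble` restricted to the selected frames.
#' @export
select_frames <- function(ensemble, window) {
  stopifnot(inherits(window, "gag_frame_window"))
  times <- ensemble$times
  if (window$start_time >= times[length(times)] || window$end_time <= times[1]) {
    stop_gag("empty_window", sprintf(
      "window (%g, %g] ps lies outside the trajectory span [%g, %g] ps",
      window$start_time, window$end_time, times[1], times[length(times)]))
  }
  if (length(times) > 1) {
    spacing <- min(diff(times))
    ratio <- window$stride / spacing
    if (abs(ratio - round(ratio)) > 1e-8 || round(ratio) < 1) {
      stop_gag("stride", sprintf(
        "stride %g ps is not an integer multiple of the frame spacing %g ps",
        window$stride, spacing))
    }
  }
  phase <- (times - window$start_time) / window$stride
  keep <- times > window$start_time & times <= window$end_time &
    abs(phase - round(phase)) < 1e-8
  if (!any(keep)) {
    stop_gag("empty_window", "no frames fall inside the window at this stride")
  }
  conformer_ensemble(ensemble$topology,
                     ensemble$coords[keep, , , drop = FALSE],
                     ensemble$times[keep])
}

#' Select a subset of atoms by predicate
#'
#' The predicate is evaluated in the atom table, so any of its columns
#' (`element`, `residue_name`, `residue_id`, `chain_id`, `atom_name`, ...)
#' may be referenced. Atom order is preserved; frames are untouched. An
#' empty result is an explicit error, never a silent 0-atom ensemble.
#'
#' @param ensemble A `gag_ensemble`.
#' @param predicate An unquoted logical expression over atom-table columns,
#'   e.g. `element != "H"` or `chain_id == "A"`.
#' @return A `gag_ensemble` over the matching atoms.
#' @export
#' @examples
#' ens <- generate_chain_ensemble(8, 3, 6, 0.5, seed = 1)$ensemble
#' heavy <- select_atoms(ens, element != "H")
select_atoms <- function(ensemble, predicate) {
  pred <- rlang::enquo(predicate)
  keep <- rlang::eval_tidy(pred, data = ensemble$topology$atoms)
  if (!is.logical(keep) || length(keep) != n_atoms(ensemble)) {
    stop_gag("selection", "predicate must yield one logical per atom")
  }
  keep[is.na(keep)] <- FALSE
  subset_atoms(ensemble, which(keep))
}

# index-based core shared by select_atoms and internal callers
subset_atoms <- function(ensemble, idx) {
  if (length(idx) == 0) {
    stop_gag("empty_selection", "atom selection matched no atoms")
  }
  top <- ensemble$topology
  remap <- match(seq_len(n_atoms(ensemble)), idx)
  bonds <- top$bonds
  if (nrow(bonds) > 0) {
    bi <- remap[bonds[, 1]]; bj <- remap[bonds[, 2]]
    ok <- !is.na(bi) & !is.na(bj)
    bonds <- cbind(i = bi[ok], j = bj[ok])
  }
  new_top <- topology(top$atoms[idx, , drop = FALSE], bonds)
  conformer_ensemble(new_top, ensemble$coords[, idx, , drop = FALSE], ensemble$times)
}

# default analysis selection: heavy atoms
heavy_atom_indices <- function(ensemble) {
  which(toupper(ensemble$topology$atoms$element) != "H")
}

#' Long-format coordinate table of an ensemble
#'
#' @param x A `gag_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `time_ps`, `atom_index`, `x`, `y`, `z`.
#' @method as_tibble gag_ensemble
#' @export
as_tibble.gag_ensemble <- function(x, ...) {
  nf <- n_frames(x); na <- n_atoms(x)
  col <- function(k) as.vector(t(matrix(x$coords[, , k], nrow = nf, ncol = na)))
  xs <- col(1); ys <- col(2); zs <- col(3)
  tibble(
    frame = rep(seq_len(nf), each = na),
    time_ps = rep(x$times, each = na),
    atom_index = rep(x$topology$atoms$atom_index, times = nf),
    x = xs, y = ys, z = zs
  )
}
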