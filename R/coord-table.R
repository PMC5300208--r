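#' Read a plain coordinate table as an ensemble
#'
#' The table format is a CSV with header `frame,atom_index,x,y,z`
#' (coordinates in Angstrom). Every (frame, atom) pair must appear exactly
#' once; atoms are matched to the supplied topology by `atom_index`. An
#' optional `time_ps` column carries frame times.
#'
#' @param path Path to the CSV file.
#' @param topology A [topology()] describing the atoms.
#' @return A `gag_ensemble`.
#' @export
read_coord_table <- function(path, topology) {
  if (!file.exists(path)) stop_gag("io", paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("frame", "atom_index", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_gag("parse", paste0("coordinate table missing column(s): ",
                             paste(missing_cols, collapse = ", ")))
  }
  frames <- sort(unique(df$frame))
  idx <- topology$atoms$atom_index
  n_at <- length(idx)
  key <- paste(df$frame, df$atom_index)
  if (anyDuplicated(key)) {
    stop_gag("duplicate", paste0("duplicate (frame, atom) pair: ",
                                 key[duplicated(key)][1]))
  }
  if (nrow(df) != length(frames) * n_at ||
      !all(df$atom_index %in% idx)) {
    expected <- paste(rep(frames, each = n_at), rep(idx, length(frames)))
    miss <- setdiff(expected, key)
    if (length(miss) > 0) {
      stop_gag("incomplete_table", paste0(
        "coordinate table is missing (frame, atom) pair(s), first: ", miss[1]))
    }
    stop_gag("incomplete_table", "coordinate table atoms do not match topology")
  }
  df <- df[order(df$frame, match(df$atom_index, idx)), , drop = FALSE]
  coords <- array(NA_real_, dim = c(length(frames), n_at, 3))
  coords[, , 1] <- matrix(df$x, nrow = length(frames), byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nrow = length(frames), byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nrow = length(frames), byrow = TRUE)
  times <- if ("time_ps" %in% names(df)) {
    unique(df[, c("frame", "time_ps")])$time_ps
  } else NULL
  conformer_ensemble(topology, coords, times)
}

#' Write an ensemble as a plain coordinate table
#'
#' Full double precision is preserved, so a write-then-read round trip
#' reproduces the coordinates exactly.
#'
#' @param ensemble A `gag_ensemble`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_coord_table <- function(ensemble, path) {
  readr::write_csv(as_tibble(ensemble), path, progress = FALSE)
  invisible(path)
}
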