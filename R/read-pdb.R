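#' Read a (multi-model) PDB file as a conformational ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame ensemble. Atom order, names and counts must
#' be identical across models. `CONECT` records, when present, populate the
#' bond list; otherwise call [infer_bonds()]. Alternate locations keep the
#' first altloc seen for each atom identity (a warning is issued).
#'
#' The parser is deliberately line-oriented so that malformed input is
#' reported with the model number or line at fault, which generic readers
#' do not surface.
#'
#' @param path Path to a PDB file.
#' @param times Optional frame times (ps); default 0, 1, 2, ... ps.
#' @return A `gag_ensemble`.
#' @export
read_multimodel_pdb <- function(path, times = NULL) {
  if (!file.exists(path)) stop_gag("io", paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop_gag("parse", "no ATOM/HETATM records found")

  # assign a model id to every line
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L

  atom_lines <- which(is_atom)
  df <- parse_atom_lines(lines[atom_lines], atom_lines)
  df$model <- model_id[atom_lines]

  # altloc: keep first alternate location per (model, chain, resid, icode, name)
  if (any(df$altloc != "")) {
    key <- paste(df$model, df$chain_id, df$residue_id, df$insertion_code,
                 df$atom_name, sep = "|")
    dup <- duplicated(key)
    if (any(dup)) {
      rlang::warn(sprintf(
        "dropping %d alternate-location atom records (keeping the first altloc)",
        sum(dup)))
      df <- df[!dup, , drop = FALSE]
    }
  }

  models <- split(df, df$model)
  ref <- models[[1]]
  n_at <- nrow(ref)
  for (m in seq_along(models)) {
    cur <- models[[m]]
    if (nrow(cur) != n_at) {
      stop_gag("malformed_ensemble", sprintf(
        "model %s has %d atoms but model %s has %d",
        names(models)[m], nrow(cur), names(models)[1], n_at))
    }
    if (!identical(cur$atom_name, ref$atom_name)) {
      stop_gag("malformed_ensemble", sprintf(
        "model %s atom names differ from model %s", names(models)[m], names(models)[1]))
    }
  }

  coords <- array(NA_real_, dim = c(length(models), n_at, 3))
  for (m in seq_along(models)) {
    coords[m, , ] <- as.matrix(models[[m]][, c("x", "y", "z")])
  }

  atoms <- tibble(
    atom_index = seq_len(n_at),
    atom_name = ref$atom_name, element = ref$element,
    residue_name = ref$residue_name, residue_id = ref$residue_id,
    chain_id = ref$chain_id, insertion_code = ref$insertion_code
  )
  bonds <- parse_conect(lines[startsWith(rec, "CONECT")], ref$serial, n_at)
  conformer_ensemble(topology(atoms, bonds), coords, times)
}

parse_atom_lines <- function(lines, line_numbers) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  lines <- vapply(lines, pad, "", n = 80, USE.NAMES = FALSE)
  num <- function(from, to, what) {
    txt <- trimws(substr(lines, from, to))
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) | !nzchar(txt))
    if (length(bad) > 0) {
      stop_gag("parse", sprintf("unreadable %s field at line %d",
                                what, line_numbers[bad[1]]))
    }
    val
  }
  name <- trimws(substr(lines, 13, 16))
  element <- trimws(substr(lines, 77, 78))
  element <- ifelse(nzchar(element), element, guess_element(name))
  data.frame(
    serial = num(7, 11, "atom serial"),
    atom_name = name,
    altloc = trimws(substr(lines, 17, 17)),
    residue_name = trimws(substr(lines, 18, 21)),
    chain_id = trimws(substr(lines, 22, 22)),
    residue_id = as.integer(num(23, 26, "residue number")),
    insertion_code = trimws(substr(lines, 27, 27)),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    element = element,
    stringsAsFactors = FALSE
  )
}

guess_element <- function(atom_name) {
  two <- c("CL", "BR", "NA", "MG", "FE", "ZN", "CA")
  up <- toupper(atom_name)
  # strip leading digits (e.g. "1HB"), then try 2- and 1-letter symbols
  core <- sub("^[0-9]+", "", up)
  first2 <- substr(core, 1, 2)
  first1 <- substr(core, 1, 1)
  ifelse(first2 %in% two & nchar(core) == nchar(atom_name), first2, first1)
}

parse_conect <- function(lines, serials, n_atoms) {
  if (length(lines) == 0) return(NULL)
  out <- list()
  for (ln in lines) {
    flds <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, 80)), "\\s+")[[1]]))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 2) next
    a <- match(flds[1], serials)
    b <- match(flds[-1], serials)
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) out[[length(out) + 1]] <- cbind(a, b[ok])
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at the format's fixed precision (0.001 Angstrom);
#' a read-back therefore reproduces them to 3 decimals.
#'
#' @param ensemble A `gag_ensemble`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  at <- ensemble$topology$atoms
  nf <- n_frames(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frame_coords(ensemble, m)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$atom_index %% 100000, format_atom_name(at$atom_name),
      substr(at$residue_name, 1, 4), substr(at$chain_id, 1, 1),
      at$residue_id %% 10000, substr(at$insertion_code, 1, 1),
      xyz[, 1], xyz[, 2], xyz[, 3], toupper(at$element)), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  if (nrow(ensemble$topology$bonds) > 0) {
    b <- ensemble$topology$bonds
    writeLines(sprintf("CONECT%5d%5d", b[, 1], b[, 2]), con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_name <- function(name) {
  # names up to 3 characters start in column 14 per PDB convention
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         paste0(" ", formatC(name, width = -3)))
}
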