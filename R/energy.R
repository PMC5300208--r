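#' Read a per-residue binding-energy decomposition table
#'
#' Ingests the per-residue output of an end-point binding free-energy
#' calculation (e.g. an MM/GBSA single-residue decomposition): a CSV with
#' columns `residue,mean,sd` in kcal/mol and a mandatory `TOTAL` row giving
#' the overall binding free energy and its standard deviation. The package
#' never computes these energies; it only ingests and compares them.
#'
#' @param path Path to the CSV file.
#' @param label Label attached to the table (e.g. the complex name).
#' @return A `gag_energy_decomposition` tibble (`residue`, `mean`, `sd`)
#'   with attributes `total_dg_mean`, `total_dg_sd`, `label`.
#' @export
read_energy_table <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop_gag("io", paste0("file not found: ", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_gag("parse", paste0("cannot parse energy table: ",
                                                 conditionMessage(e))))
  if (nrow(df) == 0 || !all(c("residue", "mean", "sd") %in% names(df))) {
    stop_gag("parse", "energy table needs columns residue,mean,sd and at least one row")
  }
  is_total <- toupper(trimws(df$residue)) == "TOTAL"
  if (!any(is_total)) {
    stop_gag("missing_total", "energy table has no TOTAL row")
  }
  total <- df[is_total, , drop = FALSE][1, ]
  body <- df[!is_total, , drop = FALSE]
  if (anyDuplicated(body$residue)) {
    stop_gag("duplicate", paste0("residue listed twice: ",
                                 body$residue[duplicated(body$residue)][1]))
  }
  if (any(body$sd < 0, na.rm = TRUE)) stop_gag("parse", "negative sd in energy table")
  new_energy_decomposition(body[, c("residue", "mean", "sd")],
                           total$mean, total$sd, label)
}

new_energy_decomposition <- function(body, total_mean, total_sd, label) {
  out <- as_tibble(body)
  class(out) <- c("gag_energy_decomposition", class(out))
  attr(out, "total_dg_mean") <- as.numeric(total_mean)
  attr(out, "total_dg_sd") <- as.numeric(total_sd)
  attr(out, "label") <- label
  out
}

#' Write an energy decomposition in the table format read_energy_table expects
#' @param energy A `gag_energy_decomposition`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_energy_table <- function(energy, path) {
  df <- rbind(
    data.frame(residue = energy$residue, mean = energy$mean, sd = energy$sd),
    data.frame(residue = "TOTAL", mean = attr(energy, "total_dg_mean"),
               sd = attr(energy, "total_dg_sd")))
  # fixed formatting so identical inputs give byte-identical files
  lines <- c("residue,mean,sd",
             sprintf("%s,%.6f,%.6f", df$residue, df$mean, df$sd))
  writeLines(lines, path)
  invisible(path)
}

#' Rank residues by binding-energy contribution
#'
#' Residues are ordered by most negative (most favourable) mean
#' contribution; ties break deterministically by residue identifier.
#'
#' @param table A `gag_energy_decomposition`.
#' @param k How many residues to return; more than available returns all.
#' @return A tibble of the top `k` rows with a `rank` column.
#' @export
dominant_residues <- function(table, k = 3) {
  if (k < 1) stop_gag("params", "k must be >= 1")
  ranked <- table |>
    as_tibble() |>
    arrange(.data$mean, .data$residue) |>
    head(k)
  ranked$rank <- seq_len(nrow(ranked))
  ranked[, c("rank", "residue", "mean", "sd")]
}

#' Total binding free-energy interval of a decomposition
#' @param energy A `gag_energy_decomposition`.
#' @return A named numeric vector `c(mean, sd)` in kcal/mol.
#' @export
total_dg <- function(energy) {
  c(mean = attr(energy, "total_dg_mean"), sd = attr(energy, "total_dg_sd"))
}
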