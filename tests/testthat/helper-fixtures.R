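# helper: fabricate a one-row summary directly from its statistics
make_summary <- function(metric, q1, q3, mean, sd, n = 100,
                         min = q1 - 1, median = (q1 + q3) / 2, max = q3 + 1) {
  out <- tibble::tibble(metric = metric, n = n, min = min, q1 = q1,
                        median = median, q3 = q3, max = max, mean = mean, sd = sd)
  class(out) <- c("gag_summary", class(out))
  out
}

# fabricated result objects used by the verdict and ranking tests
make_occupancy <- function(residues, occ) {
  out <- tibble::tibble(residue = residues, chain_id = "A",
                        residue_id = seq_along(residues), occupancy = occ,
                        n_frames_observed = round(occ * 10),
                        n_frames_window = 1000)
  class(out) <- c("gag_occupancy", class(out))
  out
}

make_energy <- function(residues, means, total_mean, total_sd) {
  gagmimic:::new_energy_decomposition(
    tibble::tibble(residue = residues, mean = means, sd = 1),
    total_mean, total_sd, "test")
}
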