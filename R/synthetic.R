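#' Seeded synthetic flexible-chain ensemble with a planted end-to-end
#' distance distribution
#'
#' A freely jointed chain of 1.5-Angstrom links is regrown every frame and
#' uniformly rescaled so that the terminal-atom distance equals a draw from
#' `Normal(target_eed_mean, target_eed_sd)` truncated to
#' `(0, contour length)`. The model reproduces the one statistical feature
#' the free-state comparison consumes — a unimodal end-to-end-distance
#' distribution of known mean and spread — with no force-field realism.
#'
#' @param n_atoms Chain length (`>= 4`).
#' @param n_frames Number of frames (`>= 1`).
#' @param target_eed_mean,target_eed_sd Planted EED distribution (Angstrom);
#'   the mean must lie below the contour length `1.5 * (n_atoms - 1)`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return A list: `ensemble` (a `gag_ensemble`, first and last atom are
#'   the endpoints) and `truth` (generator name, seed, parameters and the
#'   drawn per-frame EED values).
#' @export
generate_chain_ensemble <- function(n_atoms, n_frames, target_eed_mean,
                                    target_eed_sd, seed = 1L) {
  if (n_atoms < 4) stop_gag("params", "n_atoms must be >= 4")
  if (n_frames < 1) stop_gag("params", "n_frames must be >= 1")
  if (target_eed_sd < 0) stop_gag("params", "target_eed_sd must be >= 0")
  contour <- 1.5 * (n_atoms - 1)
  if (target_eed_mean >= contour) {
    stop_gag("infeasible", sprintf(
      "target mean %.3g A is not below the contour length %.3g A",
      target_eed_mean, contour))
  }
  set.seed(seed)
  drawn <- numeric(n_frames)
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    repeat {                               # truncated-normal draw by rejection
      eed <- stats::rnorm(1, target_eed_mean, target_eed_sd)
      if (eed > 0 && eed < contour) break
    }
    drawn[f] <- eed
    repeat {                               # regrow until endpoints are usable
      steps <- matrix(stats::rnorm(3 * (n_atoms - 1)), ncol = 3)
      steps <- 1.5 * steps / sqrt(rowSums(steps^2))
      chain <- rbind(0, apply(steps, 2, cumsum))
      raw_eed <- sqrt(sum(chain[n_atoms, ]^2))
      if (raw_eed > 1e-6) break
    }
    coords[f, , ] <- chain * (eed / raw_eed)
  }
  atoms <- tibble(atom_name = paste0("C", seq_len(n_atoms)), element = "C",
                  residue_name = "CHN", residue_id = 1L)
  bonds <- cbind(seq_len(n_atoms - 1), seq_len(n_atoms - 1) + 1L)
  list(
    ensemble = conformer_ensemble(topology(atoms, bonds), coords),
    truth = list(generator = "chain_ensemble", seed = seed,
                 n_atoms = n_atoms, n_frames = n_frames,
                 target_eed_mean = target_eed_mean,
                 target_eed_sd = target_eed_sd, drawn_eed = drawn))
}

#' Seeded mixture of discrete conformers with Gaussian jitter
#'
#' Ground truth for clustering: each frame is one of `k` template
#' structures chosen multinomially by weight, plus i.i.d. Gaussian jitter
#' on every coordinate. The frame-to-template labels are recorded, so
#' recovery can be asserted against the planted truth rather than
#' re-derived.
#'
#' @param templates List of `n_atoms x 3` matrices sharing one topology
#'   (equal atom counts).
#' @param weights Non-negative mixture weights, not all zero.
#' @param jitter_sd Per-coordinate Gaussian jitter (Angstrom).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A list: `ensemble` and `truth` (with `labels`, the planted
#'   frame-to-template assignment).
#' @export
generate_conformer_mixture <- function(templates, weights, jitter_sd,
                                       n_frames, seed = 1L) {
  k <- length(templates)
  templates <- lapply(templates, as.matrix)
  dims <- vapply(templates, nrow, integer(1))
  if (k < 1 || length(unique(dims)) != 1) {
    stop_gag("topology", "templates must share one topology (equal atom counts)")
  }
  if (length(weights) != k || any(weights < 0) || sum(weights) == 0) {
    stop_gag("params", "weights must be non-negative and not all zero")
  }
  n_at <- dims[1]
  set.seed(seed)
  labels <- sample.int(k, n_frames, replace = TRUE, prob = weights / sum(weights))
  coords <- array(NA_real_, dim = c(n_frames, n_at, 3))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- templates[[labels[f]]] +
      matrix(stats::rnorm(3 * n_at, 0, jitter_sd), ncol = 3)
  }
  atoms <- tibble(atom_name = paste0("C", seq_len(n_at)), element = "C",
                  residue_name = "MIX", residue_id = 1L)
  list(
    ensemble = conformer_ensemble(topology(atoms), coords),
    truth = list(generator = "conformer_mixture", seed = seed, k = k,
                 weights = weights, jitter_sd = jitter_sd, labels = labels))
}

#' Seeded receptor-ligand complex with planted hydrogen-bond occupancies
#'
#' Each receptor residue carries one amide-like donor (N-H); the ligand
#' carries one acceptor oxygen per residue. Per frame and residue, with the
#' planted probability the acceptor is placed in ideal bonding geometry
#' (donor-acceptor 2.9 Angstrom, linear N-H...O); otherwise it is displaced
#' to 5 Angstrom, outside any reasonable cutoff. The realized per-frame
#' incidence matrix is recorded as ground truth.
#'
#' @param receptor_residues Number of receptor residues.
#' @param bond_probabilities Per-residue bond probability in `[0, 1]`
#'   (recycled to `receptor_residues`).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A list: `ensemble` (receptor chain `"A"`, ligand chain `"L"`),
#'   `ligand`/`receptor` atom-index sets, and `truth` (with `incidence`, a
#'   frames x residues logical matrix).
#' @export
generate_complex_with_hbonds <- function(receptor_residues, bond_probabilities,
                                         n_frames, seed = 1L) {
  p <- rep_len(bond_probabilities, receptor_residues)
  if (any(p < 0 | p > 1)) stop_gag("params", "probabilities must lie in [0, 1]")
  nr <- receptor_residues
  # atoms: per residue CA, N, H (receptor) then per residue O, C (ligand)
  rec <- do.call(rbind, lapply(seq_len(nr), function(i) {
    tibble(atom_name = c("CA", "N", "H"), element = c("C", "N", "H"),
           residue_name = "RES", residue_id = i, chain_id = "A")
  }))
  lig <- do.call(rbind, lapply(seq_len(nr), function(i) {
    tibble(atom_name = c(paste0("O", i), paste0("C", i)), element = c("O", "C"),
           residue_name = "LIG", residue_id = 1L, chain_id = "L")
  }))
  atoms <- bind_rows(rec, lig)
  n_rec <- 3 * nr
  rec_idx <- function(i, at) (i - 1) * 3 + at          # CA=1, N=2, H=3
  lig_idx <- function(i, at) n_rec + (i - 1) * 2 + at  # O=1, C=2
  bonds <- rbind(
    do.call(rbind, lapply(seq_len(nr), function(i) {
      rbind(c(rec_idx(i, 1), rec_idx(i, 2)), c(rec_idx(i, 2), rec_idx(i, 3)))
    })),
    do.call(rbind, lapply(seq_len(nr), function(i) {
      c(lig_idx(i, 1), lig_idx(i, 2))
    })))
  top <- topology(atoms, bonds)

  set.seed(seed)
  incidence <- matrix(stats::runif(n_frames * nr) < rep(p, each = n_frames),
                      nrow = n_frames)
  coords <- array(NA_real_, dim = c(n_frames, nrow(atoms), 3))
  for (f in seq_len(n_frames)) {
    xyz <- matrix(0, nrow(atoms), 3)
    for (i in seq_len(nr)) {
      base <- c(10 * (i - 1), 0, 0)
      xyz[rec_idx(i, 1), ] <- base + c(0, -1.5, 0)     # CA
      xyz[rec_idx(i, 2), ] <- base                     # N (donor)
      xyz[rec_idx(i, 3), ] <- base + c(0, 1.0, 0)      # H, along the bond axis
      d_oa <- if (incidence[f, i]) 2.9 else 5.0
      xyz[lig_idx(i, 1), ] <- base + c(0, d_oa, 0)     # acceptor O, linear N-H...O
      xyz[lig_idx(i, 2), ] <- base + c(1.4, d_oa, 0)   # ligand C
    }
    coords[f, , ] <- xyz
  }
  list(
    ensemble = conformer_ensemble(top, coords),
    receptor = seq_len(n_rec),
    ligand = n_rec + seq_len(2 * nr),
    truth = list(generator = "complex_with_hbonds", seed = seed,
                 bond_probabilities = p, incidence = incidence))
}

#' Seeded per-residue energy decomposition with a planted dominant residue
#'
#' Background residues receive means around -3 kcal/mol; the dominant
#' residue's mean is set `gap` kcal/mol more negative than the most
#' negative background residue. With `noise_sd = 0` (the default) the
#' planted structure holds exactly; a positive `noise_sd` adds observation
#' noise to the reported means, emulating the frame-to-frame scatter of an
#' end-point energy estimate, and can flip the apparent top residue when
#' the gap is small relative to the noise.
#'
#' @param residues Character vector of residue identifiers.
#' @param dominant_residue One of `residues`.
#' @param gap Planted margin (kcal/mol, `> 0`).
#' @param seed Integer seed.
#' @param noise_sd Observation noise on the reported means (kcal/mol).
#' @param path Optional path; when given the table is also written with
#'   [write_energy_table()] (same seed, byte-identical file).
#' @return A list: `energy` (a `gag_energy_decomposition`) and `truth`.
#' @export
generate_energy_table <- function(residues, dominant_residue, gap, seed = 1L,
                                  noise_sd = 0, path = NULL) {
  if (!dominant_residue %in% residues) {
    stop_gag("params", "dominant_residue must be one of residues")
  }
  if (gap <= 0) stop_gag("params", "gap must be > 0")
  set.seed(seed)
  n <- length(residues)
  means <- -abs(stats::rnorm(n, 3, 1))
  others <- setdiff(seq_len(n), match(dominant_residue, residues))
  means[match(dominant_residue, residues)] <- min(means[others]) - gap
  planted <- means
  if (noise_sd > 0) means <- means + stats::rnorm(n, 0, noise_sd)
  sds <- abs(stats::rnorm(n, 1, 0.3))
  energy <- new_energy_decomposition(
    tibble(residue = residues, mean = means, sd = sds),
    total_mean = sum(means), total_sd = sqrt(sum(sds^2)),
    label = "synthetic")
  if (!is.null(path)) write_energy_table(energy, path)
  list(energy = energy,
       truth = list(generator = "energy_table", seed = seed,
                    dominant_residue = dominant_residue, gap = gap,
                    noise_sd = noise_sd, planted_means = planted))
}

#' Synthetic idealized helical hexasaccharide model
#'
#' A fully synthetic stand-in for a sulfated heparan-sulfate hexasaccharide
#' in its helical solution conformation. It is built from idealized helix
#' parameters — a two-fold helix with an axial rise per disaccharide of
#' 8.7 Angstrom (skew-boat iduronate pucker) or 8.0 Angstrom (chair
#' pucker), ring pseudo-atoms near the axis and sulfate pseudo-atoms
#' projecting radially — and NOT from any experimental coordinate set. Its
#' construction makes the terminal-atom span of the three-disaccharide
#' chain come out near 26 Angstrom, and its enclosing ellipsoid is a thin
#' scalene rod, the qualitative shape regime of the real oligosaccharide.
#' Use it where a worked example needs a hexasaccharide-shaped point cloud
#' and no experimental structure is available.
#'
#' @param pucker Iduronate ring pucker the helix parameters emulate:
#'   `"skew_boat"` (more extended) or `"chair"`.
#' @return A single-frame `gag_ensemble` (6 residues, chain `"H"`).
#' @export
synthetic_hexasaccharide_helix <- function(pucker = c("skew_boat", "chair")) {
  pucker <- match.arg(pucker)
  rise_per_disaccharide <- if (pucker == "skew_boat") 8.7 else 8.0
  rise <- rise_per_disaccharide / 2       # per residue, two residues per turn
  n_res <- 6L
  atoms <- list(); xyz <- list()
  for (i in seq_len(n_res)) {
    phase <- pi * (i - 1)                 # two-fold helix: 180 degrees per residue
    z0 <- rise * (i - 1)
    ring_r <- 1.3                         # ring centre offset from the axis
    cx <- ring_r * cos(phase); cy <- ring_r * sin(phase)
    # six ring pseudo-atoms on a 1.45 A circle tilted along the axis
    ring <- t(vapply(0:5, function(j) {
      a <- 2 * pi * j / 6
      c(cx + 1.45 * cos(a) * cos(phase) - 0.5 * sin(a) * sin(phase),
        cy + 1.45 * cos(a) * sin(phase) + 0.5 * sin(a) * cos(phase),
        z0 + 1.2 * sin(a))
    }, numeric(3)))
    # sulfate pseudo-group: S at 4.3 A radius, three O at ~5.1 A
    sdir <- c(cos(phase + pi / 3), sin(phase + pi / 3), 0)
    s_pos <- c(cx, cy, z0) + 3.0 * sdir
    s_ox <- t(vapply(1:3, function(j) {
      a <- 2 * pi * j / 3
      s_pos + 0.85 * c(cos(a) * sdir[2], -cos(a) * sdir[1], sin(a)) + 0.45 * sdir
    }, numeric(3)))
    res_name <- if (i %% 2 == 1) "IDS" else "SGN"
    atoms[[i]] <- tibble(
      atom_name = c(paste0("C", 1:6), "S1", paste0("OS", 1:3)),
      element = c(rep("C", 6), "S", rep("O", 3)),
      residue_name = res_name, residue_id = i, chain_id = "H")
    xyz[[i]] <- rbind(ring, s_pos, s_ox)
  }
  # terminal glycosidic oxygens extend the chain along the axis at both ends
  atoms[[n_res + 1]] <- tibble(
    atom_name = c("O1T", "O4T"), element = "O",
    residue_name = c("IDS", "SGN"), residue_id = c(1L, n_res), chain_id = "H")
  span <- 3 * rise_per_disaccharide
  xyz[[n_res + 1]] <- rbind(c(0.9, 0, (rise * (n_res - 1) - span) / 2),
                            c(-0.9, 0, (rise * (n_res - 1) + span) / 2))
  conformer_ensemble(topology(bind_rows(atoms)), do.call(rbind, xyz))
}
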