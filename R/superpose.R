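#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Least-squares superposition of `mobile` onto `reference` over a common
#' atom selection, restricted to proper rotations (determinant +1), via
#' singular value decomposition of the cross-covariance.
#'
#' @param mobile,reference `n x 3` coordinate matrices with matching rows.
#' @param selection Optional atom indices over which to fit and score;
#'   default all rows. At least 3 non-collinear atoms are required.
#' @return A list with `rotation` (3x3, det +1), `translation` (length-3),
#'   and `rmsd` (Angstrom). The transform maps mobile coordinates as
#'   `x %*% t(rotation) + translation`.
#' @export
superpose_rmsd <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) {
    stop_gag("superpose", "mobile and reference must have identical dimensions")
  }
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) < 3) stop_gag("degenerate", "need at least 3 atoms to superpose")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2) {
    stop_gag("degenerate", "selection is collinear; superposition is underdetermined")
  }
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- cb - as.vector(R %*% ca)
  moved <- A %*% t(R) + matrix(translation, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

# fast path used in loops: rmsd only
superpose_rmsd_value <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))
  s <- sv$d
  if (det(sv$v %*% t(sv$u)) < 0) s[3] <- -s[3]
  msd <- (sum(A0^2) + sum(B0^2) - 2 * sum(s)) / nrow(A)
  sqrt(max(msd, 0))
}

# superpose every frame onto the iteratively refined mean structure;
# returns the aligned frames x atoms x 3 array and the converged mean
superpose_to_mean <- function(ensemble, selection = NULL, tol = 1e-6,
                              max_iter = 100) {
  nf <- n_frames(ensemble)
  if (is.null(selection)) selection <- seq_len(n_atoms(ensemble))
  frames <- lapply(seq_len(nf), function(i) {
    frame_coords(ensemble, i)[selection, , drop = FALSE]
  })
  mean_str <- frames[[1]]
  aligned <- frames
  for (iter in seq_len(max_iter)) {
    aligned <- lapply(frames, function(fr) {
      tr <- superpose_rmsd(fr, mean_str)
      fr %*% t(tr$rotation) + matrix(tr$translation, nrow(fr), 3, byrow = TRUE)
    })
    new_mean <- Reduce(`+`, aligned) / nf
    shift <- sqrt(mean(rowSums((new_mean - mean_str)^2)))
    mean_str <- new_mean
    if (shift < tol) break
  }
  arr <- array(NA_real_, dim = c(nf, nrow(mean_str), 3))
  for (i in seq_len(nf)) arr[i, , ] <- aligned[[i]]
  list(aligned = arr, mean = mean_str, selection = selection)
}

#' Per-frame RMSD to the converged average structure
#'
#' All frames are superposed onto a running mean structure, the mean is
#' recomputed, and the loop repeats until the mean moves by less than
#' `1e-6` Angstrom RMSD. The reported series is each frame's RMSD to that
#' converged mean — the standard stability measure for a bound ligand or a
#' protein backbone over a production run.
#'
#' @param ensemble A `gag_ensemble` with at least 2 frames.
#' @param selection Optional atom indices; default all atoms.
#' @return A `gag_shape_series` with metric `RMSD_to_average`; the converged
#'   mean structure is attached as attribute `mean_structure`.
#' @export
rmsd_to_average <- function(ensemble, selection = NULL) {
  if (n_frames(ensemble) < 2) {
    stop_gag("insufficient_frames", "need at least 2 frames for an average structure")
  }
  sp <- superpose_to_mean(ensemble, selection)
  nf <- n_frames(ensemble)
  vals <- vapply(seq_len(nf), function(i) {
    sqrt(mean(rowSums((sp$aligned[i, , ] - sp$mean)^2)))
  }, numeric(1))
  new_shape_series(
    tibble(frame = seq_len(nf), time_ps = ensemble$times,
           metric = "RMSD_to_average", value = vals, units = "A"),
    list(mean_structure = sp$mean, selection = sp$selection))
}

#' Principal component analysis of positional fluctuations
#'
#' Frames are first superposed onto the converged mean structure (removing
#' rigid-body motion so conformational, not diffusive, variance is
#' measured), then the 3N-dimensional positional covariance matrix is
#' diagonalized and each frame projected onto the leading eigenvectors.
#'
#' @param ensemble A `gag_ensemble` with at least `n_components` frames.
#' @param selection Optional atom indices; default all atoms.
#' @param n_components Number of leading components to report (default 3).
#' @return A `gag_pca` object: `eigenvalues` (all, descending, Angstrom^2),
#'   `projections` (frames x n_components tibble), `explained_fraction`,
#'   `total_variance`.
#' @export
pca_ensemble <- function(ensemble, selection = NULL, n_components = 3) {
  nf <- n_frames(ensemble)
  if (nf < n_components) {
    stop_gag("rank", sprintf("%d frames cannot support %d components", nf, n_components))
  }
  sp <- superpose_to_mean(ensemble, selection)
  X <- matrix(sp$aligned, nrow = nf)          # frames x 3N
  X <- sweep(X, 2, colMeans(X))
  pc <- stats::prcomp(X, center = FALSE)
  eigenvalues <- pc$sdev^2
  rank <- sum(eigenvalues > max(eigenvalues) * 1e-12)
  if (n_components > rank) {
    stop_gag("rank", sprintf("requested %d components but coordinate rank is %d",
                             n_components, rank))
  }
  total <- sum(X^2) / (nf - 1)
  proj <- as_tibble(setNames(
    as.data.frame(pc$x[, seq_len(n_components), drop = FALSE]),
    paste0("PC", seq_len(n_components))))
  proj$frame <- seq_len(nf)
  structure(list(eigenvalues = eigenvalues,
                 projections = proj[, c("frame", paste0("PC", seq_len(n_components)))],
                 explained_fraction = eigenvalues[seq_len(n_components)] / total,
                 total_variance = total, n_components = n_components),
            class = "gag_pca")
}

#' @export
print.gag_pca <- function(x, ...) {
  cat(sprintf("<gag_pca> %d components; explained fractions: %s\n",
              x$n_components,
              paste(sprintf("%.3f", x$explained_fraction), collapse = ", ")))
  invisible(x)
}
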