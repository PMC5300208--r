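#' Designate the endpoint atoms used for end-to-end distance
#'
#' The choice of terminal atoms is a modelling decision; when it is left
#' open, `auto_endpoints()` picks the two heavy atoms with the largest
#' separation in the first frame and fixes that pair for the whole series.
#' The provenance of the pair travels with it and is recorded in reports.
#'
#' @param atom_a,atom_b Atom indices (1-based, distinct).
#' @param provenance `"user_specified"` or `"auto_max_extent"`.
#' @return A `gag_endpoint_pair`.
#' @export
endpoint_pair <- function(atom_a, atom_b, provenance = "user_specified") {
  if (atom_a == atom_b) stop_gag("endpoints", "endpoint atoms must differ")
  provenance <- match.arg(provenance, c("user_specified", "auto_max_extent"))
  structure(list(atom_a = as.integer(atom_a), atom_b = as.integer(atom_b),
                 provenance = provenance), class = "gag_endpoint_pair")
}

#' @rdname endpoint_pair
#' @param ensemble A `gag_ensemble`; the maximum-extent pair is found among
#'   heavy atoms of its first frame.
#' @export
auto_endpoints <- function(ensemble) {
  heavy <- heavy_atom_indices(ensemble)
  if (length(heavy) < 2) stop_gag("endpoints", "need at least two heavy atoms")
  xyz <- frame_coords(ensemble, 1)[heavy, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  endpoint_pair(heavy[ij[1]], heavy[ij[2]], provenance = "auto_max_extent")
}

new_shape_series <- function(df, extra = list()) {
  out <- as_tibble(df)
  class(out) <- c("gag_shape_series", class(out))
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Per-frame end-to-end distance
#'
#' The Euclidean distance between two designated terminal atoms, one value
#' per frame (Angstrom). Being a pairwise distance it is invariant under
#' rigid rotation and translation of any frame.
#'
#' @param ensemble A `gag_ensemble`.
#' @param pair A [endpoint_pair()], or `NULL` to use [auto_endpoints()].
#' @return A `gag_shape_series` tibble: `frame`, `time_ps`, `metric`,
#'   `value`, `units`, carrying the endpoint pair as attribute `endpoints`.
#' @export
end_to_end_distance <- function(ensemble, pair = NULL) {
  if (is.null(pair)) pair <- auto_endpoints(ensemble)
  na <- n_atoms(ensemble)
  if (pair$atom_a < 1 || pair$atom_a > na || pair$atom_b < 1 || pair$atom_b > na) {
    stop_gag("index", "endpoint atom index out of range")
  }
  delta <- ensemble$coords[, pair$atom_a, , drop = FALSE] -
    ensemble$coords[, pair$atom_b, , drop = FALSE]
  vals <- sqrt(rowSums(matrix(delta, nrow = n_frames(ensemble), ncol = 3)^2))
  new_shape_series(
    tibble(frame = seq_len(n_frames(ensemble)), time_ps = ensemble$times,
           metric = "EED", value = vals, units = "A"),
    list(endpoints = pair))
}

#' Minimum-volume enclosing ellipsoid of a point cloud
#'
#' Khachiyan's barycentric-coordinate-descent algorithm on the dual weights:
#' at each step the point with the largest Mahalanobis factor receives extra
#' weight until the `(1 + eps)` enclosure factor drops below `tolerance`.
#' The returned ellipsoid `{x : (x - c)' A (x - c) <= 1}` encloses every
#' input point (up to `10 * tolerance` slack on the quadratic form) and its
#' volume exceeds the true minimum by at most a factor `(1 + tolerance)^3`.
#'
#' @param points An `n x 3` coordinate matrix, `n >= 4`, not all coplanar.
#' @param tolerance Convergence tolerance on the enclosure factor.
#' @param max_iterations Iteration cap; exceeding it is an error that
#'   reports the final enclosure gap.
#' @return A `gag_ellipsoid`: list with `center`, `shape_matrix`,
#'   `semi_axes` (descending, Angstrom), `axes` (unit axis directions,
#'   columns matching `semi_axes`), `volume` (Angstrom^3), `shape_class`,
#'   `iterations`, `eps`.
#' @export
mvee <- function(points, tolerance = 1e-6, max_iterations = 10000) {
  P <- t(as.matrix(points))           # d x n
  d <- nrow(P); n <- ncol(P)
  if (d != 3) stop_gag("mvee", "points must be n x 3")
  if (n < 4) stop_gag("degenerate_geometry", "need at least 4 points")
  if (qr(sweep(t(P), 2, rowMeans(P)))$rank < 3) {
    stop_gag("degenerate_geometry", "points are coplanar or collinear")
  }
  Q <- rbind(P, 1)                    # (d+1) x n lifted points
  u <- rep(1 / n, n)
  eps <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))     # Mahalanobis factors
    j_up <- which.max(M)
    eps <- M[j_up] / (d + 1) - 1      # (1 + eps) enclosure factor
    if (eps < tolerance) break
    if (iter >= max_iterations) {
      stop_gag("convergence", sprintf(
        "MVEE did not converge in %d iterations (enclosure gap %.3g)",
        max_iterations, eps))
    }
    # Wolfe-Atwood variant of Khachiyan's update: take whichever of the
    # weight-increasing step (most-violating point) or the weight-decreasing
    # "away" step (most over-weighted support point) reduces log det more;
    # away steps give the linear convergence plain coordinate ascent lacks
    support <- which(u > 1e-12)
    j_dn <- support[which.min(M[support])]
    if (eps >= 1 - M[j_dn] / (d + 1)) {
      j <- j_up
      step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    } else {
      j <- j_dn
      step <- max((M[j] - d - 1) / ((d + 1) * (M[j] - 1)),
                  -u[j] / (1 - u[j]))
    }
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  center <- as.vector(P %*% u)
  S <- P %*% (u * t(P)) - tcrossprod(center)
  A <- solve(S) / d
  A <- (A + t(A)) / 2
  new_ellipsoid(center, A, iterations = iter, eps = eps)
}

new_ellipsoid <- function(center, shape_matrix, iterations = NA_integer_,
                          eps = NA_real_, axis_equality_tolerance = 0.02) {
  eg <- eigen(shape_matrix, symmetric = TRUE)
  if (any(eg$values <= 0)) stop_gag("ellipsoid", "shape matrix must be positive definite")
  semi <- 1 / sqrt(eg$values)         # eigen() sorts values descending,
  ord <- order(semi, decreasing = TRUE)  # so semi-axes come out ascending
  semi <- semi[ord]
  axes <- eg$vectors[, ord, drop = FALSE]
  vol <- 4 / 3 * pi * prod(semi)
  structure(list(center = as.vector(center), shape_matrix = shape_matrix,
                 semi_axes = semi, axes = axes, volume = vol,
                 shape_class = classify_axes(semi, axis_equality_tolerance),
                 iterations = iterations, eps = eps),
            class = "gag_ellipsoid")
}

classify_axes <- function(semi, tol = 0.02) {
  eq <- function(a, b) abs(a - b) <= tol * mean(c(a, b))
  big_mid <- eq(semi[1], semi[2]); mid_small <- eq(semi[2], semi[3])
  if (big_mid && mid_small) "spherical"
  else if (mid_small) "prolate"
  else if (big_mid) "oblate"
  else "scalene"
}

#' @export
print.gag_ellipsoid <- function(x, ...) {
  cat(sprintf("<gag_ellipsoid> %s | semi-axes %.3f, %.3f, %.3f A | volume %.2f A^3\n",
              x$shape_class, x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              x$volume))
  invisible(x)
}

#' Semi-axes, volume and shape class of an ellipsoid
#'
#' Axial lengths are reported in both conventions — semi-axes and full
#' axial lengths (twice the semi-axes) — because published shape tables do
#' not always say which they use. The shape class compares axes at a
#' relative equality tolerance: `spherical` (all three equal), `prolate`
#' (two smaller equal), `oblate` (two larger equal), else `scalene`.
#'
#' @param ellipsoid A `gag_ellipsoid`.
#' @param axis_equality_tolerance Relative tolerance for axis equality.
#' @return A one-row tibble: `semi_a >= semi_b >= semi_c`, `axial_a/b/c`
#'   (full lengths), `volume`, `shape_class`.
#' @export
ellipsoid_descriptors <- function(ellipsoid, axis_equality_tolerance = 0.02) {
  s <- ellipsoid$semi_axes
  tibble(semi_a = s[1], semi_b = s[2], semi_c = s[3],
         axial_a = 2 * s[1], axial_b = 2 * s[2], axial_c = 2 * s[3],
         volume = ellipsoid$volume,
         shape_class = classify_axes(s, axis_equality_tolerance))
}

#' Per-frame minimum-volume enclosing ellipsoid series
#'
#' Runs [mvee()] on every frame (heavy atoms by default, since sulfate and
#' ring geometry dominate molecular shape) and reports the volume and the
#' three semi-axis lengths per frame.
#'
#' @param ensemble A `gag_ensemble`.
#' @param selection Atom indices to use; default all heavy atoms.
#' @param tolerance,max_iterations Passed to [mvee()].
#' @return A `gag_shape_series` tibble in long form with metrics
#'   `MVEE_volume` (Angstrom^3), `axis_longest`, `axis_mid`,
#'   `axis_shortest` (Angstrom, semi-axis lengths).
#' @export
mvee_series <- function(ensemble, selection = NULL, tolerance = 1e-6,
                        max_iterations = 10000) {
  if (is.null(selection)) selection <- heavy_atom_indices(ensemble)
  nf <- n_frames(ensemble)
  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    e <- mvee(frame_coords(ensemble, i)[selection, , drop = FALSE],
              tolerance, max_iterations)
    rows[[i]] <- tibble(
      frame = i, time_ps = ensemble$times[i],
      metric = c("MVEE_volume", "axis_longest", "axis_mid", "axis_shortest"),
      value = c(e$volume, e$semi_axes),
      units = c("A^3", "A", "A", "A"))
  }
  new_shape_series(bind_rows(rows),
                   list(mvee_tolerance = tolerance, selection = selection))
}
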