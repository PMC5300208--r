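#' Tidy an ellipsoid into one row per axis
#'
#' @param x A `gag_ellipsoid`.
#' @param ... Unused.
#' @return A tibble: `axis` (`a`, `b`, `c` descending), `semi_axis`,
#'   `axial_length` (Angstrom) and the axis direction cosines.
#' @method tidy gag_ellipsoid
#' @export
tidy.gag_ellipsoid <- function(x, ...) {
  tibble(axis = c("a", "b", "c"),
         semi_axis = x$semi_axes,
         axial_length = 2 * x$semi_axes,
         dir_x = x$axes[1, ], dir_y = x$axes[2, ], dir_z = x$axes[3, ])
}

#' One-row summary of an ellipsoid
#' @inheritParams tidy.gag_ellipsoid
#' @return A one-row tibble: `volume`, `shape_class`, `iterations`, `eps`.
#' @method glance gag_ellipsoid
#' @export
glance.gag_ellipsoid <- function(x, ...) {
  tibble(volume = x$volume, shape_class = x$shape_class,
         iterations = x$iterations, eps = x$eps)
}

#' Tidy a cluster assignment into one row per frame
#' @param x A `gag_cluster_assignment`.
#' @param ... Unused.
#' @return A tibble: `frame`, `label`, `is_centroid`.
#' @method tidy gag_cluster_assignment
#' @export
tidy.gag_cluster_assignment <- function(x, ...) {
  tibble(frame = seq_along(x$labels), label = x$labels,
         is_centroid = seq_along(x$labels) %in% x$centroids)
}

#' One-row summary of a cluster assignment
#' @inheritParams tidy.gag_cluster_assignment
#' @return A one-row tibble: `k`, `n_frames`, `largest_size`,
#'   `max_member_rmsd`, `radius`, `seed`.
#' @method glance gag_cluster_assignment
#' @export
glance.gag_cluster_assignment <- function(x, ...) {
  tibble(k = length(x$sizes), n_frames = length(x$labels),
         largest_size = max(x$sizes), max_member_rmsd = x$max_member_rmsd,
         radius = x$radius, seed = x$seed)
}

#' Tidy a PCA of positional fluctuations
#' @param x A `gag_pca`.
#' @param ... Unused.
#' @return A tibble with one row per reported component: `component`,
#'   `eigenvalue` (Angstrom^2), `explained_fraction`.
#' @method tidy gag_pca
#' @export
tidy.gag_pca <- function(x, ...) {
  k <- x$n_components
  tibble(component = paste0("PC", seq_len(k)),
         eigenvalue = x$eigenvalues[seq_len(k)],
         explained_fraction = x$explained_fraction)
}

#' @rdname tidy.gag_pca
#' @method glance gag_pca
#' @export
glance.gag_pca <- function(x, ...) {
  tibble(n_components = x$n_components,
         total_variance = x$total_variance,
         explained_total = sum(x$explained_fraction))
}

#' Tidy a leg verdict into its component table
#' @param x A `gag_leg_verdict`.
#' @param ... Unused.
#' @return The component tibble with `leg`, `status` columns prepended.
#' @method tidy gag_leg_verdict
#' @export
tidy.gag_leg_verdict <- function(x, ...) {
  comps <- as_tibble(x$components)
  if (nrow(comps) == 0) return(tibble(leg = character(), component = character(),
                                      score = numeric(), similar = logical()))
  comps$leg <- x$leg
  comps[, union(c("leg", "component"), names(comps))]
}

#' @rdname tidy.gag_leg_verdict
#' @method glance gag_leg_verdict
#' @export
glance.gag_leg_verdict <- function(x, ...) {
  tibble(leg = x$leg, status = x$status, score = x$score)
}

#' Tidy a mimicry report into one row per leg
#' @param x A `gag_mimicry_report`.
#' @param ... Unused.
#' @return A tibble: `candidate`, `reference`, `leg`, `status`, `score`.
#' @method tidy gag_mimicry_report
#' @export
tidy.gag_mimicry_report <- function(x, ...) {
  bind_rows(lapply(x$legs, glance)) |>
    mutate(candidate = x$candidate, reference = x$reference, .before = 1)
}

#' @rdname tidy.gag_mimicry_report
#' @method glance gag_mimicry_report
#' @export
glance.gag_mimicry_report <- function(x, ...) {
  tibble(candidate = x$candidate, reference = x$reference,
         overall = x$overall, overall_score = x$overall_score,
         legs_passed = sum(vapply(x$legs, function(l) l$status == "pass",
                                  logical(1))))
}
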