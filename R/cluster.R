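#' Parameters for RMSD-radius conformer clustering
#'
#' @param radius Cluster radius in Angstrom: every member must lie within
#'   this superposed RMSD of its cluster's medoid frame (default 2.0, the
#'   conventional conformational-family cutoff).
#' @param seed Integer seed making the k-means restarts deterministic.
#' @param max_k Largest number of clusters to try.
#' @param selection Optional atom indices used for superposition and RMSD.
#' @return A `gag_clustering_params` list.
#' @export
clustering_params <- function(radius = 2.0, seed = 1L, max_k = 20L,
                              selection = NULL) {
  if (radius <= 0) stop_gag("params", "radius must be > 0")
  if (max_k < 1) stop_gag("params", "max_k must be >= 1")
  structure(list(radius = radius, seed = as.integer(seed),
                 max_k = as.integer(max_k), selection = selection),
            class = "gag_clustering_params")
}

#' Cluster ensemble frames at a fixed RMSD radius
#'
#' Incremental-k strategy: frames are superposed onto the converged mean
#' structure, then k-means (10 seeded restarts) is run in the superposed
#' coordinate space for k = 1, 2, ... until every frame lies within
#' `radius` RMSD (optimal pairwise superposition) of its cluster's medoid
#' frame. The medoid — the member minimizing summed RMSD to its cluster —
#' is reported as the representative conformation. Labels are relabelled
#' canonically by first occurrence, so the same seed always reproduces the
#' same assignment.
#'
#' @param ensemble A `gag_ensemble`.
#' @param params A [clustering_params()].
#' @return A `gag_cluster_assignment`: list with `labels` (per frame, dense
#'   1..k), `centroids` (medoid frame index per cluster), `sizes`,
#'   `max_member_rmsd`, `radius`, `seed`.
#' @export
cluster_conformers <- function(ensemble, params = clustering_params()) {
  nf <- n_frames(ensemble)
  if (nf < 1) stop_gag("cluster", "empty ensemble")
  sel <- params$selection %||% seq_len(n_atoms(ensemble))
  frames <- lapply(seq_len(nf), function(i) {
    frame_coords(ensemble, i)[sel, , drop = FALSE]
  })
  # the clustering metric is pairwise optimal-superposition RMSD, so that
  # cluster identity is rigid-motion invariant and free of the orientation
  # ambiguities a shared reference frame introduces
  D <- matrix(0, nf, nf)
  if (nf > 1) {
    for (a in seq_len(nf - 1)) {
      for (b in (a + 1):nf) {
        D[a, b] <- D[b, a] <- superpose_rmsd_value(frames[[a]], frames[[b]])
      }
    }
  }
  # k-means runs on a Euclidean embedding of that metric
  X <- if (nf > 2 && max(D) > 0) {
    emb <- suppressWarnings(stats::cmdscale(D, k = min(nf - 1, 10)))
    if (is.null(dim(emb))) matrix(emb, ncol = 1) else emb
  } else {
    matrix(0, nf, 1)
  }

  distinct <- nrow(unique(round(X, 8)))
  best_violation <- Inf
  for (k in seq_len(min(params$max_k, nf))) {
    if (k == 1) {
      labels <- rep(1L, nf)
    } else if (k > distinct) {
      break
    } else {
      set.seed(params$seed)
      labels <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)$cluster
    }
    res <- medoids_and_check(D, labels, params$radius)
    best_violation <- min(best_violation, res$worst)
    if (res$ok) {
      return(finalize_assignment(labels, res$medoids, res$worst, params))
    }
  }
  stop_gag("radius_unsatisfiable", sprintf(
    "no k <= %d satisfies radius %.3g A (best achieved max member RMSD %.3g A)",
    params$max_k, params$radius, best_violation))
}

medoids_and_check <- function(D, labels, radius) {
  ks <- sort(unique(labels))
  medoids <- integer(length(ks))
  worst <- 0
  ok <- TRUE
  for (ci in seq_along(ks)) {
    members <- which(labels == ks[ci])
    if (length(members) == 1) {
      medoids[ci] <- members
      next
    }
    Dm <- D[members, members, drop = FALSE]
    med <- which.min(rowSums(Dm))
    medoids[ci] <- members[med]
    worst_here <- max(Dm[med, ])
    worst <- max(worst, worst_here)
    if (worst_here > radius) ok <- FALSE
  }
  list(medoids = medoids, worst = worst, ok = ok)
}

finalize_assignment <- function(labels, medoids, worst, params) {
  # canonical relabelling by first occurrence; medoids follow the new ids
  first_seen <- unique(labels)
  new_lab <- match(labels, first_seen)
  med_by_new <- medoids[match(first_seen, sort(unique(labels)))]
  sizes <- tabulate(new_lab)
  structure(list(labels = new_lab, centroids = med_by_new, sizes = sizes,
                 max_member_rmsd = worst, radius = params$radius,
                 seed = params$seed),
            class = "gag_cluster_assignment")
}

#' @export
print.gag_cluster_assignment <- function(x, ...) {
  cat(sprintf("<gag_cluster_assignment> %d cluster(s) over %d frames; sizes: %s\n",
              length(x$sizes), length(x$labels),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Representative structures of a clustering
#'
#' Reports each cluster's medoid frame and the largest cluster (ties broken
#' by lower cluster index). If `reference_frame` is supplied — typically an
#' externally identified lowest-energy frame — its superposed RMSD to the
#' largest-cluster medoid is included, a standard check that the dominant
#' conformational family and the energy minimum agree.
#'
#' @param ensemble The clustered `gag_ensemble`.
#' @param assignment A `gag_cluster_assignment` from [cluster_conformers()].
#' @param reference_frame Optional frame index to compare against.
#' @return A list: `clusters` (tibble: cluster, size, centroid_frame,
#'   is_largest), `largest_centroid` (frame index), and when a reference is
#'   given, `reference_rmsd` (Angstrom).
#' @export
representative_structures <- function(ensemble, assignment,
                                      reference_frame = NULL) {
  k <- length(assignment$sizes)
  clusters <- tibble(
    cluster = seq_len(k),
    size = assignment$sizes,
    centroid_frame = assignment$centroids
  )
  largest <- which.max(clusters$size)   # which.max takes the lowest index on ties
  clusters$is_largest <- seq_len(k) == largest
  out <- list(clusters = clusters,
              largest_centroid = clusters$centroid_frame[largest])
  if (!is.null(reference_frame)) {
    if (reference_frame < 1 || reference_frame > n_frames(ensemble)) {
      stop_gag("index", "reference_frame out of range")
    }
    out$reference_rmsd <- superpose_rmsd_value(
      frame_coords(ensemble, reference_frame),
      frame_coords(ensemble, out$largest_centroid))
  }
  out
}
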