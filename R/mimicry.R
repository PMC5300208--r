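#' Five-number summary of a metric series
#'
#' The numeric backbone of every box-plot-style comparison in the package:
#' minimum, linear-interpolation quartiles (position `(n - 1) * p`, the
#' default sample-quantile convention), median, maximum, mean and the
#' (n - 1)-denominator standard deviation.
#'
#' @param series A `gag_shape_series` tibble (one row per frame, possibly
#'   several metrics), a `gag_occupancy` table (its occupancy column is
#'   summarised), or a plain numeric vector.
#' @param metric_name Metric label used when `series` is a bare vector.
#' @return A `gag_summary` tibble with one row per metric: `metric`, `n`,
#'   `min`, `q1`, `median`, `q3`, `max`, `mean`, `sd`.
#' @export
summary_stats <- function(series, metric_name = "value") {
  if (inherits(series, "gag_occupancy")) {
    df <- tibble(metric = "occupancy", value = series$occupancy)
  } else if (is.data.frame(series)) {
    if (!all(c("metric", "value") %in% names(series))) {
      stop_gag("summary", "data-frame input needs columns metric and value")
    }
    df <- series[, c("metric", "value")]
  } else {
    df <- tibble(metric = metric_name, value = as.numeric(series))
  }
  if (nrow(df) == 0) stop_gag("empty_series", "cannot summarise an empty series")
  out <- df |>
    group_by(.data$metric) |>
    summarise(
      n = dplyr::n(),
      min = min(.data$value),
      q1 = as.numeric(stats::quantile(.data$value, 0.25, type = 7)),
      median = as.numeric(stats::quantile(.data$value, 0.5, type = 7)),
      q3 = as.numeric(stats::quantile(.data$value, 0.75, type = 7)),
      max = max(.data$value),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      .groups = "drop")
  class(out) <- c("gag_summary", class(out))
  out
}

#' Quantify the overlap of two metric distributions
#'
#' Where published comparisons put two box plots side by side and call them
#' similar by eye, this makes the rule explicit: the interquartile-range
#' overlap (Jaccard of the two IQR intervals, 0 when disjoint, 1 when
#' identical) and the standardized mean difference (difference of means
#' over the pooled standard deviation). Two distributions are "similar"
#' when the IQR overlap is at least `theta_overlap` and |SMD| is at most
#' `theta_smd`.
#'
#' @param a,b One-row `gag_summary` tables (or multi-row tables sharing a
#'   single common metric) for the same metric.
#' @param theta_overlap Minimum IQR overlap (default 0.25).
#' @param theta_smd Maximum |standardized mean difference| (default 2.0).
#' @return A one-row tibble: `metric`, `iqr_overlap`, `standardized_mean_difference`,
#'   `similar`.
#' @export
overlap_index <- function(a, b, theta_overlap = 0.25, theta_smd = 2.0) {
  a <- as_tibble(a); b <- as_tibble(b)
  if (nrow(a) != 1 || nrow(b) != 1 || !identical(a$metric, b$metric)) {
    stop_gag("metric_mismatch",
             "overlap_index compares exactly one metric, present on both sides")
  }
  lo <- max(a$q1, b$q1); hi <- min(a$q3, b$q3)
  inter <- max(0, hi - lo)
  uni <- max(a$q3, b$q3) - min(a$q1, b$q1)
  iqr_overlap <- if (uni <= 0) {
    # both IQRs are single points: identical -> 1, distinct -> 0
    as.numeric(a$q1 == b$q1)
  } else inter / uni
  pooled <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) /
                   max(1, a$n + b$n - 2))
  smd <- if (pooled > 0) (a$mean - b$mean) / pooled
  else if (a$mean == b$mean) 0 else Inf * sign(a$mean - b$mean)
  tibble(metric = a$metric, iqr_overlap = iqr_overlap,
         standardized_mean_difference = smd,
         similar = iqr_overlap >= theta_overlap & abs(smd) <= theta_smd)
}

new_leg_verdict <- function(leg, status, score, components) {
  structure(list(leg = leg, status = status, score = score,
                 components = components),
            class = "gag_leg_verdict")
}

#' @export
print.gag_leg_verdict <- function(x, ...) {
  cat(sprintf("<gag_leg_verdict> %s: %s (score %.3f)\n", x$leg, x$status, x$score))
  invisible(x)
}

pick_metric <- function(summary, metric) {
  row <- summary[summary$metric == metric, , drop = FALSE]
  if (nrow(row) != 1) {
    stop_gag("missing_metric", paste0("summary is missing metric ", metric))
  }
  class(row) <- class(summary)
  row
}

#' Leg 1 — free-state shape comparison
#'
#' A candidate mimics the reference glycosaminoglycan in free solution when
#' both its end-to-end-distance and its enclosing-ellipsoid-volume
#' distributions are similar to the reference's under [overlap_index()].
#' The leg score is the mean of the two IQR overlaps.
#'
#' @param candidate,reference `gag_summary` tables containing metrics
#'   `EED` and `MVEE_volume`.
#' @param theta_overlap,theta_smd Thresholds passed to [overlap_index()].
#' @return A `gag_leg_verdict`.
#' @export
free_state_verdict <- function(candidate, reference,
                               theta_overlap = 0.25, theta_smd = 2.0) {
  comps <- bind_rows(lapply(c("EED", "MVEE_volume"), function(m) {
    overlap_index(pick_metric(candidate, m), pick_metric(reference, m),
                  theta_overlap, theta_smd)
  }))
  comps$component <- comps$metric
  comps$score <- comps$iqr_overlap
  new_leg_verdict("free_state",
                  if (all(comps$similar)) "pass" else "fail",
                  mean(comps$iqr_overlap), comps)
}

#' Docking evidence record
#'
#' The binding-site leg does not dock anything; it ingests the outcome of
#' an external docking run: a dimensionless fitness score (e.g. a
#' genetic-algorithm docking fitness) and whether the best pose occupies
#' the same site as the reference ligand.
#'
#' @param label Candidate label.
#' @param score Docking fitness score (finite).
#' @param same_site_as_reference Logical: does the best pose sit in the
#'   reference ligand's site?
#' @param pose_rmsd_spread Optional spread (Angstrom) of the top poses.
#' @return A `gag_docking_evidence` list.
#' @export
docking_evidence <- function(label, score, same_site_as_reference,
                             pose_rmsd_spread = NA_real_) {
  if (!is.finite(score)) stop_gag("invalid_evidence", "docking score must be finite")
  structure(list(label = label, score = score,
                 same_site_as_reference = isTRUE(same_site_as_reference),
                 pose_rmsd_spread = pose_rmsd_spread),
            class = "gag_docking_evidence")
}

#' Leg 2 — binding-site identity check
#'
#' Passes when the candidate's best pose occupies the same site as the
#' reference ligand and its docking score reaches at least
#' `score_ratio_threshold` of the reference score. With either evidence
#' record absent the leg is inconclusive (it cannot fail what was never
#' docked). The leg score is the score ratio clipped to `[0, 1]`.
#'
#' @param candidate,reference [docking_evidence()] records, or `NULL`.
#' @param score_ratio_threshold Minimum candidate/reference score ratio
#'   (default 0.8).
#' @return A `gag_leg_verdict`.
#' @export
binding_site_check <- function(candidate, reference,
                               score_ratio_threshold = 0.8) {
  if (is.null(candidate) || is.null(reference)) {
    return(new_leg_verdict("binding_site", "inconclusive", NA_real_,
                           tibble(component = "docking", score = NA_real_,
                                  similar = NA)))
  }
  if (reference$score <= 0) {
    stop_gag("invalid_evidence", "reference docking score must be positive")
  }
  ratio <- candidate$score / reference$score
  score <- min(1, max(0, ratio))
  pass <- candidate$same_site_as_reference && ratio >= score_ratio_threshold
  comps <- tibble(component = c("same_site", "score_ratio"),
                  score = c(as.numeric(candidate$same_site_as_reference), score),
                  similar = c(candidate$same_site_as_reference,
                              ratio >= score_ratio_threshold))
  new_leg_verdict("binding_site", if (pass) "pass" else "fail", score, comps)
}

#' Leg 3 — bound-state interaction and energetics comparison
#'
#' Compares the candidate and reference in the protein-bound state across
#' up to three component families:
#'
#' 1. **shape** — bound-state `EED` and `MVEE_volume` distributions, as in
#'    leg 1;
#' 2. **occupancy** — Jaccard similarity of the residue sets with hydrogen-
#'    bond occupancy at least `occupancy_threshold` percent, plus the
#'    absolute difference of the overall mean occupancy;
#' 3. **energy** — overlap of the total binding free-energy intervals
#'    (mean plus/minus sd) and Jaccard of the top-`top_k` dominant
#'    residues.
#'
#' Occupancy and energy components are optional; absent components are
#' skipped and flagged, and the leg passes only if every evaluated
#' component is similar. The leg score is the mean of the evaluated
#' component scores.
#'
#' @param candidate,reference `gag_summary` tables with bound-state `EED`
#'   and `MVEE_volume`.
#' @param candidate_occupancy,reference_occupancy Optional `gag_occupancy`
#'   tables.
#' @param candidate_energy,reference_energy Optional
#'   `gag_energy_decomposition` tables.
#' @param theta_overlap,theta_smd Shape thresholds, as in [overlap_index()].
#' @param occupancy_threshold Occupancy (percent) above which a residue
#'   counts as a stable hydrogen-bonding partner (default 50).
#' @param occupancy_jaccard_min Minimum residue-set Jaccard for the
#'   occupancy component (default 0.5).
#' @param occupancy_mean_diff_max Maximum absolute difference of mean
#'   occupancies, percentage points (default 25).
#' @param top_k Number of dominant residues compared (default 3).
#' @return A `gag_leg_verdict`.
#' @export
bound_state_verdict <- function(candidate, reference,
                                candidate_occupancy = NULL,
                                reference_occupancy = NULL,
                                candidate_energy = NULL,
                                reference_energy = NULL,
                                theta_overlap = 0.25, theta_smd = 2.0,
                                occupancy_threshold = 50,
                                occupancy_jaccard_min = 0.5,
                                occupancy_mean_diff_max = 25,
                                top_k = 3) {
  comps <- list()

  if (!is.null(candidate) && !is.null(reference)) {
    shape <- bind_rows(lapply(c("EED", "MVEE_volume"), function(m) {
      overlap_index(pick_metric(candidate, m), pick_metric(reference, m),
                    theta_overlap, theta_smd)
    }))
    comps$shape <- tibble(component = paste0("shape_", shape$metric),
                          score = shape$iqr_overlap, similar = shape$similar)
  }

  if (!is.null(candidate_occupancy) && !is.null(reference_occupancy)) {
    set_a <- candidate_occupancy$residue[candidate_occupancy$occupancy >= occupancy_threshold]
    set_b <- reference_occupancy$residue[reference_occupancy$occupancy >= occupancy_threshold]
    jac <- jaccard(set_a, set_b)
    mean_diff <- abs(mean(candidate_occupancy$occupancy) -
                       mean(reference_occupancy$occupancy))
    comps$occupancy <- tibble(
      component = c("occupancy_residue_sets", "occupancy_mean_diff"),
      score = c(jac, max(0, 1 - mean_diff / 100)),
      similar = c(jac >= occupancy_jaccard_min,
                  mean_diff <= occupancy_mean_diff_max))
  }

  if (!is.null(candidate_energy) && !is.null(reference_energy)) {
    ga <- total_dg(candidate_energy); gb <- total_dg(reference_energy)
    intervals_overlap <- (ga["mean"] - ga["sd"]) <= (gb["mean"] + gb["sd"]) &&
      (gb["mean"] - gb["sd"]) <= (ga["mean"] + ga["sd"])
    jac3 <- jaccard(dominant_residues(candidate_energy, top_k)$residue,
                    dominant_residues(reference_energy, top_k)$residue)
    comps$energy <- tibble(
      component = c("dg_interval_overlap", "dominant_residues"),
      score = c(as.numeric(intervals_overlap), jac3),
      similar = c(intervals_overlap, NA))   # jaccard informs the score only
  }

  if (length(comps) == 0) {
    stop_gag("nothing_to_compare", "no bound-state components were supplied")
  }
  comps <- bind_rows(comps)
  evaluated <- comps[!is.na(comps$similar), , drop = FALSE]
  pass <- all(evaluated$similar)
  new_leg_verdict("bound_state", if (pass) "pass" else "fail",
                  mean(comps$score), comps)
}

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
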