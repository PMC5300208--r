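#' Provenance block for a mimicry report
#'
#' Every report records the analysis conventions it was produced under, so
#' that two reports are only ever compared when their settings match.
#'
#' @param hbond_convention Angle convention used for hydrogen-bond
#'   detection (see [hbond_criteria()]).
#' @param analysis_window Description of the analysis window, e.g.
#'   `"(10000, 20000] ps, stride 10 ps"`.
#' @param clustering_seed,clustering_radius Clustering settings.
#' @param mvee_tolerance Convergence tolerance used for [mvee()].
#' @param eed_endpoints Endpoint provenance, `"user_specified"` or
#'   `"auto_max_extent"`.
#' @param ... Further named settings worth recording.
#' @return A named list.
#' @export
provenance_block <- function(hbond_convention = "deviation_from_linearity_DHA",
                             analysis_window = "final 50% of frames",
                             clustering_seed = NA_integer_,
                             clustering_radius = 2.0,
                             mvee_tolerance = 1e-6,
                             eed_endpoints = "auto_max_extent",
                             ...) {
  list(hbond_convention = hbond_convention,
       analysis_window = analysis_window,
       clustering_seed = clustering_seed,
       clustering_radius = clustering_radius,
       mvee_tolerance = mvee_tolerance,
       eed_endpoints = eed_endpoints, ...)
}

#' Assemble a mimicry report from the three sequential legs
#'
#' The legs are sequential: a failed leg short-circuits the procedure and
#' later legs are marked `not_evaluated` (whether or not their inputs were
#' available). The overall verdict is `non_mimic` as soon as any completed
#' leg fails, `inconclusive` when no leg fails but at least one evaluated
#' leg is inconclusive, and `mimic` only when every evaluated leg passes.
#' The overall score is the mean score of the evaluated legs.
#'
#' @param candidate,reference Labels of the candidate mimetic and the
#'   reference glycosaminoglycan.
#' @param free_state,binding_site,bound_state `gag_leg_verdict`s from
#'   [free_state_verdict()], [binding_site_check()],
#'   [bound_state_verdict()]; later legs may be `NULL` when never run.
#' @param provenance A [provenance_block()].
#' @return A `gag_mimicry_report`.
#' @export
mimicry_report <- function(candidate, reference, free_state,
                           binding_site = NULL, bound_state = NULL,
                           provenance = provenance_block()) {
  legs_in <- list(free_state = free_state, binding_site = binding_site,
                  bound_state = bound_state)
  legs <- list()
  failed <- FALSE
  for (nm in names(legs_in)) {
    v <- legs_in[[nm]]
    if (failed || is.null(v)) {
      legs[[nm]] <- new_leg_verdict(nm, "not_evaluated", NA_real_,
                                    tibble(component = character(),
                                           score = numeric(), similar = logical()))
      next
    }
    legs[[nm]] <- v
    if (v$status == "fail") failed <- TRUE
  }
  statuses <- vapply(legs, function(l) l$status, character(1))
  evaluated <- statuses %in% c("pass", "fail", "inconclusive")
  overall <- if (any(statuses == "fail")) "non_mimic"
  else if (any(statuses == "inconclusive")) "inconclusive"
  else "mimic"
  scores <- vapply(legs, function(l) l$score, numeric(1))[evaluated]
  overall_score <- if (any(!is.na(scores))) mean(scores, na.rm = TRUE) else NA_real_
  structure(list(candidate = candidate, reference = reference, legs = legs,
                 overall = overall, overall_score = overall_score,
                 provenance = provenance),
            class = "gag_mimicry_report")
}

#' @export
print.gag_mimicry_report <- function(x, ...) {
  cat(sprintf("<gag_mimicry_report> %s vs %s: %s (score %.3f)\n",
              x$candidate, x$reference, x$overall, x$overall_score))
  for (l in x$legs) {
    cat(sprintf("  %-12s %s%s\n", l$leg, l$status,
                if (is.na(l$score)) "" else sprintf(" (%.3f)", l$score)))
  }
  invisible(x)
}

#' Rank candidate mimetics against a common reference
#'
#' Candidates are ordered by number of passed legs, then by overall score,
#' with a deterministic alphabetical tie-break on the candidate label.
#' Candidates whose reports were produced against different references
#' cannot be ranked together.
#'
#' @param reports A list of `gag_mimicry_report`s sharing one reference.
#' @return A tibble: `rank`, `candidate`, `reference`, `legs_passed`,
#'   `overall`, `overall_score`, `tie_note`.
#' @export
rank_candidates <- function(reports) {
  if (inherits(reports, "gag_mimicry_report")) reports <- list(reports)
  refs <- unique(vapply(reports, function(r) r$reference, character(1)))
  if (length(refs) != 1) {
    stop_gag("reference_mismatch", paste0(
      "reports target different references: ", paste(refs, collapse = ", ")))
  }
  df <- bind_rows(lapply(reports, function(r) {
    tibble(candidate = r$candidate, reference = r$reference,
           legs_passed = sum(vapply(r$legs, function(l) l$status == "pass",
                                    logical(1))),
           overall = r$overall,
           overall_score = r$overall_score)
  }))
  df <- df |>
    arrange(desc(.data$legs_passed), desc(.data$overall_score), .data$candidate)
  df$rank <- seq_len(nrow(df))
  key <- paste(df$legs_passed, signif(df$overall_score, 12))
  df$tie_note <- ifelse(duplicated(key) | duplicated(key, fromLast = TRUE),
                        "tied on legs passed and score; alphabetical order", "")
  df[, c("rank", "candidate", "reference", "legs_passed", "overall",
         "overall_score", "tie_note")]
}

#' Serialize / restore a mimicry report
#'
#' Reports round-trip through structured JSON with full fidelity: legs,
#' component tables, scores and the provenance block are all preserved.
#'
#' @param report A `gag_mimicry_report`.
#' @param path Output (or input) file path.
#' @return `write_mimicry_report()` returns `path` invisibly;
#'   `read_mimicry_report()` returns the restored `gag_mimicry_report`.
#' @export
write_mimicry_report <- function(report, path) {
  payload <- list(
    candidate = report$candidate, reference = report$reference,
    overall = report$overall, overall_score = report$overall_score,
    legs = lapply(report$legs, function(l) {
      list(leg = l$leg, status = l$status, score = l$score,
           components = as.data.frame(l$components))
    }),
    provenance = report$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_mimicry_report
#' @export
read_mimicry_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  legs <- lapply(payload$legs, function(l) {
    comps <- as_tibble(l$components)
    if (nrow(comps) == 0) {
      comps <- tibble(component = character(), score = numeric(),
                      similar = logical())
    }
    new_leg_verdict(l$leg, l$status, l$score %||% NA_real_, comps)
  })
  prov <- payload$provenance
  structure(list(candidate = payload$candidate, reference = payload$reference,
                 legs = legs, overall = payload$overall,
                 overall_score = payload$overall_score %||% NA_real_,
                 provenance = prov),
            class = "gag_mimicry_report")
}
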