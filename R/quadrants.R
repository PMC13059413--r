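#' Sample-mean cut-offs for the LAI-LAD plane
#'
#' The boundary between "low" and "high" on each axis is the sample mean over
#' the scored actors of the current network boundary: LAI averaged over actors
#' with a defined LAI, LAD averaged over all boundary actors. Cut-offs are
#' therefore boundary-specific and must be recomputed when the network is
#' restricted.
#'
#' @param scores output of [score_cohort()].
#' @return object of class `lead_cutoffs`: list `lai_cutoff`, `lad_cutoff`,
#'   `boundary`.
#' @export
compute_cutoffs <- function(scores) {
  lai_vals <- scores$lai[scores$lai_defined]
  if (length(lai_vals) < 2 || sum(!is.na(scores$lad)) < 2)
    stop("cut-offs need at least 2 actors with defined scores", call. = FALSE)
  structure(list(
    lai_cutoff = mean(lai_vals),
    lad_cutoff = mean(scores$lad),
    boundary = attr(scores, "boundary") %||% "full"
  ), class = "lead_cutoffs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lead_cutoffs <- function(x, ...) {
  cat(sprintf("<lead_cutoffs> LAI >= %.2f, LAD >= %.2f (%s boundary)\n",
              x$lai_cutoff, x$lad_cutoff, x$boundary))
  invisible(x)
}

#' Classify actors into the four leadership quadrants
#'
#' Actors at or above both cut-offs are established leaders; at or above the
#' LAD cut-off only, humble; at or above the LAI cut-off only, aspirational;
#' below both, latent. Scores exactly at a cut-off classify as "high"
#' (boundary-inclusive rule). Actors without a defined LAI are excluded with a
#' logged note.
#'
#' @param scores output of [score_cohort()].
#' @param cutoffs a `lead_cutoffs` object.
#' @return tibble: `actor_id`, `role`, `lai`, `lad`, `quadrant` (factor with
#'   levels established, humble, aspirational, latent); `cutoffs` attribute
#'   attached.
#' @export
classify_quadrants <- function(scores, cutoffs) {
  stopifnot(inherits(cutoffs, "lead_cutoffs"))
  excluded <- !scores$lai_defined
  if (any(excluded))
    message(sum(excluded),
            " actor(s) excluded from quadrant assignment (no LAI score)")
  s <- scores[!excluded, , drop = FALSE]
  hi_lai <- s$lai >= cutoffs$lai_cutoff
  hi_lad <- s$lad >= cutoffs$lad_cutoff
  q <- dplyr::case_when(
    hi_lai & hi_lad ~ "established",
    !hi_lai & hi_lad ~ "humble",
    hi_lai & !hi_lad ~ "aspirational",
    TRUE ~ "latent"
  )
  out <- tibble::tibble(
    actor_id = s$actor_id, role = s$role, lai = s$lai, lad = s$lad,
    quadrant = factor(q, levels = .lm_quadrants)
  )
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Quadrant distribution table
#'
#' Tabulates quadrant membership in the reporting layout: per quadrant the
#' overall count with its percentage of all classified actors, per-role counts
#' with percentages within the quadrant, and — for residents — counts with
#' percentages of all classified residents (the "x of 46 residents" shares).
#' Percentages are rounded half-up to one decimal.
#'
#' @param assignments output of [classify_quadrants()].
#' @return list with tibbles `by_quadrant` (long: `quadrant`, `group`, `n`,
#'   `pct`, `pct_basis`) and `resident_shares` (`quadrant`, `n`, `pct` over
#'   residents).
#' @export
distribution_table <- function(assignments) {
  stopifnot(nrow(assignments) > 0)
  n_all <- nrow(assignments)
  roles_present <- intersect(.lm_roles, unique(assignments$role))
  rows <- list()
  for (q in .lm_quadrants) {
    in_q <- assignments$quadrant == q
    n_q <- sum(in_q)
    rows[[length(rows) + 1]] <- tibble::tibble(
      quadrant = q, group = "all", n = n_q,
      pct = pct_share(n_q, n_all), pct_basis = "of classified actors"
    )
    for (r in roles_present) {
      n_qr <- sum(in_q & assignments$role == r)
      rows[[length(rows) + 1]] <- tibble::tibble(
        quadrant = q, group = r, n = n_qr,
        pct = if (n_q > 0) pct_share(n_qr, n_q) else NA_real_,
        pct_basis = "within quadrant"
      )
    }
  }
  res <- assignments[assignments$role %in% .lm_resident_roles, , drop = FALSE]
  resident_shares <- tibble::tibble(
    quadrant = .lm_quadrants,
    n = unname(vapply(.lm_quadrants, function(q) sum(res$quadrant == q), 0L)),
    pct = unname(vapply(.lm_quadrants, function(q)
      if (nrow(res) > 0) pct_share(sum(res$quadrant == q), nrow(res))
      else NA_real_, 0))
  )
  list(by_quadrant = dplyr::bind_rows(rows), resident_shares = resident_shares)
}

#' Network-boundary sensitivity of quadrant assignment
#'
#' Runs the whole pipeline (adjacency, centralities with boundary-specific
#' rescaling, LAD, cut-offs, classification) under the full boundary and under
#' the residents-only boundary, then compares resident assignments. Per-actor
#' LAI values are frozen across boundaries (self-perception does not depend on
#' who is in the network) but both cut-offs are recomputed over the boundary's
#' actors. Style weights are an exogenous preceptor-elicited input and are not
#' re-derived.
#'
#' @param ds a `survey_dataset` containing both preceptors and residents.
#' @param w a `style_weights` object.
#' @param closeness_variant,weighted passed down to the centrality engine.
#' @return list: `full` and `residents_only` (each with `scores`, `cutoffs`,
#'   `assignments`), `per_resident` (tibble `actor_id`, `role`,
#'   `quadrant_full`, `quadrant_residents_only`, `moved`), `transitions`
#'   (4x4 count matrix, full boundary in rows) and `stability_share`.
#' @export
boundary_sensitivity <- function(ds, w,
                                 closeness_variant = c("harmonic", "freeman"),
                                 weighted = FALSE) {
  stopifnot(inherits(ds, "survey_dataset"))
  closeness_variant <- match.arg(closeness_variant)
  if (!any(ds$actors$role == "preceptor") ||
      !any(ds$actors$role %in% .lm_resident_roles))
    stop("boundary sensitivity needs both preceptors and residents",
         call. = FALSE)
  A_full <- build_adjacency(ds)
  run_one <- function(A) {
    scores <- score_cohort(ds, A, w, closeness_variant, weighted)
    cutoffs <- compute_cutoffs(scores)
    list(scores = scores, cutoffs = cutoffs,
         assignments = classify_quadrants(scores, cutoffs))
  }
  full <- run_one(A_full)
  res <- run_one(restrict_boundary(A_full, .lm_resident_roles))

  per_resident <- dplyr::inner_join(
    dplyr::filter(full$assignments, .data$role %in% .lm_resident_roles)[,
      c("actor_id", "role", "quadrant")],
    res$assignments[, c("actor_id", "quadrant")],
    by = "actor_id", suffix = c("_full", "_residents_only")
  )
  per_resident$moved <-
    per_resident$quadrant_full != per_resident$quadrant_residents_only
  transitions <- table(
    full = factor(per_resident$quadrant_full, levels = .lm_quadrants),
    residents_only = factor(per_resident$quadrant_residents_only,
                            levels = .lm_quadrants)
  )
  list(
    full = full, residents_only = res, per_resident = per_resident,
    transitions = unclass(transitions),
    stability_share = if (nrow(per_resident) > 0)
      sum(!per_resident$moved) / nrow(per_resident) else NA_real_
  )
}
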