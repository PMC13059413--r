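#' Run the full informal-leadership pipeline
#'
#' Orchestrates every stage: ingest (or synthetic generation), advice-network
#' construction, centrality profiles, style weights, LAD/LAI scoring, quadrant
#' classification, and — when `boundary = "both"` — the residents-only
#' sensitivity analysis. When `out_dir` is given, all artifacts are written:
#' profile/assignment/distribution CSVs, a weights CSV, a machine-readable
#' `summary.json` (cut-offs, weights, quadrant counts, stability share), and
#' optionally the scatter and sociogram figures. Outputs are deterministic:
#' the same dataset or seed yields byte-identical CSV/JSON files.
#'
#' @param ds a [survey_dataset()]; or `NULL` to generate one from
#'   `cohort_config`.
#' @param config a [cohort_config()] used when `ds` is `NULL`.
#' @param boundary `"full"`, `"residents_only"` or `"both"`.
#' @param closeness_variant `"harmonic"` or `"freeman"`.
#' @param weighted use frequency-weighted centralities (default `FALSE`).
#' @param out_dir output directory (created if needed); `NULL` for no files.
#' @param figures also render the LAI-LAD scatter and the sociogram (PNG).
#' @param fig_seed seed for the deterministic sociogram layout.
#' @return a report bundle (list): `dataset`, `weights`, and per-boundary
#'   `scores`, `cutoffs`, `assignments`, `distribution`; plus `sensitivity`
#'   when `boundary = "both"` and `truth` for synthetic runs. Invisible when
#'   writing files.
#' @export
run_pipeline <- function(ds = NULL, config = cohort_config(),
                         boundary = c("full", "residents_only", "both"),
                         closeness_variant = c("harmonic", "freeman"),
                         weighted = FALSE,
                         out_dir = NULL, figures = FALSE, fig_seed = 1L) {
  boundary <- match.arg(boundary)
  closeness_variant <- match.arg(closeness_variant)
  truth <- NULL
  if (is.null(ds)) {
    gen <- generate_cohort(config)
    ds <- gen$dataset
    truth <- gen$truth
  }
  w <- compute_style_weights(ds$ratings)
  A_full <- build_adjacency(ds)

  bundle <- list(dataset = ds, weights = w, truth = truth)
  if (boundary == "both") {
    sens <- boundary_sensitivity(ds, w, closeness_variant, weighted)
    bundle$full <- sens$full
    bundle$residents_only <- sens$residents_only
    bundle$sensitivity <- sens[c("per_resident", "transitions",
                                 "stability_share")]
  } else {
    A <- if (boundary == "residents_only")
      restrict_boundary(A_full, .lm_resident_roles) else A_full
    scores <- score_cohort(ds, A, w, closeness_variant, weighted)
    cutoffs <- compute_cutoffs(scores)
    bundle[[boundary]] <- list(scores = scores, cutoffs = cutoffs,
                               assignments = classify_quadrants(scores, cutoffs))
  }
  for (b in intersect(c("full", "residents_only"), names(bundle)))
    bundle[[b]]$distribution <- distribution_table(bundle[[b]]$assignments)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bundle(bundle, out_dir, A_full, figures, fig_seed)
    return(invisible(bundle))
  }
  bundle
}

# CSV/JSON artifact writer; kept separate so run_pipeline stays readable
write_bundle <- function(bundle, out_dir, A_full, figures, fig_seed) {
  p <- function(...) file.path(out_dir, ...)
  w <- bundle$weights
  readr::write_csv(tibble::tibble(
    style = names(w$weights),
    aggregated_score = as.numeric(w$aggregated_scores),
    weight = as.numeric(w$weights)
  ), p("weights.csv"), progress = FALSE)

  summary <- list(weights = as.list(w$weights))
  for (b in intersect(c("full", "residents_only"), names(bundle))) {
    part <- bundle[[b]]
    write_profiles(part$scores, p(paste0("scores_", b, ".csv")))
    readr::write_csv(part$assignments, p(paste0("assignments_", b, ".csv")),
                     progress = FALSE)
    readr::write_csv(part$distribution$by_quadrant,
                     p(paste0("distribution_", b, ".csv")), progress = FALSE)
    counts <- table(part$assignments$quadrant)
    summary[[b]] <- list(
      lai_cutoff = part$cutoffs$lai_cutoff,
      lad_cutoff = part$cutoffs$lad_cutoff,
      quadrant_counts = as.list(setNames(as.integer(counts), names(counts)))
    )
  }
  if (!is.null(bundle$sensitivity)) {
    tr <- as.data.frame.matrix(bundle$sensitivity$transitions)
    tr <- dplyr::bind_cols(tibble::tibble(full = rownames(tr)),
                           tibble::as_tibble(tr))
    readr::write_csv(tr, p("transitions.csv"), progress = FALSE)
    readr::write_csv(bundle$sensitivity$per_resident, p("per_resident.csv"),
                     progress = FALSE)
    summary$stability_share <- bundle$sensitivity$stability_share
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_edge_list(A_full, p("edge_list.csv"))

  if (figures) {
    part <- bundle$full %||% bundle$residents_only
    render_scatter(part$assignments, attr(part$assignments, "cutoffs"),
                   p("lai_lad_scatter.png"))
    render_sociogram(A_full, p("sociogram.png"), seed = fig_seed)
  }
  invisible(out_dir)
}

#' LAI-LAD scatter plot with quadrant partition
#'
#' Plots each classified actor by LAI (horizontal) and LAD (vertical) score,
#' with dashed reference lines at the two sample-mean cut-offs partitioning
#' the plane into the four leadership quadrants, and role-coded markers
#' (squares for preceptors, circles for residents).
#'
#' @param assignments output of [classify_quadrants()].
#' @param cutoffs a `lead_cutoffs` object.
#' @param path optional PNG path; when given the figure is written and the
#'   plot object returned invisibly.
#' @return a `ggplot` object.
#' @export
render_scatter <- function(assignments, cutoffs, path = NULL) {
  stopifnot(nrow(assignments) > 0, inherits(cutoffs, "lead_cutoffs"))
  df <- dplyr::mutate(assignments,
    group = ifelse(.data$role == "preceptor", "preceptor", "resident"))
  plt <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lai, y = .data$lad)) +
    ggplot2::geom_vline(xintercept = cutoffs$lai_cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cutoffs$lad_cutoff, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$group,
                                     colour = .data$quadrant), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(preceptor = 15, resident = 16)) +
    ggplot2::coord_cartesian(xlim = c(1, 5), ylim = c(1, 5)) +
    ggplot2::labs(x = "Leadership-as-Imagined (LAI)",
                  y = "Leadership-as-Done (LAD)",
                  shape = "Role", colour = "Quadrant") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, plt, width = 7, height = 5.5, dpi = 150)
    return(invisible(plt))
  }
  plt
}

#' Sociogram of the advice network
#'
#' Directed network drawing with square blue markers for preceptors and round
#' red markers for residents. The force-directed layout is seeded, so the same
#' seed always yields identical coordinates.
#'
#' @param A an `advice_matrix`.
#' @param path optional PNG path.
#' @param seed layout seed.
#' @return the layout coordinate matrix, invisibly.
#' @export
render_sociogram <- function(A, path = NULL, seed = 1L) {
  stopifnot(inherits(A, "advice_matrix"))
  if (nrow(A$matrix) == 0) stop("empty network", call. = FALSE)
  g <- as_advice_graph(A)
  is_prec <- A$actors$role == "preceptor"
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  draw <- function() {
    igraph::plot.igraph(
      g, layout = lay,
      vertex.shape = ifelse(is_prec, "square", "circle"),
      vertex.color = ifelse(is_prec, "steelblue", "indianred"),
      vertex.size = 7, vertex.label.cex = 0.5, vertex.label.color = "black",
      edge.arrow.size = 0.2, edge.color = grDevices::grey(0.6)
    )
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 1000, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(lay)
}
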