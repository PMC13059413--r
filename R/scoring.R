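#' Style importance weights from preceptor ratings
#'
#' Each preceptor ranks the four leadership styles from 1 (most important) to
#' 4 (least important), ties allowed. Ranks are mapped through the reciprocal
#' values 1 -> 1.00, 2 -> 0.50, 3 -> 0.33, 4 -> 0.25 (the two-decimal
#' constants are part of the elicitation rule), summed per style across
#' raters, and normalized by the grand total so the weights sum to 1.
#'
#' @param ratings tibble with columns `rater_id`, `relational`,
#'   `transformational`, `adaptive`, `resilient` (integer ranks 1-4), e.g. the
#'   `ratings` element of a [survey_dataset()].
#' @return object of class `style_weights`: list with `weights` (named, sums
#'   to 1), `aggregated_scores` (pre-normalization per-style sums) and
#'   `grand_total`.
#' @export
#' @examples
#' r <- tibble::tibble(rater_id = "p1", relational = 1L,
#'                     transformational = 2L, adaptive = 3L, resilient = 4L)
#' compute_style_weights(r)
compute_style_weights <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  if (nrow(ratings) == 0) stop("no importance ratings provided", call. = FALSE)
  miss <- setdiff(.lm_styles, names(ratings))
  if (length(miss) > 0)
    stop("ratings table is missing style column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  agg <- vapply(.lm_styles, function(s) {
    v <- ratings[[s]]
    if (any(is.na(v) | !v %in% 1:4))
      stop("ratings must be integers in 1..4 (column ", s, ")", call. = FALSE)
    sum(.lm_rank_values[as.character(v)])
  }, 0)
  total <- sum(agg)
  w <- agg / total
  stopifnot(abs(sum(w) - 1) < 1e-9)
  structure(list(weights = w, aggregated_scores = agg, grand_total = total),
            class = "style_weights")
}

#' @export
print.style_weights <- function(x, ...) {
  cat("<style_weights> grand total ", format(x$grand_total), "\n", sep = "")
  for (s in names(x$weights))
    cat(sprintf("  %-16s %6.2f  ->  w = %.4f\n", s,
                x$aggregated_scores[[s]], x$weights[[s]]))
  invisible(x)
}

#' Construct style weights directly from known values
#'
#' Convenience constructor for working with published weight vectors (e.g.
#' relational 0.29, transformational 0.28, adaptive 0.23, resilient 0.20)
#' without the underlying rating table. Values are normalized to sum to 1.
#'
#' @param weights named numeric vector over the four styles.
#' @return a `style_weights` object (aggregated scores equal the normalized
#'   weights, grand total 1).
#' @export
style_weights <- function(weights) {
  miss <- setdiff(.lm_styles, names(weights))
  if (length(miss) > 0)
    stop("weights must be named by the four styles; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  w <- weights[.lm_styles] / sum(weights[.lm_styles])
  structure(list(weights = w, aggregated_scores = w, grand_total = 1),
            class = "style_weights")
}

# weighted components in style order for a named vector of style-keyed values
style_components <- function(values, w) {
  stopifnot(inherits(w, "style_weights"))
  w$weights[.lm_styles] * values[.lm_styles]
}

#' Leadership-as-Done (LAD) composite scores
#'
#' For each actor, the composite leadership score is the weighted sum of the
#' four rescaled centrality proxies,
#' `LS_k = sum_i w_i * n_ik`, with `n_ik` the 1-5 rescaled metric proxying
#' style i (see [style_proxy_map()]). The reported dispersion is the sample
#' standard deviation (n-1 denominator) of the four weighted components
#' `w_i * n_ik`, describing how evenly an actor's leadership is spread across
#' styles.
#'
#' @param profiles tibble with columns `actor_id` and the four
#'   `*_rescaled` metrics (as from [centrality_profiles()]).
#' @param w a `style_weights` object.
#' @return tibble: `actor_id`, `lad`, `lad_sd`, plus one `lad_comp_<style>`
#'   column per style.
#' @export
lad_score <- function(profiles, w) {
  stopifnot(inherits(w, "style_weights"))
  cols <- paste0(.lm_style_metric, "_rescaled")
  miss <- setdiff(cols, names(profiles))
  if (length(miss) > 0)
    stop("missing rescaled metric(s) for style(s): ",
         paste(.lm_styles[match(miss, paste0(.lm_style_metric, "_rescaled"))],
               collapse = ", "), call. = FALSE)
  comp <- sapply(.lm_styles, function(s)
    w$weights[[s]] * profiles[[paste0(.lm_style_metric[[s]], "_rescaled")]])
  comp <- matrix(comp, ncol = 4,
                 dimnames = list(NULL, paste0("lad_comp_", .lm_styles)))
  out <- tibble::tibble(
    actor_id = profiles$actor_id,
    lad = as.numeric(rowSums(comp)),
    lad_sd = apply(comp, 1, sd)
  )
  dplyr::bind_cols(out, tibble::as_tibble(comp))
}

#' Leadership-as-Imagined (LAI) scores
#'
#' For each actor with a complete eight-item block, the two items of each
#' style are averaged, each style mean is multiplied by its importance weight,
#' and the four weighted means are summed. Actors with incomplete blocks get
#' `lai_defined = FALSE` and no score. The dispersion is the sample standard
#' deviation of the four weighted components, as for [lad_score()].
#'
#' @param likert tibble with `actor_id` and `likert_1` ... `likert_8` (items
#'   1-2 relational, 3-4 transformational, 5-6 adaptive, 7-8 resilient).
#' @param w a `style_weights` object.
#' @return tibble: `actor_id`, `lai`, `lai_sd`, `lai_defined`.
#' @export
lai_score <- function(likert, w) {
  stopifnot(inherits(w, "style_weights"))
  lik_cols <- paste0("likert_", 1:8)
  items <- as.matrix(likert[, lik_cols])
  n <- nrow(items)
  lai <- lai_sd <- rep(NA_real_, n)
  defined <- rowSums(!is.na(items)) == 8
  for (i in which(defined)) {
    style_means <- vapply(.lm_styles, function(s)
      mean(items[i, .lm_item_styles == s]), 0)
    comp <- style_components(style_means, w)
    lai[i] <- sum(comp)
    lai_sd[i] <- sd(comp)
  }
  tibble::tibble(actor_id = likert$actor_id, lai = lai, lai_sd = lai_sd,
                 lai_defined = defined)
}

#' Score a cohort: LAD and LAI profiles over a network boundary
#'
#' Computes centrality profiles on `A`, the LAD composite for every actor in
#' `A`'s boundary, and the LAI score for those with complete Likert blocks
#' (actors with incomplete blocks remain in the LAD analysis but are flagged
#' `lai_defined = FALSE`).
#'
#' @param ds the `survey_dataset` supplying Likert blocks.
#' @param A an `advice_matrix` (any boundary).
#' @param w a `style_weights` object.
#' @param closeness_variant,weighted passed to [centrality_profiles()].
#' @return tibble with one row per actor of `A`: role, raw and rescaled
#'   metrics, `lad`, `lad_sd`, `lai`, `lai_sd`, `lai_defined`; `boundary`
#'   attribute preserved.
#' @export
score_cohort <- function(ds, A, w,
                         closeness_variant = c("harmonic", "freeman"),
                         weighted = FALSE) {
  stopifnot(inherits(ds, "survey_dataset"), inherits(A, "advice_matrix"))
  profiles <- centrality_profiles(A, closeness_variant, weighted)
  lad <- lad_score(profiles, w)
  lai <- lai_score(ds$likert, w)
  n_inelig <- sum(!lai$lai_defined[lai$actor_id %in% profiles$actor_id])
  if (n_inelig > 0)
    message(n_inelig,
            " actor(s) with incomplete Likert blocks: LAD only, no LAI score")
  out <- dplyr::left_join(profiles,
                          lad[, c("actor_id", "lad", "lad_sd")],
                          by = "actor_id")
  out <- dplyr::left_join(out, lai, by = "actor_id")
  out$lai_defined[is.na(out$lai_defined)] <- FALSE
  attr(out, "boundary") <- A$boundary
  out
}
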