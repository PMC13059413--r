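#' Raw centrality metrics of the advice network
#'
#' The four node metrics used as leadership-style proxies. All are computed on
#' the binarized network by default: the in-degree narrative of a roster
#' survey counts distinct nominators, and geodesic metrics on raw frequencies
#' would need an arbitrary weight-to-distance transform. Frequency-weighted
#' variants are available via `weighted = TRUE` (in-degree becomes the
#' frequency sum; geodesics use distance 1/frequency).
#'
#' * `in_degree()`: number of distinct actors nominating the node.
#' * `betweenness_centrality()`: sum over ordered pairs (s, t) of the share of
#'   shortest directed s->t paths passing through the node; unreachable pairs
#'   contribute 0.
#' * `closeness_centrality()`: by default harmonic closeness normalized to
#'   \[0, 1\] — for `direction = "out"`, `(1/(n-1)) * sum(1/d(v, u))` with
#'   `1/Inf = 0`; `direction = "in"` reverses the distances. Harmonic closeness
#'   stays defined for actors with no incoming (or outgoing) paths, which occur
#'   in real advice networks. `variant = "freeman"` gives the classic
#'   closeness computed on the reachable set, rescaled by the reachable share
#'   (Wasserman-Faust form).
#'
#' @param A an `advice_matrix`.
#' @param weighted use frequency weights (default `FALSE`).
#' @param direction `"in"` or `"out"` (closeness only).
#' @param variant `"harmonic"` (default) or `"freeman"` (closeness only).
#' @return named numeric vector over the actors of `A`.
#' @export
in_degree <- function(A, weighted = FALSE) {
  stopifnot(inherits(A, "advice_matrix"))
  m <- A$matrix
  if (weighted) colSums(m) else colSums(m > 0)
}

#' @rdname in_degree
#' @export
betweenness_centrality <- function(A, weighted = FALSE) {
  stopifnot(inherits(A, "advice_matrix"))
  g <- as_advice_graph(A, weighted = weighted)
  w <- if (weighted && igraph::ecount(g) > 0) 1 / igraph::E(g)$weight else NULL
  b <- igraph::betweenness(g, directed = TRUE, weights = w)
  setNames(as.numeric(b), A$actors$actor_id)
}

#' @rdname in_degree
#' @export
closeness_centrality <- function(A, direction = c("in", "out"),
                                 variant = c("harmonic", "freeman"),
                                 weighted = FALSE) {
  stopifnot(inherits(A, "advice_matrix"))
  direction <- match.arg(direction)
  variant <- match.arg(variant)
  n <- nrow(A$matrix)
  if (n < 2) stop("closeness undefined for fewer than 2 actors", call. = FALSE)
  g <- as_advice_graph(A, weighted = weighted)
  w <- if (weighted && igraph::ecount(g) > 0) 1 / igraph::E(g)$weight else NULL
  if (variant == "harmonic") {
    v <- igraph::harmonic_centrality(g, mode = direction, weights = w,
                                     normalized = TRUE)
    return(setNames(as.numeric(v), A$actors$actor_id))
  }
  # Freeman closeness on the reachable set, scaled by the reachable share so
  # that poorly reachable nodes are not rewarded for a tiny reachable set
  d <- igraph::distances(g, mode = direction, weights = w)
  val <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    finite <- is.finite(di)
    r <- sum(finite)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(di[finite]))
  }, 0)
  setNames(val, A$actors$actor_id)
}

#' Rescale a raw metric onto the 1-5 Likert scale
#'
#' Affine min-max rescaling `x -> 1 + 4 * (x - min) / (max - min)`, so the
#' raw minimum maps to 1 and the raw maximum to 5, making centralities
#' commensurate with the 5-point self-perception items before weighting. A
#' constant vector maps to the mid-scale value 3 (with a warning) so the
#' composite score stays defined.
#'
#' @param x numeric vector (length >= 2).
#' @return rescaled vector in \[1, 5\].
#' @export
rescale_likert <- function(x) {
  if (length(x) == 0) stop("cannot rescale an empty vector", call. = FALSE)
  if (length(x) < 2) stop("rescaling needs at least 2 values", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant metric: all values rescaled to mid-scale 3",
            call. = FALSE)
    return(setNames(rep(3, length(x)), names(x)))
  }
  1 + 4 * (x - rng[1]) / (rng[2] - rng[1])
}

#' Per-actor centrality profiles with style-keyed rescaled metrics
#'
#' Computes the four raw centralities on `A`, rescales each onto 1-5 across
#' the actors of `A`'s boundary (so a residents-only network is rescaled
#' against residents-only extremes), and returns one row per actor. Rescaled
#' columns are the `n_ik` inputs of the composite leadership score, keyed to
#' styles through [style_proxy_map()].
#'
#' @param A an `advice_matrix`.
#' @param closeness_variant `"harmonic"` (default) or `"freeman"`.
#' @param weighted use frequency weights for the raw metrics (default
#'   `FALSE`).
#' @return tibble: `actor_id`, `role`, raw columns (`in_degree`,
#'   `betweenness`, `out_closeness`, `in_closeness`) and `*_rescaled`
#'   counterparts, plus a `boundary` attribute.
#' @export
centrality_profiles <- function(A, closeness_variant = c("harmonic", "freeman"),
                                weighted = FALSE) {
  stopifnot(inherits(A, "advice_matrix"))
  closeness_variant <- match.arg(closeness_variant)
  B <- if (weighted) A else binarize(A)
  raw <- list(
    in_degree = in_degree(B, weighted = weighted),
    betweenness = betweenness_centrality(B, weighted = weighted),
    out_closeness = closeness_centrality(B, "out", closeness_variant,
                                         weighted = weighted),
    in_closeness = closeness_centrality(B, "in", closeness_variant,
                                        weighted = weighted)
  )
  out <- tibble::tibble(actor_id = A$actors$actor_id, role = A$actors$role)
  for (nm in names(raw)) {
    out[[nm]] <- as.numeric(raw[[nm]])
    out[[paste0(nm, "_rescaled")]] <- as.numeric(rescale_likert(raw[[nm]]))
  }
  attr(out, "boundary") <- A$boundary
  out
}

#' Write centrality profiles to CSV
#'
#' Raw metrics at full precision; rescaled metrics additionally provided as
#' two-decimal display columns (round half-up), matching the reporting
#' convention.
#'
#' @param profiles output of [centrality_profiles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  for (nm in grep("_rescaled$", names(out), value = TRUE))
    out[[paste0(nm, "_2dp")]] <- round_half_up(out[[nm]], 2)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
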