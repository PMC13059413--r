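#' Build the directed advice adjacency matrix
#'
#' Cell `x[j, k]` holds how frequently actor j sought advice from actor k
#' (0 where no nomination exists). Duplicate (source, target) nominations are
#' summed with a warning; the diagonal is structurally zero.
#'
#' @param ds a validated [survey_dataset()].
#' @return object of class `advice_matrix`: list with `matrix` (named integer
#'   matrix), `actors` (tibble `actor_id`, `role` in matrix order) and
#'   `boundary` (`"full"` until restricted).
#' @export
build_adjacency <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  ids <- ds$actors$actor_id
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  noms <- ds$nominations
  unknown <- !(noms$source_id %in% ids & noms$target_id %in% ids)
  if (any(unknown))
    stop("nominations reference actors absent from the roster", call. = FALSE)
  if (anyDuplicated(noms[, c("source_id", "target_id")]) > 0)
    warning("duplicate nominations for the same (source, target) pair summed",
            call. = FALSE)
  for (i in seq_len(nrow(noms))) {
    j <- noms$source_id[i]; k <- noms$target_id[i]
    if (j == k) next
    m[j, k] <- m[j, k] + noms$frequency[i]
  }
  new_advice_matrix(m, ds$actors[, c("actor_id", "role")], "full")
}

new_advice_matrix <- function(m, actors, boundary) {
  stopifnot(nrow(m) == ncol(m), nrow(m) == nrow(actors))
  if (any(diag(m) != 0)) stop("advice matrix must have a zero diagonal")
  structure(list(matrix = m, actors = tibble::as_tibble(actors),
                 boundary = boundary),
            class = "advice_matrix")
}

#' @export
print.advice_matrix <- function(x, ...) {
  cat("<advice_matrix> ", nrow(x$matrix), " actors, ",
      sum(x$matrix > 0), " ties, boundary: ", x$boundary, "\n", sep = "")
  invisible(x)
}

#' Binarize an advice matrix
#'
#' Maps every positive frequency to 1, preserving the boundary tag. Idempotent.
#'
#' @param A an `advice_matrix`.
#' @return an `advice_matrix` with entries in \{0, 1\}.
#' @export
binarize <- function(A) {
  stopifnot(inherits(A, "advice_matrix"))
  m <- (A$matrix > 0) * 1L
  dimnames(m) <- dimnames(A$matrix)
  new_advice_matrix(m, A$actors, A$boundary)
}

#' Restrict an advice network to a set of roles
#'
#' Keeps only actors (and hence ties) whose role is in `keep_roles`. Restricting
#' to the resident roles tags the result `"residents_only"`; this is the
#' network-boundary manipulation behind the sensitivity analysis.
#'
#' @param A an `advice_matrix`.
#' @param keep_roles character vector of roles to keep.
#' @return the restricted `advice_matrix`.
#' @export
restrict_boundary <- function(A, keep_roles) {
  stopifnot(inherits(A, "advice_matrix"), length(keep_roles) > 0)
  keep <- A$actors$role %in% keep_roles
  if (!any(keep)) stop("boundary restriction leaves an empty network",
                       call. = FALSE)
  if (all(keep)) return(A)
  tag <- if (setequal(intersect(keep_roles, .lm_roles), .lm_resident_roles))
    "residents_only" else "restricted"
  new_advice_matrix(A$matrix[keep, keep, drop = FALSE],
                    A$actors[keep, , drop = FALSE], tag)
}

#' Tie counts, role involvement and density
#'
#' Ties are counted as nonzero cells (arcs). For each role the count and share
#' of ties with source or target of that role is reported, reproducing the
#' "ties involving preceptors" bookkeeping of the boundary comparison.
#'
#' @param A an `advice_matrix`.
#' @return list: `n_ties`, `density` (arcs over n(n-1)), `n_involving` and
#'   `share_involving` (named by role).
#' @export
tie_stats <- function(A) {
  stopifnot(inherits(A, "advice_matrix"))
  n <- nrow(A$matrix)
  if (n < 2) stop("density undefined for fewer than 2 actors", call. = FALSE)
  idx <- which(A$matrix > 0, arr.ind = TRUE)
  n_ties <- nrow(idx)
  roles_present <- unique(A$actors$role)
  role_of <- setNames(A$actors$role, A$actors$actor_id)
  src_role <- A$actors$role[idx[, 1]]
  tgt_role <- A$actors$role[idx[, 2]]
  n_inv <- vapply(roles_present, function(r)
    sum(src_role == r | tgt_role == r), 0L)
  list(
    n_ties = n_ties,
    density = n_ties / (n * (n - 1)),
    n_involving = n_inv,
    share_involving = if (n_ties > 0) n_inv / n_ties else
      setNames(rep(NA_real_, length(roles_present)), roles_present)
  )
}

#' Convert an advice matrix to an igraph graph
#'
#' @param A an `advice_matrix`.
#' @param weighted keep frequencies as edge weights (default `FALSE`: binary
#'   arcs).
#' @return a directed `igraph` graph with `role` vertex attribute.
#' @export
as_advice_graph <- function(A, weighted = FALSE) {
  stopifnot(inherits(A, "advice_matrix"))
  m <- if (weighted) A$matrix else (A$matrix > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(
    m, mode = "directed", weighted = if (weighted) TRUE else NULL
  )
  igraph::V(g)$role <- A$actors$role
  g
}

#' Export an advice network
#'
#' `write_edge_list()` writes a `source,target,frequency` CSV;
#' `write_ucinet_dl()` writes a UCINET DL full-matrix file with embedded
#' labels; `write_advice_graphml()` writes GraphML (role carried as a node
#' attribute) for visualization tools.
#'
#' @param A an `advice_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(A, path) {
  stopifnot(inherits(A, "advice_matrix"))
  idx <- which(A$matrix > 0, arr.ind = TRUE)
  el <- tibble::tibble(
    source = rownames(A$matrix)[idx[, 1]],
    target = colnames(A$matrix)[idx[, 2]],
    frequency = A$matrix[idx]
  )
  el <- dplyr::arrange(el, .data$source, .data$target)
  readr::write_csv(el, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_ucinet_dl <- function(A, path) {
  stopifnot(inherits(A, "advice_matrix"))
  n <- nrow(A$matrix)
  lines <- c(
    sprintf("dl n=%d format=fullmatrix", n),
    "labels:",
    paste(rownames(A$matrix), collapse = ","),
    "data:",
    apply(A$matrix, 1, paste, collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_advice_graphml <- function(A, path) {
  g <- as_advice_graph(A, weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an edge-list CSV back into an advice matrix
#'
#' @param path edge-list CSV (`source,target,frequency`).
#' @param actors tibble `actor_id`, `role` giving the full roster and order
#'   (isolates carry no edges, so the roster cannot be inferred from edges).
#' @return an `advice_matrix`.
#' @export
read_edge_list <- function(path, actors) {
  el <- readr::read_csv(path, col_types = readr::cols(
    source = readr::col_character(), target = readr::col_character(),
    frequency = readr::col_integer()
  ), progress = FALSE)
  ids <- actors$actor_id
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(el))) m[el$source[i], el$target[i]] <- el$frequency[i]
  new_advice_matrix(m, actors, "full")
}
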