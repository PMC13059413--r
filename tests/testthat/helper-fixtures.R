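# Shared fixtures and independent oracles, all built in code.

# minimal well-formed dataset: 3 actors, 2 nominations, full Likert blocks
tiny_dataset <- function() {
  survey_dataset(
    actors = tibble::tibble(
      actor_id = c("a", "b", "c"),
      role = c("preceptor", "R1", "R2"),
      gender = c("female", "male", "female"),
      years_doctor_band = c(">10", "1-2", "2-3"),
      years_specialty_band = c(">10", "<1", "1-2")
    ),
    nominations = tibble::tibble(
      source_id = c("a", "b"), target_id = c("b", "c"), frequency = c(2L, 1L)
    ),
    likert = tibble::tibble(
      actor_id = c("a", "b", "c"),
      likert_1 = c(5L, 3L, 2L), likert_2 = c(4L, 3L, 2L),
      likert_3 = c(5L, 4L, 1L), likert_4 = c(5L, 2L, 3L),
      likert_5 = c(4L, 3L, 2L), likert_6 = c(4L, 4L, 2L),
      likert_7 = c(5L, 3L, 1L), likert_8 = c(3L, 3L, 2L)
    ),
    ratings = tibble::tibble(
      rater_id = "a", relational = 1L, transformational = 2L,
      adaptive = 3L, resilient = 4L
    )
  )
}

# advice matrix straight from a 0/1-or-frequency matrix and roles
matrix_to_advice <- function(m, roles = NULL) {
  n <- nrow(m)
  ids <- paste0("v", seq_len(n))
  dimnames(m) <- list(ids, ids)
  if (is.null(roles)) roles <- rep("R1", n)
  leadmap:::new_advice_matrix(
    m, tibble::tibble(actor_id = ids, role = roles), "full"
  )
}

# random binary digraph adjacency with zero diagonal
random_digraph <- function(n, p = 0.4) {
  m <- matrix(rbinom(n * n, 1, p), n, n)
  diag(m) <- 0L
  m
}

# Independent betweenness oracle: exhaustive enumeration of all simple paths
# between every ordered pair, restricted to the shortest ones. O(n!) — only
# for graphs with <= ~7 nodes.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  res <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    visited <- rep(FALSE, n)
    rec <- function(v, path) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (u in which(adj[v, ] > 0)) {
        if (!visited[u]) {
          visited[u] <<- TRUE
          rec(u, c(path, u))
          visited[u] <<- FALSE
        }
      }
    }
    visited[s] <- TRUE
    rec(s, s)
    paths
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, 0L)
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(shortest, function(p) v %in% p, TRUE))
      res[v] <- res[v] + through / sigma
    }
  }
  res
}

expect_dataset_equal <- function(a, b) {
  for (part in c("actors", "nominations", "likert", "ratings")) {
    expect_equal(as.data.frame(a[[part]]), as.data.frame(b[[part]]),
                 ignore_attr = TRUE)
  }
}

# published top-10 composite-score table used as a recomputable fixture:
# rescaled metrics, printed LS and printed component SD
published_lad_rows <- function() {
  tibble::tribble(
    ~actor_id, ~in_degree_rescaled, ~betweenness_rescaled,
    ~out_closeness_rescaled, ~in_closeness_rescaled, ~ls_printed, ~sd_printed,
    "P9",    3.31, 5.00, 4.26, 3.06, 3.97, 0.35,
    "P12",   4.02, 4.05, 4.56, 2.59, 3.87, 0.30,
    "R2.14", 2.42, 4.86, 3.27, 5.00, 3.84, 0.33,
    "P4",    4.56, 3.34, 4.78, 2.28, 3.80, 0.35,
    "P21",   4.73, 2.18, 4.83, 1.94, 3.46, 0.43,
    "P7",    5.00, 1.46, 5.00, 1.65, 3.31, 0.53,
    "R2.5",  2.07, 3.50, 3.63, 3.63, 3.16, 0.18,
    "R2.3",  2.78, 2.21, 3.50, 2.99, 2.82, 0.10,
    "R1.6",  1.62, 2.30, 3.06, 4.54, 2.74, 0.19,
    "R1.8",  1.98, 2.50, 3.50, 3.13, 2.71, 0.11
  )
}

published_weights <- function() {
  style_weights(c(relational = 0.29, transformational = 0.28,
                  adaptive = 0.23, resilient = 0.20))
}
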