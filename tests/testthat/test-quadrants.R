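make_scores <- function(lai, lad, roles = NULL, boundary = "full") {
  n <- length(lai)
  s <- tibble::tibble(
    actor_id = paste0("x", seq_len(n)),
    role = roles %||% rep("R1", n),
    lad = lad, lad_sd = 0, lai = lai, lai_sd = 0,
    lai_defined = !is.na(lai)
  )
  attr(s, "boundary") <- boundary
  s
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cut-offs are the sample means of the defined scores", {
  s <- make_scores(lai = c(4, 5), lad = c(2, 3))
  cut <- compute_cutoffs(s)
  expect_equal(cut$lai_cutoff, 4.5)
  expect_equal(cut$lad_cutoff, 2.5)
  expect_equal(cut$boundary, "full")
  expect_error(compute_cutoffs(make_scores(lai = 4, lad = 2)), "at least 2")
})

test_that("classification follows the boundary-inclusive quadrant rules", {
  cut <- structure(list(lai_cutoff = 4.20, lad_cutoff = 2.22,
                        boundary = "full"), class = "lead_cutoffs")
  s <- make_scores(lai = c(4.20, 3.0, 4.5, 3.5), lad = c(2.22, 1.5, 2.0, 3.0))
  asg <- classify_quadrants(s, cut)
  expect_equal(as.character(asg$quadrant),
               c("established", "latent", "aspirational", "humble"))

  # actors without a defined LAI are excluded with a note
  s2 <- make_scores(lai = c(4.5, NA), lad = c(3, 3))
  expect_message(asg2 <- classify_quadrants(s2, cut), "excluded")
  expect_equal(nrow(asg2), 1)
})

test_that("quadrant labels partition the classified actors", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    sc <- make_scores(lai = runif(n, 1, 5), lad = runif(n, 1, 5),
                      roles = sample(c("preceptor", "R1", "R2"), n, TRUE))
    asg <- classify_quadrants(sc, compute_cutoffs(sc))
    expect_equal(sum(table(asg$quadrant)), n)
  }
})

test_that("raising LAD can only promote along the LAD axis", {
  cut <- structure(list(lai_cutoff = 3, lad_cutoff = 3, boundary = "full"),
                   class = "lead_cutoffs")
  set.seed(8)
  for (i in 1:40) {
    lai <- runif(1, 1, 5); lad <- runif(1, 1, 5)
    before <- classify_quadrants(make_scores(lai, lad), cut)$quadrant
    after <- classify_quadrants(make_scores(lai, min(lad + runif(1, 0, 2), 5)),
                                cut)$quadrant
    legal <- list(
      latent = c("latent", "humble"),
      aspirational = c("aspirational", "established"),
      humble = "humble",
      established = "established"
    )
    expect_true(as.character(after) %in% legal[[as.character(before)]])
  }
})

test_that("distribution table reproduces the reporting layout percentages", {
  # full-cohort fixture with the published quadrant x role counts
  counts <- list(
    established = c(preceptor = 8, R1 = 3, R2 = 3, R3 = 1),
    humble = c(preceptor = 1, R1 = 5, R2 = 6, R3 = 0),
    aspirational = c(preceptor = 10, R1 = 2, R2 = 8, R3 = 0),
    latent = c(preceptor = 3, R1 = 12, R2 = 6, R3 = 0)
  )
  rows <- do.call(rbind, lapply(names(counts), function(q) {
    do.call(rbind, lapply(names(counts[[q]]), function(r) {
      k <- counts[[q]][[r]]
      if (k == 0) return(NULL)
      data.frame(role = rep(r, k), quadrant = rep(q, k))
    }))
  }))
  asg <- tibble::tibble(
    actor_id = paste0("a", seq_len(nrow(rows))),
    role = rows$role, lai = 0, lad = 0,
    quadrant = factor(rows$quadrant,
                      levels = c("established", "humble", "aspirational",
                                 "latent"))
  )
  dist <- distribution_table(asg)
  rs <- dist$resident_shares
  expect_equal(rs$n, c(7L, 11L, 10L, 18L))
  expect_equal(rs$pct, c(15.2, 23.9, 21.7, 39.1))
  bq <- dist$by_quadrant
  est_all <- bq[bq$quadrant == "established" & bq$group == "all", ]
  expect_equal(est_all$n, 15L)
  expect_equal(est_all$pct, 22.1)  # 15/68 of classified actors
  est_p <- bq[bq$quadrant == "established" & bq$group == "preceptor", ]
  expect_equal(est_p$pct, 53.3)    # 8/15 within the quadrant
  hum_R2 <- bq[bq$quadrant == "humble" & bq$group == "R2", ]
  expect_equal(hum_R2$pct, 50.0)
  # counts across quadrants sum to the classified actors
  expect_equal(sum(bq$n[bq$group == "all"]), 68L)
})

test_that("share formatting follows the half-up single-decimal convention", {
  expect_equal(pct_share(68, 77), 88.3)
  expect_equal(pct_share(7, 46), 15.2)
  expect_equal(pct_share(18, 46), 39.1)
  expect_equal(pct_share(35, 46), 76.1)
})

test_that("boundary sensitivity recomputes cut-offs and conserves residents", {
  gen <- generate_cohort(cohort_config(seed = 19))
  w <- compute_style_weights(gen$dataset$ratings)
  sens <- boundary_sensitivity(gen$dataset, w)
  expect_equal(sum(sens$transitions), 46)
  expect_equal(nrow(sens$per_resident), 46)
  expect_equal(sens$stability_share,
               sum(diag(sens$transitions)) / 46)
  # LAI values are frozen across boundaries, cut-offs are not
  m <- dplyr::inner_join(sens$full$scores, sens$residents_only$scores,
                         by = "actor_id", suffix = c("_f", "_r"))
  expect_equal(m$lai_f, m$lai_r)
  expect_false(isTRUE(all.equal(sens$full$cutoffs$lai_cutoff,
                                sens$residents_only$cutoffs$lai_cutoff)))
  # preceptor-attracted cohorts shift the LAD cut-off across boundaries
  expect_false(isTRUE(all.equal(sens$full$cutoffs$lad_cutoff,
                                sens$residents_only$cutoffs$lad_cutoff)))
  # full-boundary assignments equal a direct full-network run
  A <- build_adjacency(gen$dataset)
  sc <- score_cohort(gen$dataset, A, w)
  direct <- classify_quadrants(sc, compute_cutoffs(sc))
  expect_equal(as.character(sens$full$assignments$quadrant),
               as.character(direct$quadrant))
})

test_that("residents untouched by preceptor ties keep their quadrants", {
  # residents form two well-separated blocks (central vs peripheral, confident
  # vs modest); preceptors are isolated so both boundaries see the same ties
  n_res <- 12
  ids <- c(paste0("p", 1:4), paste0("r", 1:n_res))
  roles <- c(rep("preceptor", 4), rep("R1", n_res))
  central <- c(rep(FALSE, 4), rep(c(TRUE, FALSE), each = n_res / 2))
  noms <- list()
  for (j in seq_along(ids)) for (k in seq_along(ids)) {
    if (j == k || roles[j] == "preceptor" || roles[k] == "preceptor") next
    if (central[k]) noms[[length(noms) + 1]] <-
        tibble::tibble(source_id = ids[j], target_id = ids[k], frequency = 2L)
  }
  lik_val <- ifelse(central, 5L, 2L)
  lik_val[roles == "preceptor"] <- 3L
  likert <- tibble::as_tibble(
    setNames(as.data.frame(matrix(rep(lik_val, 8), ncol = 8)),
             paste0("likert_", 1:8)))
  ds <- survey_dataset(
    actors = tibble::tibble(actor_id = ids, role = roles, gender = "female",
                            years_doctor_band = "1-2",
                            years_specialty_band = "<1"),
    nominations = dplyr::bind_rows(noms),
    likert = dplyr::bind_cols(tibble::tibble(actor_id = ids), likert),
    ratings = tibble::tibble(rater_id = paste0("p", 1:4), relational = 1L,
                             transformational = 2L, adaptive = 3L,
                             resilient = 4L)
  )
  sens <- suppressWarnings(
    boundary_sensitivity(ds, compute_style_weights(ds$ratings)))
  expect_equal(sens$stability_share, 1.0)
})
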