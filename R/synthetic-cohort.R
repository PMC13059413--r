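#' Configuration for a synthetic sociometric cohort
#'
#' Parameters of the generative model used to emulate a roster advice-seeking
#' survey of an internal-medicine service. Defaults reproduce the study
#' composition this pipeline was designed around: 68 actors (22 preceptors,
#' 22 first-year, 23 second-year and 1 third-year resident) in a dense
#' directed network centralized around a subset of planted hub actors, with
#' 19 preceptor importance-rating responses.
#'
#' The network model is a planted-hub Bernoulli digraph: each ordered pair
#' (j, k), j != k, receives a tie with probability
#' `base_tie_prob * hub_tie_multiplier^[k is hub] * preceptor_attraction^[k is
#' preceptor]`, capped at 0.99. Self-perception is planted as a bimodal
#' archetype (confident vs modest responders); `alignment_rho` rank-couples
#' the planted self-perception means to centrality propensity through a
#' Gaussian copula, so `alignment_rho = 1` makes self-ratings a monotone
#' transform of network prominence.
#'
#' @param n_preceptors,n_R1,n_R2,n_R3 role counts (defaults 22/22/23/1).
#' @param base_tie_prob baseline probability of an advice tie (default 0.05).
#' @param hub_fraction fraction of actors planted as hubs (default 0.15).
#' @param hub_tie_multiplier factor (>= 1) on the incoming-tie probability of
#'   hubs (default 8).
#' @param preceptor_attraction factor (>= 1) on ties directed at preceptors
#'   (default 1.5): advice flows disproportionately toward supervisors.
#' @param frequency_model probabilities of advice frequencies 1..5 given a tie
#'   (default skewed toward occasional advice).
#' @param alignment_rho correlation in \[-1, 1\] between centrality propensity
#'   and planted self-perception (default 0.7).
#' @param likert_noise_sd item-level noise around an actor's planted style
#'   mean, on the 1-5 scale (default 0.5).
#' @param rating_concentration probability that a synthetic preceptor uses the
#'   modal style ordering (relational > transformational > adaptive >
#'   resilient) instead of rating styles independently (default 0.5).
#' @param confident_fraction fraction of actors planted as confident
#'   self-perceivers (default 0.5).
#' @param n_raters number of preceptors returning the importance-rating
#'   questionnaire (default 19, capped at `n_preceptors`).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_preceptors = 22, n_R1 = 22, n_R2 = 23, n_R3 = 1,
                          base_tie_prob = 0.05,
                          hub_fraction = 0.15,
                          hub_tie_multiplier = 8,
                          preceptor_attraction = 1.5,
                          frequency_model = c(0.35, 0.25, 0.20, 0.12, 0.08),
                          alignment_rho = 0.7,
                          likert_noise_sd = 0.5,
                          rating_concentration = 0.5,
                          confident_fraction = 0.5,
                          n_raters = 19,
                          seed = 1L) {
  counts <- c(n_preceptors, n_R1, n_R2, n_R3)
  if (any(counts < 0) || sum(counts) < 2)
    stop("degenerate cohort: role counts must be >= 0 with total >= 2",
         call. = FALSE)
  if (base_tie_prob < 0 || base_tie_prob >= 1)
    stop("base_tie_prob must lie in [0, 1)", call. = FALSE)
  if (hub_tie_multiplier < 1 || preceptor_attraction < 1)
    stop("tie multipliers must be >= 1", call. = FALSE)
  if (abs(alignment_rho) > 1)
    stop("alignment_rho must lie in [-1, 1]", call. = FALSE)
  if (length(frequency_model) != 5 || any(frequency_model < 0) ||
      sum(frequency_model) <= 0)
    stop("frequency_model must be 5 non-negative weights", call. = FALSE)
  structure(list(
    n_preceptors = n_preceptors, n_R1 = n_R1, n_R2 = n_R2, n_R3 = n_R3,
    base_tie_prob = base_tie_prob, hub_fraction = hub_fraction,
    hub_tie_multiplier = hub_tie_multiplier,
    preceptor_attraction = preceptor_attraction,
    frequency_model = frequency_model / sum(frequency_model),
    alignment_rho = alignment_rho, likert_noise_sd = likert_noise_sd,
    rating_concentration = rating_concentration,
    confident_fraction = confident_fraction,
    n_raters = min(n_raters, n_preceptors), seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_preceptors + x$n_R1 + x$n_R2 + x$n_R3,
      " actors (P=", x$n_preceptors, ", R1=", x$n_R1, ", R2=", x$n_R2,
      ", R3=", x$n_R3, "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# per-target tie probability given hub/preceptor status
tie_probability <- function(config, hub, is_preceptor) {
  p <- config$base_tie_prob *
    ifelse(hub, config$hub_tie_multiplier, 1) *
    ifelse(is_preceptor, config$preceptor_attraction, 1)
  pmin(p, 0.99)
}

#' Generate a synthetic survey cohort with planted leadership archetypes
#'
#' Draws a complete [survey_dataset()] from the generative model described in
#' [cohort_config()], together with the planted ground truth: per actor, the
#' hub flag, the planted self-perception mean, and the quadrant expected under
#' perfect alignment (`alignment_rho = 1`): hub and confident -> established;
#' hub and modest -> humble; non-hub and confident -> aspirational; otherwise
#' latent. ("Confident" means the planted self-perception mean is at or above
#' the cohort average of planted means, mirroring the sample-mean cutoff used
#' downstream.)
#'
#' @param config a [cohort_config()].
#' @return list with elements `dataset` (a `survey_dataset`) and `truth`
#'   (tibble: `actor_id`, `role`, `hub`, `propensity`, `target_mean`,
#'   `high_self`, `expected_quadrant`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  counts <- c(preceptor = config$n_preceptors, R1 = config$n_R1,
              R2 = config$n_R2, R3 = config$n_R3)
  roles <- rep(names(counts), counts)
  ids <- unlist(lapply(names(counts), function(r) {
    k <- counts[[r]]
    if (k == 0) return(character(0))
    if (r == "preceptor") paste0("P", seq_len(k)) else paste0(r, ".", seq_len(k))
  }))
  n <- length(ids)

  # demographics: marginals loosely emulating a mixed junior/senior service
  gender <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.38, 0.62))
  doctor_bands <- c("<1", "1-2", "2-3", "3-5", "6-10", ">10")
  years_doctor <- ifelse(
    roles == "preceptor",
    sample(c("6-10", ">10"), n, replace = TRUE, prob = c(0.25, 0.75)),
    sample(doctor_bands[1:4], n, replace = TRUE, prob = c(0.3, 0.45, 0.15, 0.1))
  )
  years_spec <- ifelse(
    roles == "preceptor",
    sample(c("3-5", "6-10", ">10"), n, replace = TRUE, prob = c(0.2, 0.3, 0.5)),
    sample(c("<1", "1-2", "2-3"), n, replace = TRUE, prob = c(0.55, 0.4, 0.05))
  )
  actors <- tibble::tibble(
    actor_id = ids, role = roles, gender = gender,
    years_doctor_band = years_doctor, years_specialty_band = years_spec
  )

  # planted hubs and incoming-tie probabilities
  n_hubs <- max(if (config$hub_fraction > 0) 1L else 0L,
                round(config$hub_fraction * n))
  hub <- rep(FALSE, n)
  if (n_hubs > 0) hub[sample.int(n, n_hubs)] <- TRUE
  p_in <- tie_probability(config, hub, roles == "preceptor")
  # continuous centrality propensity: log-odds of attracting ties plus a
  # small jitter to obtain a strict ordering for rank coupling
  propensity <- log(pmax(p_in, 1e-12)) + rnorm(n, 0, 0.01)

  # directed ties: P(j -> k) depends only on the target k
  tie <- matrix(rbinom(n * n, 1, rep(p_in, each = n)), n, n)
  diag(tie) <- 0L
  idx <- which(tie == 1, arr.ind = TRUE)
  nominations <- tibble::tibble(
    source_id = ids[idx[, 1]],
    target_id = ids[idx[, 2]],
    frequency = if (nrow(idx) > 0)
      sample(1:5, nrow(idx), replace = TRUE, prob = config$frequency_model)
    else integer(0)
  )
  # canonical roster order (not lexicographic), so that writing and re-reading
  # the survey preserves the row order exactly
  nominations <- nominations[order(match(nominations$source_id, ids),
                                   match(nominations$target_id, ids)), ]

  # planted self-perception: bimodal archetypes (confident vs modest), then
  # rank-coupled to centrality propensity via a Gaussian copula at alignment_rho
  confident <- runif(n) < config$confident_fraction
  target_pool <- ifelse(confident, rnorm(n, 4.5, 0.20), rnorm(n, 3.2, 0.30))
  target_pool <- pmin(pmax(target_pool, 1.2), 5)
  # complete item blocks are drawn first, then whole blocks are reassigned to
  # actors by rank-coupling their REALIZED means to centrality propensity, so
  # that alignment_rho = 1 makes observed self-rating means an exactly
  # monotone transform of propensity
  blocks <- t(vapply(target_pool, function(m) {
    as.integer(pmin(pmax(round(m + rnorm(8, 0, config$likert_noise_sd)),
                         1), 5))
  }, integer(8)))
  block_order <- order(rowMeans(blocks), target_pool)
  z_prop <- qnorm(rank(propensity, ties.method = "first") / (n + 1))
  z <- config$alignment_rho * z_prop +
    sqrt(1 - config$alignment_rho^2) * rnorm(n)
  assign <- rank(z, ties.method = "first")
  lik <- blocks[block_order, , drop = FALSE][assign, , drop = FALSE]
  target_mean <- target_pool[block_order][assign]
  likert <- tibble::as_tibble(as.data.frame(lik))
  names(likert) <- paste0("likert_", 1:8)
  likert <- dplyr::bind_cols(tibble::tibble(actor_id = ids), likert)

  # preceptor importance ratings: modal ordering with probability
  # rating_concentration, otherwise independent 1-4 ratings (ties allowed)
  raters <- ids[roles == "preceptor"]
  raters <- raters[seq_len(min(config$n_raters, length(raters)))]
  modal <- c(relational = 1L, transformational = 2L, adaptive = 3L,
             resilient = 4L)
  ratings <- dplyr::bind_rows(lapply(raters, function(r) {
    v <- if (runif(1) < config$rating_concentration) modal
         else setNames(sample(1:4, 4, replace = TRUE), .lm_styles)
    tibble::tibble(rater_id = r, relational = v[["relational"]],
                   transformational = v[["transformational"]],
                   adaptive = v[["adaptive"]], resilient = v[["resilient"]])
  }))

  high_self <- target_mean >= mean(target_mean)
  truth <- tibble::tibble(
    actor_id = ids, role = roles, hub = hub,
    propensity = propensity, target_mean = target_mean,
    high_self = high_self,
    expected_quadrant = dplyr::case_when(
      hub & high_self ~ "established",
      hub & !high_self ~ "humble",
      !hub & high_self ~ "aspirational",
      TRUE ~ "latent"
    )
  )

  list(
    dataset = survey_dataset(actors, nominations, likert, ratings),
    truth = truth
  )
}

#' Planted quadrant labels from a cohort truth table
#'
#' @param truth the `truth` tibble returned by [generate_cohort()].
#' @return tibble `actor_id`, `quadrant` (the quadrant each actor should land
#'   in under perfect alignment between self-perception and network position).
#' @export
expected_quadrants <- function(truth) {
  stopifnot(all(c("actor_id", "expected_quadrant") %in% names(truth)))
  tibble::tibble(actor_id = truth$actor_id,
                 quadrant = truth$expected_quadrant)
}
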