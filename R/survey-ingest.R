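#' Construct a survey dataset
#'
#' Container for a roster advice-seeking survey: the respondent roster, the
#' directed advice nominations with frequencies, the eight-item leadership
#' self-perception blocks, and the preceptor importance ratings for the four
#' styles. Normally produced by [read_survey()] or [generate_cohort()];
#' exported so that datasets can be assembled programmatically.
#'
#' @param actors tibble with columns `actor_id`, `role` (one of `"preceptor"`,
#'   `"R1"`, `"R2"`, `"R3"`), `gender`, `years_doctor_band`,
#'   `years_specialty_band`.
#' @param nominations tibble with columns `source_id`, `target_id`,
#'   `frequency` (non-negative integer).
#' @param likert tibble with columns `actor_id`, `likert_1` ... `likert_8`
#'   (integers 1-5, `NA` for unanswered items).
#' @param ratings tibble with columns `rater_id` and one column per style
#'   (`relational`, `transformational`, `adaptive`, `resilient`), each an
#'   integer rank 1 (most important) to 4 (least important); ties allowed.
#' @return an object of class `survey_dataset`.
#' @export
survey_dataset <- function(actors, nominations, likert, ratings) {
  actors <- tibble::as_tibble(actors)
  nominations <- tibble::as_tibble(nominations)
  likert <- tibble::as_tibble(likert)
  ratings <- tibble::as_tibble(ratings)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0)
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(actors, c("actor_id", "role", "gender", "years_doctor_band",
                 "years_specialty_band"), "actors")
  need(nominations, c("source_id", "target_id", "frequency"), "nominations")
  need(likert, c("actor_id", paste0("likert_", 1:8)), "likert")
  need(ratings, c("rater_id", .lm_styles), "ratings")
  bad_role <- setdiff(unique(actors$role), .lm_roles)
  if (length(bad_role) > 0)
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  if (any(nominations$frequency < 0))
    stop("nomination frequencies must be non-negative", call. = FALSE)
  structure(
    list(actors = actors, nominations = nominations,
         likert = likert, ratings = ratings),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat("  actors:      ", nrow(x$actors), " (",
      paste(sprintf("%s=%d", .lm_roles,
                    vapply(.lm_roles, function(r) sum(x$actors$role == r), 0L)),
            collapse = ", "), ")\n", sep = "")
  cat("  nominations: ", nrow(x$nominations), "\n", sep = "")
  cat("  likert rows: ", nrow(x$likert), "\n", sep = "")
  cat("  raters:      ", nrow(x$ratings), "\n", sep = "")
  invisible(x)
}

#' Read the two survey tables
#'
#' Reads the roster survey export (one row per respondent, with advice
#' nominations encoded as semicolon-separated `target:frequency` pairs) and
#' the preceptor style-importance rating table, applies the inclusion rules
#' (consent given, role among the four included categories), removes
#' self-nominations and nominations of targets absent from the respondent
#' roster, and returns a validated [survey_dataset()].
#'
#' Dropped rows and edges are reported via [message()] so a run log captures
#' the cleaning counts.
#'
#' @param survey_path path to the respondent CSV with columns `actor_id`,
#'   `role`, `gender`, `years_doctor_band`, `years_specialty_band`, `consent`
#'   (`"Yes"`/`"No"`), `nominations`, `likert_1` ... `likert_8`.
#' @param rating_path path to the rating CSV with columns `rater_id`,
#'   `relational`, `transformational`, `adaptive`, `resilient`.
#' @return a `survey_dataset`.
#' @export
read_survey <- function(survey_path, rating_path) {
  for (p in c(survey_path, rating_path))
    if (!file.exists(p)) stop("cannot read file: ", p, call. = FALSE)
  raw <- readr::read_csv(survey_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("actor_id", "role", "gender", "years_doctor_band",
            "years_specialty_band", "consent", "nominations",
            paste0("likert_", 1:8))
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("survey table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  # consent gate: "No" or missing consent rows are dropped, with a count
  keep <- !is.na(raw$consent) & raw$consent == "Yes"
  if (any(!keep))
    message(sum(!keep), " row(s) dropped: consent not given")
  raw <- raw[keep, , drop = FALSE]

  bad <- which(!raw$role %in% .lm_roles)
  if (length(bad) > 0)
    stop("unknown role value at row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(raw$role[bad]), collapse = ", "), call. = FALSE)

  lik_cols <- paste0("likert_", 1:8)
  lik <- raw[, c("actor_id", lik_cols)]
  for (cc in lik_cols) lik[[cc]] <- suppressWarnings(as.integer(lik[[cc]]))
  offending <- character(0)
  for (cc in lik_cols) {
    v <- lik[[cc]]
    bad_i <- which(!is.na(v) & (v < 1 | v > 5))
    if (length(bad_i) > 0)
      offending <- c(offending,
                     sprintf("%s[%s]", lik$actor_id[bad_i], cc))
  }
  if (length(offending) > 0)
    stop("Likert value(s) outside 1..5: ", paste(offending, collapse = ", "),
         call. = FALSE)

  noms <- parse_nominations(raw$actor_id, raw$nominations)
  n_self <- sum(noms$source_id == noms$target_id)
  if (n_self > 0)
    message(n_self, " self-nomination(s) removed")
  noms <- noms[noms$source_id != noms$target_id, , drop = FALSE]
  dangling <- !noms$target_id %in% raw$actor_id
  if (any(dangling))
    message(sum(dangling),
            " nomination(s) dropped: target not on the respondent roster")
  noms <- noms[!dangling, , drop = FALSE]

  ratings <- readr::read_csv(rating_path, col_types = readr::cols(
    rater_id = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  miss <- setdiff(c("rater_id", .lm_styles), names(ratings))
  if (length(miss) > 0)
    stop("rating table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (s in .lm_styles) {
    v <- ratings[[s]]
    if (any(is.na(v) | v < 1 | v > 4))
      stop("importance ratings must be integers in 1..4 (column ", s, ")",
           call. = FALSE)
  }

  survey_dataset(
    actors = raw[, c("actor_id", "role", "gender", "years_doctor_band",
                     "years_specialty_band")],
    nominations = noms,
    likert = lik,
    ratings = ratings[, c("rater_id", .lm_styles)]
  )
}

# "t1:3;t2:1" strings -> long nomination tibble
parse_nominations <- function(source_ids, nom_strings) {
  out <- lapply(seq_along(source_ids), function(i) {
    s <- nom_strings[i]
    if (is.na(s) || !nzchar(trimws(s))) return(NULL)
    pairs <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
    pairs <- pairs[nzchar(trimws(pairs))]
    if (length(pairs) == 0) return(NULL)
    parts <- strsplit(trimws(pairs), ":", fixed = TRUE)
    bad <- vapply(parts, length, 0L) != 2
    if (any(bad))
      stop("malformed nomination entry for actor ", source_ids[i], ": ",
           paste(pairs[bad], collapse = ", "), call. = FALSE)
    tibble::tibble(
      source_id = source_ids[i],
      target_id = trimws(vapply(parts, `[`, "", 1)),
      frequency = as.integer(vapply(parts, `[`, "", 2))
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0)
    return(tibble::tibble(source_id = character(0), target_id = character(0),
                          frequency = integer(0)))
  if (any(is.na(out$frequency) | out$frequency < 0))
    stop("nomination frequencies must be non-negative integers", call. = FALSE)
  out
}

#' Write a survey dataset back to the two-table CSV schema
#'
#' Inverse of [read_survey()]: nominations are folded back into the
#' semicolon-separated `target:frequency` column and consent is written as
#' `"Yes"` (only consenting rows exist inside a dataset). `read_survey()`
#' applied to the written files reproduces the dataset field for field.
#'
#' @param ds a `survey_dataset`.
#' @param survey_path,rating_path output CSV paths.
#' @return `ds`, invisibly.
#' @export
write_survey <- function(ds, survey_path, rating_path) {
  stopifnot(inherits(ds, "survey_dataset"))
  nom_str <- vapply(ds$actors$actor_id, function(a) {
    rows <- ds$nominations[ds$nominations$source_id == a, , drop = FALSE]
    if (nrow(rows) == 0) return("")
    paste(sprintf("%s:%d", rows$target_id, rows$frequency), collapse = ";")
  }, "")
  out <- dplyr::mutate(ds$actors, consent = "Yes",
                       nominations = unname(nom_str))
  out <- dplyr::left_join(out, ds$likert, by = "actor_id")
  readr::write_csv(out, survey_path, progress = FALSE)
  readr::write_csv(ds$ratings, rating_path, progress = FALSE)
  invisible(ds)
}

#' Structural validation report for a survey dataset
#'
#' Reports (without modifying the dataset) duplicate actor ids, nominations
#' whose target is absent from the roster, actors whose Likert block has fewer
#' than eight answered items (and is therefore ineligible for an LAI score),
#' and importance ratings submitted by non-preceptors.
#'
#' @param ds a `survey_dataset`.
#' @return object of class `validation_report`: a list with elements
#'   `duplicate_ids`, `dangling_targets`, `incomplete_likert`,
#'   `non_preceptor_raters` and logical `clean`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  dup <- unique(ds$actors$actor_id[duplicated(ds$actors$actor_id)])
  dangling <- ds$nominations[!ds$nominations$target_id %in% ds$actors$actor_id,
                             c("source_id", "target_id")]
  lik_cols <- paste0("likert_", 1:8)
  n_items <- rowSums(!is.na(as.matrix(ds$likert[, lik_cols])))
  incomplete <- tibble::tibble(
    actor_id = ds$likert$actor_id[n_items < 8],
    n_items = as.integer(n_items[n_items < 8])
  )
  preceptors <- ds$actors$actor_id[ds$actors$role == "preceptor"]
  non_prec <- unique(ds$ratings$rater_id[!ds$ratings$rater_id %in% preceptors])
  rep <- list(
    duplicate_ids = dup,
    dangling_targets = dangling,
    incomplete_likert = incomplete,
    non_preceptor_raters = non_prec
  )
  rep$clean <- length(dup) == 0 && nrow(dangling) == 0 &&
    nrow(incomplete) == 0 && length(non_prec) == 0
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$clean) "clean" else "issues found", "\n")
  cat("  duplicate ids:        ", length(x$duplicate_ids), "\n")
  cat("  dangling targets:     ", nrow(x$dangling_targets), "\n")
  cat("  incomplete likert:    ", nrow(x$incomplete_likert), "\n")
  cat("  non-preceptor raters: ", length(x$non_preceptor_raters), "\n")
  invisible(x)
}

#' De-identify a survey dataset
#'
#' Replaces actor ids with role-prefixed pseudonyms (`P1`, `P2`, ... for
#' preceptors; `R1.1`, `R2.1`, `R3.1`, ... for residents by year), applied
#' consistently across the roster, nominations, Likert blocks and ratings.
#' Pseudonyms are assigned by a stable sort on (role, original id), so the
#' operation is deterministic and idempotent in the sense that re-applying it
#' to an already de-identified dataset reproduces the same pseudonyms.
#'
#' @param ds a `survey_dataset`.
#' @return list with elements `dataset` (the de-identified `survey_dataset`)
#'   and `key_map` (tibble `original_id`, `pseudonym` inverting the
#'   substitution).
#' @export
deidentify <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  a <- ds$actors
  # natural sort on ids (embedded numbers compared numerically) so that
  # re-running on already-pseudonymised ids is a no-op
  natural_key <- function(x) {
    vapply(x, function(s) {
      toks <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
      digits <- grepl("^[0-9]+$", toks)
      toks[digits] <- sprintf("%012d", as.numeric(toks[digits]))
      paste(toks, collapse = "")
    }, "")
  }
  ord <- order(match(a$role, .lm_roles), natural_key(a$actor_id))
  a <- a[ord, , drop = FALSE]
  pseud <- character(nrow(a))
  for (r in .lm_roles) {
    i <- which(a$role == r)
    if (length(i) == 0) next
    pseud[i] <- if (r == "preceptor") paste0("P", seq_along(i))
                else paste0(r, ".", seq_along(i))
  }
  key <- tibble::tibble(original_id = a$actor_id, pseudonym = pseud)
  sub <- setNames(key$pseudonym, key$original_id)
  remap <- function(x) unname(sub[x])
  out <- survey_dataset(
    actors = dplyr::mutate(a, actor_id = remap(.data$actor_id)),
    nominations = dplyr::mutate(ds$nominations,
                                source_id = remap(.data$source_id),
                                target_id = remap(.data$target_id)),
    likert = dplyr::mutate(ds$likert[match(a$actor_id, ds$likert$actor_id), ,
                                     drop = FALSE],
                           actor_id = remap(.data$actor_id)),
    ratings = dplyr::mutate(ds$ratings, rater_id = remap(.data$rater_id))
  )
  list(dataset = out, key_map = key)
}
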