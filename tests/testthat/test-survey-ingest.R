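test_that("a minimal well-formed survey reads into 3 actors and 2 nominations", {
  sp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  write_survey(tiny_dataset(), sp, rp)
  ds <- read_survey(sp, rp)
  expect_s3_class(ds, "survey_dataset")
  expect_equal(nrow(ds$actors), 3)
  expect_equal(nrow(ds$nominations), 2)
  expect_setequal(ds$actors$role, c("preceptor", "R1", "R2"))
})

test_that("consent gating and self-nominations are applied with logged counts", {
  sp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  lines <- c(
    paste0("actor_id,role,gender,years_doctor_band,years_specialty_band,",
           "consent,nominations,likert_1,likert_2,likert_3,likert_4,",
           "likert_5,likert_6,likert_7,likert_8"),
    'a,preceptor,female,>10,>10,Yes,"b:2;a:1",5,4,5,5,4,4,5,3',
    "b,R1,male,1-2,<1,Yes,,3,3,4,2,3,4,3,3",
    "c,R2,female,2-3,1-2,No,,2,2,1,3,2,2,1,2"
  )
  writeLines(lines, sp)
  writeLines(c("rater_id,relational,transformational,adaptive,resilient",
               "a,1,2,3,4"), rp)
  msgs <- capture_messages(ds <- read_survey(sp, rp))
  expect_match(msgs, "1 row\\(s\\) dropped: consent not given", all = FALSE)
  expect_match(msgs, "1 self-nomination\\(s\\) removed", all = FALSE)
  expect_equal(nrow(ds$actors), 2)          # consent "No" dropped
  expect_equal(nrow(ds$nominations), 1)     # a->a removed, a->b kept
  expect_equal(ds$nominations$target_id, "b")
  # dropped + retained row counts equal the input row count
  expect_equal(nrow(ds$actors) + 1, 3)
})

test_that("schema violations fail with informative errors", {
  sp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  header <- paste0("actor_id,role,gender,years_doctor_band,",
                   "years_specialty_band,consent,nominations,likert_1,",
                   "likert_2,likert_3,likert_4,likert_5,likert_6,likert_7,",
                   "likert_8")
  writeLines(c("rater_id,relational,transformational,adaptive,resilient",
               "a,1,2,3,4"), rp)
  writeLines(c(header, "a,attending,f,>10,>10,Yes,,5,4,5,5,4,4,5,3"), sp)
  expect_error(read_survey(sp, rp), "unknown role value at row\\(s\\) 1")
  writeLines(c(header, "a,preceptor,f,>10,>10,Yes,,5,4,9,5,4,4,5,3"), sp)
  expect_error(read_survey(sp, rp), "outside 1..5.*a\\[likert_3\\]")
  expect_error(read_survey("no/such/file.csv", rp), "cannot read file")
})

test_that("a synthetic cohort round-trips through write and read unchanged", {
  gen <- generate_cohort(cohort_config(seed = 42))
  sp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  write_survey(gen$dataset, sp, rp)
  ds2 <- read_survey(sp, rp)
  expect_dataset_equal(gen$dataset, ds2)
})

test_that("validate_dataset reports structural issues without modifying data", {
  ds <- tiny_dataset()
  expect_true(validate_dataset(ds)$clean)

  ds_bad <- ds
  ds_bad$nominations <- tibble::add_row(
    ds_bad$nominations, source_id = "a", target_id = "ghost", frequency = 1L)
  ds_bad$likert$likert_8[2] <- NA
  ds_bad$ratings <- tibble::add_row(
    ds_bad$ratings, rater_id = "b", relational = 2L, transformational = 1L,
    adaptive = 3L, resilient = 4L)
  rep <- validate_dataset(ds_bad)
  expect_false(rep$clean)
  expect_equal(nrow(rep$dangling_targets), 1)
  expect_equal(rep$dangling_targets$target_id, "ghost")
  # 7-item block flags the actor as LAI-ineligible
  expect_equal(rep$incomplete_likert$actor_id, "b")
  expect_equal(rep$incomplete_likert$n_items, 7L)
  expect_equal(rep$non_preceptor_raters, "b")
  # reporting only: input unchanged
  expect_equal(nrow(ds_bad$nominations), 3)
})

test_that("de-identification is deterministic, idempotent and structure-preserving", {
  ds <- survey_dataset(
    actors = tibble::tibble(
      actor_id = c("bob", "alice"), role = c("R1", "preceptor"),
      gender = c("male", "female"),
      years_doctor_band = c("1-2", ">10"), years_specialty_band = c("<1", ">10")
    ),
    nominations = tibble::tibble(source_id = "bob", target_id = "alice",
                                 frequency = 3L),
    likert = tibble::tibble(actor_id = c("bob", "alice"),
                            likert_1 = 3L, likert_2 = 3L, likert_3 = 3L,
                            likert_4 = 3L, likert_5 = 3L, likert_6 = 3L,
                            likert_7 = 3L, likert_8 = 3L),
    ratings = tibble::tibble(rater_id = "alice", relational = 1L,
                             transformational = 1L, adaptive = 2L,
                             resilient = 2L)
  )
  out <- deidentify(ds)
  expect_setequal(out$key_map$pseudonym, c("P1", "R1.1"))
  expect_equal(out$key_map$pseudonym[out$key_map$original_id == "alice"], "P1")
  # every edge references only pseudonyms
  expect_true(all(out$dataset$nominations$source_id %in%
                    out$dataset$actors$actor_id))
  expect_true(all(out$dataset$nominations$target_id %in%
                    out$dataset$actors$actor_id))
  # the nomination multigraph is isomorphic under the key map
  sub <- setNames(out$key_map$pseudonym, out$key_map$original_id)
  expect_equal(
    dplyr::arrange(dplyr::mutate(ds$nominations,
                                 source_id = unname(sub[source_id]),
                                 target_id = unname(sub[target_id])),
                   source_id, target_id),
    dplyr::arrange(out$dataset$nominations, source_id, target_id)
  )
  # idempotence: de-identifying the pseudonymised dataset changes nothing
  again <- deidentify(out$dataset)
  expect_dataset_equal(out$dataset, again$dataset)
})

test_that("de-identification is idempotent past single-digit counts", {
  gen <- generate_cohort(cohort_config(seed = 7))  # ids like P10, R1.12
  once <- deidentify(gen$dataset)
  twice <- deidentify(once$dataset)
  expect_dataset_equal(once$dataset, twice$dataset)
})
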