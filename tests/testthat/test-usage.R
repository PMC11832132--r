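needs_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    hashed_id = "h1",
    dd_category = vapply(rows, `[[`, character(1), 1),
    year = as.integer(vapply(rows, `[[`, character(1), 2))
  )
}

test_that("usage summaries count years, needs and repetitions as defined", {
  # same category twice within one year is one need, one access year
  s1 <- summarize_usage(needs_tbl(c("poverty", "2018"), c("poverty", "2018")))
  expect_equal(s1$n_access_years, 1)
  expect_equal(s1$n_needs, 1)
  expect_false(s1$has_repeated_need)

  s2 <- summarize_usage(needs_tbl(c("poverty", "2018"),
                                  c("homelessness or housing issues", "2019")))
  expect_equal(s2$n_access_years, 2)
  expect_equal(s2$n_needs, 2)
  expect_false(s2$has_repeated_need)
  expect_equal(s2$max_years_single_need, 1)

  s3 <- summarize_usage(needs_tbl(c("poverty", "2018"),
                                  c("homelessness or housing issues", "2018"),
                                  c("poverty", "2020")))
  expect_equal(s3$n_access_years, 2)
  expect_equal(s3$n_needs, 3)
  expect_true(s3$has_repeated_need)
  expect_equal(s3$max_years_single_need, 2)

  expect_error(summarize_usage(needs_tbl()[0, ]),
               class = "vetlink_validation_error")
})

test_that("usage summaries agree with the naive loop oracle on random cases", {
  set.seed(123)
  cats <- dd_categories()
  for (i in 1:200) {
    k <- sample(1:8, 1)
    categories <- sample(cats[1:4], k, replace = TRUE)
    years <- sample(2018:2021, k, replace = TRUE)
    got <- summarize_usage(tibble::tibble(
      hashed_id = "p", dd_category = categories, year = years
    ))
    want <- naive_usage(categories, years)
    expect_equal(got$n_access_years, want$n_access_years)
    expect_equal(got$n_needs, want$n_needs)
    expect_equal(got$max_years_single_need, want$max_years_single_need)
    expect_equal(got$has_repeated_need, want$has_repeated_need)
  }
})

test_that("classification matches the independent truth table exhaustively", {
  for (years in 1:3) {
    for (needs in 1:5) {
      if (needs < years) next  # at least one need per access year
      for (repeated in c(FALSE, TRUE)) {
        if (repeated && years < 2) next  # repetition spans distinct years
        expect_equal(
          classify_pattern(years, needs, repeated),
          truth_table_label(years, needs, repeated),
          info = sprintf("y=%d n=%d rep=%s", years, needs, repeated)
        )
      }
    }
  }
  expect_error(classify_pattern(0, 1, FALSE),
               class = "vetlink_validation_error")
})

test_that("features are a fixed-order triple, invariant to record order", {
  needs <- needs_tbl(c("poverty", "2018"),
                     c("homelessness or housing issues", "2018"),
                     c("poverty", "2019"))
  f <- build_features(summarize_usage(needs))
  expect_equal(colnames(f),
               c("n_access_years", "n_needs", "max_years_single_need"))
  expect_equal(unname(f[1, ]), c(2, 3, 2))

  f_rev <- build_features(summarize_usage(needs[3:1, ]))
  expect_equal(f, f_rev)

  # single access, single need person
  f1 <- build_features(summarize_usage(needs_tbl(c("poverty", "2018"))))
  expect_equal(unname(f1[1, ]), c(1, 1, 1))
})

test_that("strata partition the population and recover the planted labels", {
  cfg <- generator_config(n_persons = 400, seed = 19)
  ext <- generate_charity_extracts(generate_population(cfg), cfg)
  anon <- lapply(names(ext$extracts), function(nm) {
    e <- ext$extracts[[nm]]
    e$provider <- nm
    anonymize_extract(e, salt = "strata")
  })
  reg <- build_registry(anon)
  summaries <- stratify_registry(reg)

  expect_equal(sum(table(summaries$stratum)), nrow(summaries))
  expect_setequal(unique(summaries$stratum), stratum_levels())

  # (1,1,1) if and only if single access single need
  sss <- summaries$stratum == "single_access_single_need"
  trip <- summaries$n_access_years == 1 & summaries$n_needs == 1 &
    summaries$max_years_single_need == 1
  expect_equal(sss, trip)

  # planted strata recovered for 100% of persons: tie summaries back to
  # ground truth through the re-hashed identity
  pop <- generate_population(cfg)
  key <- canonicalize_key(pop$persons$service_number,
                          pop$persons$date_of_birth, pop$persons$gender)
  truth <- tibble::tibble(hashed_id = hash_identity(key, "strata"),
                          planted = pop$persons$stratum)
  joined <- dplyr::inner_join(summaries, truth, by = "hashed_id")
  expect_equal(nrow(joined), 400)
  expect_equal(joined$stratum, joined$planted)
})
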