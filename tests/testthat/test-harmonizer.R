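test_that("parsing maps provider columns and collects rejects with reasons", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Service No,DOB,Sex,Date of Request,Need Type,Role",
    "AB1,01/02/1960,male,05/06/2020,rent arrears,veteran",
    "AB2,02/03/1961,female,06/07/2021,ptsd support,veteran",
    "AB3,03/04/1962,m,07/08/2022,food bank referral,family",
    "AB4,99/99/1963,m,07/08/2022,rent arrears,veteran",
    ",01/01/1960,m,01/01/2020,rent arrears,veteran"
  ), path)
  schema <- provider_schema(
    "charity_x",
    columns = c("Service No" = "service_number", "DOB" = "date_of_birth",
                "Sex" = "gender", "Date of Request" = "date",
                "Need Type" = "provider_category", "Role" = "role"),
    date_format = "dmy"
  )
  parsed <- parse_charity_file(path, schema)
  expect_equal(nrow(parsed$records), 3)
  expect_equal(parsed$records$provider_category[1], "rent arrears")
  expect_equal(parsed$records$date[1], as.Date("2020-06-05"))
  expect_equal(parsed$records$provider, rep("charity_x", 3))
  expect_setequal(parsed$rejects$reason,
                  c("bad date", "missing service number"))
  expect_equal(parsed$rejects$row, c(4, 5))

  writeLines(c("Service No,Sex", "AB1,m"), path)
  expect_error(parse_charity_file(path, schema),
               class = "vetlink_schema_error")
})

test_that("last-declared attribute resolution never lets missing win", {
  expect_equal(
    resolve_attribute(c("single", "married"),
                      as.Date(c("2019-05-01", "2021-02-01"))),
    "married"
  )
  expect_equal(resolve_attribute("widowed", as.Date("2020-01-01")),
               "widowed")
  # latest non-missing wins under every input ordering
  vals <- c("A", NA, "B")
  dats <- as.Date(c("2018-01-01", "2020-01-01", "2019-01-01"))
  for (p in list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), 3:1)) {
    expect_equal(resolve_attribute(vals[p], dats[p]), "B")
  }
  expect_true(is.na(resolve_attribute(c(NA, NA),
                                      as.Date(c("2018-01-01", "2019-01-01")))))
})

test_that("role precedence is veteran-if-any, for every tag combination", {
  expect_equal(resolve_role(c("family", "veteran")), "veteran")
  expect_equal(resolve_role(c("family", "family")), "family")
  for (n in 1:4) {
    combos <- expand.grid(rep(list(c("veteran", "family")), n),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      tags <- unlist(combos[i, ])
      expect_equal(resolve_role(tags),
                   if (any(tags == "veteran")) "veteran" else "family")
    }
  }
  expect_error(resolve_role(c("veteran", "spouse")),
               class = "vetlink_validation_error")
})

test_that("age is completed whole years with the birthday boundary", {
  expect_equal(compute_age(as.Date("1960-03-15"), as.Date("2020-03-14")), 59)
  expect_equal(compute_age(as.Date("1960-03-15"), as.Date("2020-03-15")), 60)
  expect_error(compute_age(as.Date("1990-01-01"), as.Date("1980-01-01")),
               class = "vetlink_validation_error")
  expect_equal(classify_age_band(c(65, 66)), c("working", "non_working"))
  expect_equal(classify_age_band(65, threshold = 60), "non_working")
})

test_that("almonised duplicates collapse to one person and one need", {
  a <- make_anon_extract("h1", "charity_a", "rent arrears", "2020-03-01")
  b <- make_anon_extract("h1", "charity_b", "emergency housing", "2020-09-01")
  reg <- build_registry(list(a, b))
  expect_equal(reg$report$n_persons, 1)
  expect_equal(reg$report$n_needs, 1)
  expect_equal(reg$report$n_collapsed, 1)
  expect_equal(reg$needs$dd_category, "homelessness or housing issues")
  # collapse at the raw provider wording keeps both
  reg_l1 <- build_registry(list(a, b), collapse_layer = "provider")
  expect_equal(reg_l1$report$n_needs, 2)
})

test_that("disjoint extracts add person counts and registries rebuild stably", {
  a <- make_anon_extract(c("h1", "h2"), "charity_a",
                         c("rent arrears", "ptsd support"),
                         c("2019-01-01", "2020-01-01"))
  b <- make_anon_extract("h3", "charity_b", "job seeking", "2021-05-05")
  reg <- build_registry(list(a, b))
  expect_equal(reg$report$n_persons, 3)

  # almonisation idempotence: rebuilding from the collapsed needs is a no-op
  back <- reg$needs
  back$age_at_event <- 50
  back$gender <- "M"
  back$role <- "veteran"
  reg2 <- build_registry(back)
  expect_equal(reg2$report$n_collapsed, 0)
  expect_equal(reg2$report$n_needs, reg$report$n_needs)
  expect_equal(reg2$report$n_persons, reg$report$n_persons)
})

test_that("profiles resolve by declaration date, not input order", {
  recs <- tibble::tibble(
    hashed_id = "h1",
    provider = "charity_a",
    provider_category = c("rent arrears", "ptsd support", "job seeking"),
    date = as.Date(c("2019-01-01", "2021-06-01", "2020-03-01")),
    age_at_event = c(50, 52, 51),
    gender = "M",
    role = c("family", "veteran", "family"),
    marital_status = c("single_divorced_widowed", "married_cohabiting_civil", NA)
  )
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    reg <- build_registry(recs[perm, ])
    expect_equal(reg$profiles$marital_status, "married_cohabiting_civil")
    expect_equal(reg$profiles$role, "veteran")
    expect_equal(reg$profiles$age_at_first_need, 50)
    expect_equal(reg$profiles$age_band, "working")
  }
})

test_that("conflicting genders warn and resolve instead of failing", {
  recs <- make_anon_extract(c("h1", "h1"), "charity_a",
                            c("rent arrears", "rent arrears"),
                            c("2019-01-01", "2020-01-01"))
  recs$gender <- c("M", "F")
  expect_warning(reg <- build_registry(recs), "conflicting gender")
  expect_equal(reg$profiles$gender, "F")
})

test_that("person conservation holds across synthetic overlap settings", {
  for (rate in c(0, 0.5)) {
    cfg <- generator_config(n_persons = 120, overlap_rate = rate, seed = 41)
    ext <- generate_charity_extracts(generate_population(cfg), cfg)
    anon <- lapply(names(ext$extracts), function(nm) {
      e <- ext$extracts[[nm]]
      e$provider <- nm
      anonymize_extract(e, salt = "conserve")
    })
    reg <- build_registry(anon)
    per_provider <- sum(reg$report$persons_per_provider$n_persons)
    expect_equal(reg$report$n_persons, 120)
    if (rate == 0) expect_equal(per_provider, 120)
    if (rate > 0) expect_gt(per_provider, 120)
  }
})
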