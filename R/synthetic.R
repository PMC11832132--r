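#' Configuration for the synthetic multi-charity generator
#'
#' Bundles and validates the knobs of the synthetic registry generator.
#' Defaults reproduce the study conditions of the registry the package
#' models: five national charities, the 2018-2023 observation window,
#' a four-stratum usage mixture equal to the observed stratum shares
#' (29.4% single access/single need, 30.8% single access/multiple
#' needs, 33.0% multiple access/repeated needs, 6.8% multiple
#' access/all new needs), and per-attribute missingness matched to the
#' reported per-variable denominators.
#'
#' @param n_persons number of true persons to generate.
#' @param n_charities number of provider extracts (>= 2).
#' @param overlap_rate fraction in \[0, 1\] of persons whose records
#'   appear in at least two charities (every such person gets at least
#'   one almonised duplicate: the same need contributed by two
#'   providers).
#' @param stratum_mix four non-negative weights summing to 1, in the
#'   order single access/single need, single access/multiple needs,
#'   multiple access/repeated needs, multiple access/all new needs.
#' @param years inclusive calendar-year range `c(first, last)`.
#' @param missingness named fractions in \[0, 1\]: probability that a
#'   person's value for that attribute is blank in every raw record.
#'   Recognized names: `rank`, `marital_status`, `service_branch`,
#'   `accommodation`, `benefits_receipt`, `n_dependants`.
#' @param seed integer master seed; fixed seed gives byte-identical
#'   output.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_persons = 2000,
                             n_charities = 5,
                             overlap_rate = 0.2,
                             stratum_mix = default_stratum_mix(),
                             years = c(2018, 2023),
                             missingness = default_missingness(),
                             seed = 1L) {
  n_persons <- check_count(n_persons, "n_persons")
  n_charities <- check_count(n_charities, "n_charities", min = 2)
  check_fraction(overlap_rate, "overlap_rate")
  if (!is.numeric(stratum_mix) || length(stratum_mix) != 4 ||
      any(stratum_mix < 0)) {
    stop_vetlink("`stratum_mix` must be 4 non-negative weights",
                 "vetlink_config_error")
  }
  if (abs(sum(stratum_mix) - 1) > 1e-9) {
    stop_vetlink(
      sprintf("`stratum_mix` must sum to 1 (got %.12f)", sum(stratum_mix)),
      "vetlink_config_error"
    )
  }
  if (length(years) != 2 || years[1] > years[2]) {
    stop_vetlink("`years` must be a nonempty inclusive range c(first, last)",
                 "vetlink_config_error")
  }
  full_miss <- default_missingness()
  full_miss[] <- 0
  if (length(missingness)) {
    unknown <- setdiff(names(missingness), names(full_miss))
    if (length(unknown)) {
      stop_vetlink(
        sprintf("`missingness` has unknown attribute(s): %s",
                paste(unknown, collapse = ", ")),
        "vetlink_config_error"
      )
    }
    for (nm in names(missingness)) check_fraction(missingness[[nm]], paste0("missingness.", nm))
    full_miss[names(missingness)] <- unlist(missingness)
  }
  if (n_charities < 2 && overlap_rate > 0) {
    stop_vetlink("`overlap_rate` > 0 requires `n_charities` >= 2",
                 "vetlink_config_error")
  }
  structure(
    list(
      n_persons = n_persons,
      n_charities = n_charities,
      overlap_rate = overlap_rate,
      stratum_mix = setNames(as.numeric(stratum_mix), stratum_levels()),
      years = as.integer(years),
      missingness = full_miss,
      seed = check_count(seed, "seed", min = 0)
    ),
    class = "generator_config"
  )
}

#' The four a-priori usage-pattern strata
#'
#' @return character vector of the four stratum labels, in canonical
#'   order.
#' @export
stratum_levels <- function() {
  c("single_access_single_need",
    "single_access_multiple_needs",
    "multiple_access_repeated_needs",
    "multiple_access_all_new_needs")
}

#' Default stratum mixture
#'
#' The observed shares of the four usage-pattern subgroups in the
#' registry population (12409, 13018, 13957 and 2880 of 42264
#' veterans).
#'
#' @return numeric vector of 4 weights summing to 1.
#' @export
default_stratum_mix <- function() {
  c(12409, 13018, 13957, 2880) / 42264
}

#' Default per-attribute missingness rates
#'
#' One minus the reported per-variable denominator over the registry
#' total: attributes whose denominator equals the population have rate
#' 0.
#'
#' @return named numeric vector of fractions.
#' @export
default_missingness <- function() {
  n <- 42264
  c(
    rank = 1 - 30259 / n,
    marital_status = 0,
    service_branch = 0,
    accommodation = 1 - 38085 / n,
    benefits_receipt = 1 - 35082 / n,
    n_dependants = 1 - 35384 / n
  )
}

# attribute marginals among non-missing values, from the registry's
# reported frequency blocks
attribute_marginals <- function() {
  list(
    gender = c(F = 4802, M = 37453, O = 9) / 42264,
    rank = c(non_officer = 29550, officer = 709) / 30259,
    marital_status = c(married_cohabiting_civil = 16159,
                       single_divorced_widowed = 26105) / 42264,
    service_branch = c(army = 27280, other = 1361, royal_air_force = 8602,
                       royal_marines = 860, royal_navy = 4195) / 42298,
    accommodation = c(flat_apartment = 10398, homeless_tent_shelter = 2178,
                      hotel = 578, house = 18673, nursing_home = 654,
                      other = 5233, prison = 371) / 38085,
    benefits_receipt = c(no = 12553, yes = 22529) / 35082,
    n_dependants = c(`0` = 9194, `1` = 6552, `2` = 9189, `3+` = 10449) / 35384
  )
}

sample_level <- function(n, marginal) {
  sample(names(marginal), n, replace = TRUE, prob = marginal)
}

# sample() treats a length-1 numeric x as 1:x; this never does
resample <- function(x, size) x[sample.int(length(x), size)]

random_date_in_year <- function(year) {
  start <- as.Date(sprintf("%d-01-01", year))
  start + sample.int(365, length(year), replace = TRUE) - 1L
}

#' Generate the true population and its usage trajectories
#'
#' Draws `n_persons` true persons: an identity triple (synthetic
#' service number drawn without replacement from a 10^8 ID space, date
#' of birth, gender), harmonized attribute values from the default
#' marginals, a stratum from `stratum_mix`, and a need trajectory
#' constructed from the stratum definition:
#'
#' * single access, single need: one year, one category;
#' * single access, multiple needs: one year, two distinct categories;
#' * multiple access, repeated needs: two distinct years, the same
#'   category in both (a repetition by definition);
#' * multiple access, all new needs: two distinct years, a different
#'   category in each.
#'
#' Trajectories are built constructively (years drawn, then categories
#' forced or forbidden to repeat), so the a-priori classifier recovers
#' the planted stratum exactly, and each stratum has a single
#' characteristic feature signature — the within-stratum variation of
#' the generator lives in categories, dates, providers, attributes and
#' missingness, not in the three clustering features.
#'
#' @param config a [generator_config()].
#' @return a list of class `synthetic_population`: `persons` (one row
#'   per true person: identity, attributes, stratum), `needs` (one row
#'   per true need: person, layer-2 category, provider term, date,
#'   year) and `truth` (per-person stratum and feature triple).
#' @export
generate_population <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop_vetlink("`config` must come from generator_config()",
                 "vetlink_config_error")
  }
  set.seed(config$seed)
  n <- config$n_persons
  marg <- attribute_marginals()
  strata <- sample(stratum_levels(), n, replace = TRUE,
                   prob = config$stratum_mix)

  persons <- tibble::tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    service_number = sprintf("SN%08d", sample.int(99999999L, n)),
    gender = sample_level(n, marg$gender),
    stratum = strata,
    rank = sample_level(n, marg$rank),
    marital_status = sample_level(n, marg$marital_status),
    service_branch = sample_level(n, marg$service_branch),
    accommodation = sample_level(n, marg$accommodation),
    benefits_receipt = sample_level(n, marg$benefits_receipt),
    n_dependants = sample_level(n, marg$n_dependants)
  )

  # working-age (< 66 at first need) share 60.9%
  working <- runif(n) < 25724 / 42264
  age_target <- ifelse(working,
                       sample(20:65, n, replace = TRUE),
                       sample(66:95, n, replace = TRUE))

  year_range <- seq(config$years[1], config$years[2])
  if (length(year_range) < 2 && sum(config$stratum_mix[3:4]) > 0) {
    stop_vetlink(
      "`years`: multiple-access strata need a range of at least two years",
      "vetlink_config_error"
    )
  }
  terms <- synthetic_provider_terms()
  cats <- names(terms)

  needs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- strata[i]
    if (s == "single_access_single_need") {
      yrs <- resample(year_range, 1)
      dd <- resample(cats, 1)
    } else if (s == "single_access_multiple_needs") {
      yrs <- rep(resample(year_range, 1), 2)
      dd <- resample(cats, 2)
    } else if (s == "multiple_access_repeated_needs") {
      yrs <- sort(resample(year_range, 2))
      dd <- rep(resample(cats, 1), 2)
    } else {
      yrs <- sort(resample(year_range, 2))
      dd <- resample(cats, 2)
    }
    term <- vapply(dd, function(d) resample(terms[[d]], 1), character(1))
    needs[[i]] <- tibble::tibble(
      person_id = persons$person_id[i],
      dd_category = dd,
      provider_category = unname(term),
      year = as.integer(yrs)
    )
  }
  needs <- dplyr::bind_rows(needs)
  needs$date <- random_date_in_year(needs$year)

  first_need <- needs |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_date = min(.data$date), .groups = "drop")
  first_date <- first_need$first_date[match(persons$person_id,
                                            first_need$person_id)]
  persons$date_of_birth <- first_date - round(age_target * 365.25) -
    sample(0:180, n, replace = TRUE)

  truth <- needs |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_access_years = dplyr::n_distinct(.data$year),
      n_needs = dplyr::n_distinct(paste(.data$dd_category, .data$year)),
      max_years_single_need = max(tapply(.data$year, .data$dd_category,
                                         function(y) length(unique(y)))),
      .groups = "drop"
    ) |>
    dplyr::left_join(persons[c("person_id", "stratum")], by = "person_id")

  structure(
    list(persons = persons, needs = needs, truth = truth, config = config),
    class = "synthetic_population"
  )
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("synthetic population:", nrow(x$persons), "persons,",
      nrow(x$needs), "true needs\n")
  print(table(x$persons$stratum))
  invisible(x)
}

#' Split a synthetic population into per-charity raw extracts
#'
#' Assigns every person a home charity, gives an `overlap_rate`
#' fraction of persons a second charity, and plants one almonised
#' duplicate per overlapping person: one of their needs is contributed
#' by both charities (same category and year; the provider wording may
#' differ, as it does between real charities). Attribute fields are
#' blanked at the configured per-attribute missingness rates, and a
#' small share of persons with several records carry one record tagged
#' `family` rather than `veteran`, exercising the role-precedence rule.
#'
#' @param population a [generate_population()] result.
#' @param config the same [generator_config()] (defaults to the one the
#'   population was generated with).
#' @return a list of class `charity_extracts`: `extracts` (named list
#'   of raw tibbles, one per charity) and `truth` (the population truth
#'   plus the planted duplicate groups and expected registry counts).
#' @export
generate_charity_extracts <- function(population,
                                      config = population$config) {
  if (!inherits(population, "synthetic_population")) {
    stop_vetlink("`population` must come from generate_population()",
                 "vetlink_config_error")
  }
  if (config$n_charities < 2 && config$overlap_rate > 0) {
    stop_vetlink("`overlap_rate` > 0 requires `n_charities` >= 2",
                 "vetlink_config_error")
  }
  set.seed(config$seed + 1L)
  persons <- population$persons
  needs <- population$needs
  n <- nrow(persons)
  terms <- synthetic_provider_terms()

  home <- sample.int(config$n_charities, n, replace = TRUE)
  overlaps <- runif(n) < config$overlap_rate
  second <- vapply(seq_len(n), function(i) {
    if (!overlaps[i]) return(NA_integer_)
    resample(setdiff(seq_len(config$n_charities), home[i]), 1)
  }, integer(1))

  rows <- needs
  rows$charity <- home[match(rows$person_id, persons$person_id)]

  # plant one almonised duplicate per overlapping person
  dup_rows <- vector("list", n)
  for (i in which(overlaps)) {
    pn <- needs[needs$person_id == persons$person_id[i], ]
    pick <- pn[sample.int(nrow(pn), 1), ]
    pick$provider_category <- resample(terms[[pick$dd_category]], 1)
    pick$charity <- second[i]
    dup_rows[[i]] <- pick
  }
  duplicates <- dplyr::bind_rows(dup_rows)
  rows <- dplyr::bind_rows(rows, duplicates)

  attr_cols <- c("rank", "marital_status", "service_branch",
                 "accommodation", "benefits_receipt", "n_dependants")
  rows <- dplyr::left_join(
    rows,
    persons[c("person_id", "service_number", "date_of_birth", "gender",
              attr_cols)],
    by = "person_id"
  )
  rows$role <- "veteran"

  # person-level missingness: a blank attribute is blank in all records
  for (a in attr_cols) {
    miss <- persons$person_id[runif(n) < config$missingness[[a]]]
    rows[[a]][rows$person_id %in% miss] <- NA_character_
  }

  # some multi-record persons appear once as a family member
  multi <- names(which(table(rows$person_id) >= 2))
  flip_person <- multi[runif(length(multi)) < 0.05]
  for (p in flip_person) {
    idx <- which(rows$person_id == p)
    rows$role[sample(idx, 1)] <- "family"
  }

  extracts <- lapply(seq_len(config$n_charities), function(ch) {
    ex <- rows[rows$charity == ch,
               c("service_number", "date_of_birth", "gender", "date",
                 "provider_category", "role", attr_cols)]
    ex[sample.int(nrow(ex)), , drop = FALSE]
  })
  names(extracts) <- sprintf("charity_%02d", seq_len(config$n_charities))

  truth <- list(
    persons = population$truth,
    n_persons = n,
    duplicates = if (is.null(duplicates) || nrow(duplicates) == 0) {
      tibble::tibble(person_id = character(), dd_category = character(),
                     year = integer())
    } else {
      duplicates[c("person_id", "dd_category", "year")]
    },
    n_planted_duplicates = if (is.null(duplicates)) 0L else nrow(duplicates),
    n_true_needs = sum(population$truth$n_needs),
    charity_of_person = tibble::tibble(
      person_id = persons$person_id, home = home, second = second
    )
  )
  structure(list(extracts = extracts, truth = truth, config = config),
            class = "charity_extracts")
}

#' @export
print.charity_extracts <- function(x, ...) {
  cat("charity extracts:", length(x$extracts), "providers,",
      sum(vapply(x$extracts, nrow, integer(1))), "raw records,",
      x$truth$n_planted_duplicates, "planted almonised duplicates\n")
  invisible(x)
}

#' Write charity extracts and ground truth to disk
#'
#' One comma-separated file per charity (header row, ISO-8601 dates,
#' empty string for missing), a `ground_truth.csv` with the planted
#' per-person strata and feature counts, and a `salts.csv` carrying the
#' per-provider salt out-of-band from the extracts themselves.
#'
#' @param extracts a [generate_charity_extracts()] result.
#' @param dir output directory (created if absent).
#' @param salt the shared linkage salt written to `salts.csv`.
#' @return `dir`, invisibly.
#' @export
write_extracts <- function(extracts, dir, salt = "synthetic-linkage-salt") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(extracts$extracts)) {
    readr::write_csv(extracts$extracts[[nm]],
                     file.path(dir, paste0(nm, ".csv")), na = "")
  }
  readr::write_csv(extracts$truth$persons,
                   file.path(dir, "ground_truth.csv"), na = "")
  readr::write_csv(
    tibble::tibble(provider = names(extracts$extracts), salt = salt),
    file.path(dir, "salts.csv")
  )
  invisible(dir)
}
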