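#' Describe one provider's file layout
#'
#' A schema maps a provider's column names onto the canonical fields
#' and records the provider's date dialect. Canonical fields:
#' `service_number`, `date_of_birth`, `gender`, `date`,
#' `provider_category`, `role`, plus the harmonized attribute columns.
#'
#' @param provider short provider code (used in reports and needs).
#' @param columns named character vector `c(provider_column =
#'   canonical_field)`; columns already canonically named need no
#'   entry.
#' @param date_format date dialect of the file, see
#'   [canonicalize_key()].
#' @return a list of class `provider_schema`.
#' @export
provider_schema <- function(provider, columns = character(),
                            date_format = "ymd") {
  structure(
    list(provider = provider, columns = columns, date_format = date_format),
    class = "provider_schema"
  )
}

mandatory_fields <- function() {
  c("service_number", "date_of_birth", "gender", "date", "provider_category")
}

#' Parse one raw charity file
#'
#' Reads a delimited provider extract, renames columns per the schema,
#' and parses dates under the provider's dialect. Malformed rows
#' (unparseable date, empty identifying field) are collected into a
#' rejects table with row numbers and reasons — never silently
#' dropped; missing mandatory columns are an error.
#'
#' @param path path to a comma-separated extract with a header row.
#' @param schema a [provider_schema()].
#' @return a list of class `parsed_extract`: `records` (clean rows with
#'   a `provider` column), `rejects` (tibble of `row`, `reason`).
#' @export
parse_charity_file <- function(path, schema) {
  if (!file.exists(path)) {
    stop_vetlink(sprintf("file not found: %s", path), "vetlink_config_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  raw[raw == ""] <- NA
  hit <- names(raw) %in% names(schema$columns)
  names(raw)[hit] <- unname(schema$columns[names(raw)[hit]])
  missing_cols <- setdiff(mandatory_fields(), names(raw))
  if (length(missing_cols)) {
    stop_vetlink(
      sprintf("%s: missing mandatory column(s): %s", path,
              paste(missing_cols, collapse = ", ")),
      "vetlink_schema_error"
    )
  }

  reasons <- rep(NA_character_, nrow(raw))
  dob <- parse_identity_date(raw$date_of_birth, schema$date_format)
  evt <- parse_identity_date(raw$date, schema$date_format)
  gender <- canonical_gender(raw$gender)
  reasons[is.na(raw$service_number)] <- "missing service number"
  reasons[is.na(raw$provider_category)] <- "missing need category"
  reasons[is.na(gender)] <- "bad gender"
  reasons[is.na(dob) | is.na(evt)] <- "bad date"

  keep <- is.na(reasons)
  records <- raw[keep, , drop = FALSE]
  records$date_of_birth <- dob[keep]
  records$date <- evt[keep]
  records$gender <- gender[keep]
  records$provider <- schema$provider

  structure(
    list(
      records = tibble::as_tibble(records),
      rejects = tibble::tibble(row = which(!keep),
                               reason = reasons[!keep])
    ),
    class = "parsed_extract"
  )
}

#' @export
print.parsed_extract <- function(x, ...) {
  cat("parsed extract:", nrow(x$records), "records,",
      nrow(x$rejects), "rejects\n")
  invisible(x)
}

#' Last-declared attribute resolution
#'
#' Resolves one attribute for one person from their records: the value
#' attached to the latest declaration date wins, but a missing value
#' never wins over a present one (the latest non-missing declaration is
#' taken; all-missing resolves to missing). Ties on the declaration
#' date are broken by `priority` (larger wins; e.g. a provider
#' priority), then by input order (later record wins), so resolution
#' depends only on dates and priorities, not on how records happened to
#' be ordered.
#'
#' @param values vector of declared values (NA = missing).
#' @param dates declaration dates, same length.
#' @param priority optional numeric tie-break, same length.
#' @return the resolved value (possibly NA).
#' @export
resolve_attribute <- function(values, dates, priority = NULL) {
  stopifnot(length(values) == length(dates))
  ok <- !is.na(values)
  if (!any(ok)) return(values[NA_integer_])
  values <- values[ok]
  dates <- dates[ok]
  priority <- if (is.null(priority)) seq_along(values) else priority[ok]
  ord <- order(dates, priority, seq_along(values))
  values[ord[length(ord)]]
}

#' Veteran-over-family role precedence
#'
#' A person recorded both as a veteran and as a family member (for
#' example the spouse of a veteran who is also a veteran) is classified
#' as a veteran: any veteran tag wins.
#'
#' @param roles character vector of `"veteran"` / `"family"` tags for
#'   one person's records.
#' @return `"veteran"` if any record is tagged veteran, else
#'   `"family"`.
#' @export
resolve_role <- function(roles) {
  bad <- setdiff(unique(roles), c("veteran", "family"))
  if (length(bad) || any(is.na(roles))) {
    stop_vetlink(
      sprintf("untagged or unknown role value(s): %s",
              paste(bad, collapse = ", ")),
      "vetlink_validation_error"
    )
  }
  if (any(roles == "veteran")) "veteran" else "family"
}

#' Age in completed years and the working-age band
#'
#' Age is the difference between the first recorded need and the date
#' of birth in completed whole years: if the birthday has not yet been
#' reached in the need's year, one year less. `classify_age_band()`
#' assigns `working` to ages strictly below the threshold (default 66,
#' the state-pension boundary) and `non_working` at or above it.
#'
#' @param date_of_birth `Date` vector.
#' @param at_date `Date` vector, the date the age is computed at
#'   (first recorded need).
#' @return integer vector of completed years.
#' @export
compute_age <- function(date_of_birth, at_date) {
  date_of_birth <- as.Date(date_of_birth)
  at_date <- as.Date(at_date)
  if (any(at_date < date_of_birth, na.rm = TRUE)) {
    stop_vetlink("need date before date of birth",
                 "vetlink_validation_error")
  }
  by <- as.integer(format(date_of_birth, "%Y"))
  ay <- as.integer(format(at_date, "%Y"))
  before_birthday <- format(at_date, "%m%d") < format(date_of_birth, "%m%d")
  ay - by - as.integer(before_birthday)
}

#' @rdname compute_age
#' @param age integer vector of ages in completed years.
#' @param threshold age at which `working` turns into `non_working`.
#' @export
classify_age_band <- function(age, threshold = 66) {
  ifelse(is.na(age), NA_character_,
         ifelse(age < threshold, "working", "non_working"))
}

#' Merge anonymized extracts into one registry
#'
#' Concatenates anonymized provider extracts, maps provider categories
#' through the taxonomy, collapses almonised duplicates — the same
#' person, mapped need category and calendar year contributed by more
#' than one provider (or more than once within a year) counts as one
#' need — and resolves one harmonized profile per distinct hashed
#' identifier: last-declared attributes, veteran-over-family role, age
#' at first need and the working-age band.
#'
#' Re-running the build on an already-collapsed registry changes
#' nothing, and profile resolution does not depend on the order records
#' arrive in.
#'
#' @param extracts list of anonymized extract tibbles (each with
#'   `hashed_id`, `provider`, `provider_category`, `date`,
#'   `age_at_event`, `gender`, `role` and attribute columns). A single
#'   tibble is accepted.
#' @param taxonomy taxonomy tibble for the layer-2 mapping.
#' @param collapse_layer `"dd"` (default) to collapse duplicates at the
#'   harmonized layer-2 category, `"provider"` to collapse at the raw
#'   provider wording.
#' @param age_threshold working-age boundary passed to
#'   [classify_age_band()].
#' @return a list of class `registry`: `profiles` (one row per person),
#'   `needs` (collapsed need records with both taxonomy layers) and
#'   `report` (person/need counts, per-provider persons, collapse and
#'   unmapped counts).
#' @export
build_registry <- function(extracts, taxonomy = default_taxonomy(),
                           collapse_layer = c("dd", "provider"),
                           age_threshold = 66) {
  collapse_layer <- match.arg(collapse_layer)
  if (is.data.frame(extracts)) extracts <- list(extracts)
  rows <- dplyr::bind_rows(extracts)
  req <- c("hashed_id", "provider", "provider_category", "date",
           "age_at_event", "gender", "role")
  miss <- setdiff(req, names(rows))
  if (length(miss)) {
    stop_vetlink(
      sprintf("anonymized extracts lack column(s): %s",
              paste(miss, collapse = ", ")),
      "vetlink_pipeline_order_error"
    )
  }

  mapped <- map_need(rows$provider_category, taxonomy)
  rows$dd_category <- mapped$dd_category
  rows$pillar <- mapped$pillar
  rows$year <- as.integer(format(rows$date, "%Y"))
  rows$need_key <- if (collapse_layer == "dd") {
    rows$dd_category
  } else {
    rows$provider_category
  }

  needs_all <- rows[c("hashed_id", "provider", "provider_category",
                      "dd_category", "pillar", "date", "year", "need_key")]
  needs <- needs_all |>
    dplyr::arrange(.data$date, .data$provider) |>
    dplyr::distinct(.data$hashed_id, .data$need_key, .data$year,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$hashed_id, .data$date)
  n_collapsed <- nrow(needs_all) - nrow(needs)
  needs$need_key <- NULL

  gender_conflicts <- rows |>
    dplyr::group_by(.data$hashed_id) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$gender), .groups = "drop")
  if (any(gender_conflicts$k > 1)) {
    warn(sprintf(
      "%d person(s) with conflicting gender across records; last-declared value used",
      sum(gender_conflicts$k > 1)
    ))
  }

  attr_cols <- intersect(
    c("gender", "rank", "marital_status", "service_branch",
      "accommodation", "benefits_receipt", "n_dependants"),
    names(rows)
  )
  profiles <- rows |>
    dplyr::group_by(.data$hashed_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(attr_cols),
                    ~ resolve_attribute(.x, .data$date)),
      role = resolve_role(.data$role),
      age_at_first_need = .data$age_at_event[which.min(.data$date)],
      .groups = "drop"
    )
  profiles$age_band <- classify_age_band(profiles$age_at_first_need,
                                         age_threshold)

  report <- list(
    n_persons = nrow(profiles),
    n_raw_records = nrow(rows),
    n_needs = nrow(needs),
    n_collapsed = n_collapsed,
    n_unmapped = attr(mapped, "n_unmapped"),
    persons_per_provider = rows |>
      dplyr::distinct(.data$provider, .data$hashed_id) |>
      dplyr::count(.data$provider, name = "n_persons"),
    collapse_layer = collapse_layer
  )
  structure(list(profiles = profiles, needs = needs, report = report),
            class = "registry")
}

#' @export
print.registry <- function(x, ...) {
  cat("registry:", x$report$n_persons, "persons,", x$report$n_needs,
      "needs (", x$report$n_collapsed, "almonised duplicates collapsed,",
      x$report$n_unmapped, "unmapped categories )\n")
  invisible(x)
}
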