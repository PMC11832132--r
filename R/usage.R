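#' Per-veteran usage summary
#'
#' Computes, for every person in a collapsed need table, the outcome
#' variables of the registry:
#'
#' * `n_access_years` — number of distinct calendar years with at least
#'   one need (the number of accesses);
#' * `n_needs` — total needs, i.e. distinct (category, year) pairs
#'   after almonisation collapse;
#' * `max_years_single_need` — the largest number of distinct years any
#'   single category was met in;
#' * `has_repeated_need` — whether some category was met in a year
#'   strictly later than a year in which it had already been met
#'   (equivalently `max_years_single_need >= 2`). Two requests for the
#'   same category within one year are one need and no repetition.
#'
#' Repetition is evaluated at the category layer the needs carry
#' (default: layer-2 Dual Diagnosis categories, matching the
#' almonisation collapse key).
#'
#' @param needs collapsed need records (columns `hashed_id`, `year` and
#'   the category layer in `layer`).
#' @param layer column holding the need category (default
#'   `"dd_category"`).
#' @return a tibble, one row per person, with the four summary fields.
#' @export
summarize_usage <- function(needs, layer = "dd_category") {
  if (nrow(needs) == 0) {
    stop_vetlink("empty need table: persons enter the registry only via a need",
                 "vetlink_validation_error")
  }
  if (!layer %in% names(needs)) {
    stop_vetlink(sprintf("no `%s` column in needs", layer),
                 "vetlink_validation_error")
  }
  cat_col <- needs[[layer]]
  needs |>
    dplyr::mutate(.category = cat_col) |>
    dplyr::group_by(.data$hashed_id) |>
    dplyr::summarise(
      n_access_years = dplyr::n_distinct(.data$year),
      n_needs = dplyr::n_distinct(paste(.data$.category, .data$year)),
      max_years_single_need = max(tapply(.data$year, .data$.category,
                                         function(y) length(unique(y)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(has_repeated_need = .data$max_years_single_need >= 2)
}

#' Assign the four a-priori usage-pattern strata
#'
#' The classification rules are total over valid summaries:
#' one access year and one need is `single_access_single_need`; one
#' access year and several needs is `single_access_multiple_needs`;
#' two or more access years with a repeated need is
#' `multiple_access_repeated_needs`; two or more access years with
#' every need new is `multiple_access_all_new_needs`.
#'
#' @param n_access_years,n_needs,has_repeated_need vectors of equal
#'   length (typically columns of [summarize_usage()] output).
#' @return character vector of stratum labels (see
#'   [stratum_levels()]).
#' @export
classify_pattern <- function(n_access_years, n_needs, has_repeated_need) {
  if (any(n_access_years < 1 | n_needs < 1, na.rm = TRUE)) {
    stop_vetlink("usage summaries need n_access_years >= 1 and n_needs >= 1",
                 "vetlink_validation_error")
  }
  dplyr::case_when(
    n_access_years == 1 & n_needs == 1 ~ "single_access_single_need",
    n_access_years == 1 & n_needs >= 2 ~ "single_access_multiple_needs",
    n_access_years >= 2 & has_repeated_need ~ "multiple_access_repeated_needs",
    n_access_years >= 2 & !has_repeated_need ~ "multiple_access_all_new_needs"
  )
}

#' Clustering feature matrix
#'
#' The fixed-order numeric feature triple used for k-means: total
#' accesses (distinct years), total needs, and the per-category year
#' counts summarized by their maximum — the quantity that separates
#' repeated from all-new usage (maximum at least 2 exactly when some
#' need repeated).
#'
#' @param summaries a [summarize_usage()] result.
#' @return numeric matrix with columns `n_access_years`, `n_needs`,
#'   `max_years_single_need`; row names are the hashed identifiers.
#' @export
build_features <- function(summaries) {
  m <- as.matrix(summaries[c("n_access_years", "n_needs",
                             "max_years_single_need")])
  rownames(m) <- summaries$hashed_id
  m
}

#' Summarize and stratify a registry
#'
#' Runs [summarize_usage()] and [classify_pattern()] over a built
#' registry, returning one row per veteran with the feature fields and
#' the a-priori stratum.
#'
#' @param registry a [build_registry()] result.
#' @param layer category layer for repetition, see [summarize_usage()].
#' @return a tibble of usage summaries with a `stratum` column.
#' @export
stratify_registry <- function(registry, layer = "dd_category") {
  summaries <- summarize_usage(registry$needs, layer = layer)
  summaries$stratum <- classify_pattern(summaries$n_access_years,
                                        summaries$n_needs,
                                        summaries$has_repeated_need)
  summaries
}
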