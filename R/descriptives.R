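#' One-variable frequency table
#'
#' Counts and percentages for one categorical profile variable, the
#' building block of the registry's descriptive tables. Missing values
#' are excluded from the denominator — each variable reports over its
#' own non-missing denominator, so denominators visibly differ across
#' variables. Percentages are 100 * count / denominator rounded half-up
#' to one decimal.
#'
#' @param data data frame of profiles (or any table with the
#'   variable), or a named numeric vector of counts to tabulate
#'   directly.
#' @param variable column name to tabulate (ignored for a counts
#'   vector).
#' @param levels optional level ordering; defaults to sorted observed
#'   levels.
#' @return a tibble of class `frequency_table` with columns `level`,
#'   `count`, `percent`; attributes `variable` and `denominator`.
#' @export
#' @examples
#' frequency_table(c(Female = 4802, Male = 37453, Other = 9))
frequency_table <- function(data, variable = NULL, levels = NULL) {
  if (is.numeric(data) && !is.null(names(data))) {
    counts <- data
    variable <- variable %||% "counts"
  } else {
    if (is.null(variable) || !variable %in% names(data)) {
      stop_vetlink(
        sprintf("unknown variable `%s`; available: %s",
                variable %||% "<missing>",
                paste(names(data), collapse = ", ")),
        "vetlink_validation_error"
      )
    }
    x <- data[[variable]]
    x <- x[!is.na(x)]
    counts <- table(x)
    counts <- setNames(as.numeric(counts), names(counts))
  }
  if (!is.null(levels)) {
    counts <- counts[levels]
    counts[is.na(counts)] <- 0
    names(counts) <- levels
  }
  denom <- sum(counts)
  out <- tibble::tibble(
    level = names(counts),
    count = as.numeric(counts),
    percent = round_half_up(100 * as.numeric(counts) / denom, 1)
  )
  attr(out, "variable") <- variable
  attr(out, "denominator") <- denom
  class(out) <- c("frequency_table", class(out))
  out
}

#' Per-pillar helped flags
#'
#' One boolean per pillar per veteran: whether the person was helped at
#' least once for a need in that pillar. The flags are non-exclusive —
#' a veteran helped for both a physical and a social need is counted in
#' both rows, so pillar percentages may jointly exceed 100.
#'
#' @param needs mapped need records (columns `hashed_id`, `pillar`).
#' @return a tibble, one row per person, with logical columns
#'   `helped_physical`, `helped_mental`, `helped_social`.
#' @export
multi_need_flags <- function(needs) {
  needs |>
    dplyr::group_by(.data$hashed_id) |>
    dplyr::summarise(
      helped_physical = any(.data$pillar == "physical"),
      helped_mental = any(.data$pillar == "mental"),
      helped_social = any(.data$pillar == "social"),
      .groups = "drop"
    )
}

#' Cross-tabulate a profile variable by stratum
#'
#' Observed counts of a categorical variable against the four
#' usage-pattern strata, missing values dropped.
#'
#' @param profiles profiles tibble carrying the variable and a
#'   `stratum` column (join [stratify_registry()] output onto
#'   profiles).
#' @param variable column name to cross-tabulate.
#' @return an r x (number of strata) integer matrix.
#' @export
crosstab_by_stratum <- function(profiles, variable) {
  if (!variable %in% names(profiles)) {
    stop_vetlink(
      sprintf("unknown variable `%s`; available: %s", variable,
              paste(names(profiles), collapse = ", ")),
      "vetlink_validation_error"
    )
  }
  if (!"stratum" %in% names(profiles)) {
    stop_vetlink("profiles carry no `stratum` column",
                 "vetlink_validation_error")
  }
  keep <- !is.na(profiles[[variable]]) & !is.na(profiles$stratum)
  tab <- table(profiles[[variable]][keep], profiles$stratum[keep])
  as.matrix(unclass(tab))
}

#' Pearson chi-square test on an observed contingency table
#'
#' Pearson's chi-square without continuity correction, expected counts
#' from the margins, degrees of freedom (r - 1)(c - 1). A warning flag
#' is set when any expected count falls below 5 (the usual validity
#' caveat for sparse cells). Per-test significance at p < .05 with no
#' multiple-testing adjustment is the reporting convention mirrored
#' here; see the package vignette for the caveat.
#'
#' @param observed numeric matrix of observed counts (r x c, r, c >=
#'   2).
#' @return a list of class `contingency_result`: `observed`,
#'   `expected`, `statistic`, `df`, `p_value`, `low_expected`.
#' @export
chi_square <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    stop_vetlink("chi-square needs at least a 2 x 2 table",
                 "vetlink_validation_error")
  }
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0)) {
    stop_vetlink("degenerate table: a row or column margin is zero",
                 "vetlink_validation_error")
  }
  fit <- suppressWarnings(chisq.test(observed, correct = FALSE))
  structure(
    list(
      observed = observed,
      expected = fit$expected,
      statistic = unname(fit$statistic),
      df = unname(fit$parameter),
      p_value = unname(fit$p.value),
      low_expected = any(fit$expected < 5)
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$low_expected) " (expected count < 5 in some cell)" else ""))
  invisible(x)
}

#' Characteristics table of the registry population
#'
#' Frequency and percentage blocks for the harmonized profile
#' variables plus the non-exclusive type-of-need flags and the
#' needs-per-veteran distribution — the shape of the registry's
#' population-description table.
#'
#' @param registry a [build_registry()] result.
#' @param summaries a [stratify_registry()] result.
#' @return a tibble with columns `variable`, `level`, `count`,
#'   `percent`.
#' @export
table_characteristics <- function(registry, summaries) {
  profiles <- registry$profiles
  vars <- intersect(
    c("gender", "age_band", "rank", "marital_status", "service_branch",
      "accommodation", "benefits_receipt", "n_dependants"),
    names(profiles)
  )
  blocks <- lapply(vars, function(v) {
    ft <- frequency_table(profiles, v)
    tibble::tibble(variable = v, level = ft$level, count = ft$count,
                   percent = ft$percent)
  })

  flags <- multi_need_flags(registry$needs)
  n <- nrow(flags)
  pillar_block <- tibble::tibble(
    variable = "type_of_need",
    level = c("helped_physical", "helped_mental", "helped_social"),
    count = c(sum(flags$helped_physical), sum(flags$helped_mental),
              sum(flags$helped_social)),
    percent = round_half_up(100 * c(sum(flags$helped_physical),
                                    sum(flags$helped_mental),
                                    sum(flags$helped_social)) / n, 1)
  )

  needs_band <- cut(summaries$n_needs, c(0, 1, 2, 3, 4, Inf),
                    labels = c("1", "2", "3", "4", "5+"))
  needs_block <- {
    ft <- frequency_table(data.frame(n_needs_band = needs_band),
                          "n_needs_band")
    tibble::tibble(variable = "needs_per_veteran", level = ft$level,
                   count = ft$count, percent = ft$percent)
  }
  strat_block <- {
    ft <- frequency_table(data.frame(stratum = summaries$stratum), "stratum",
                          levels = stratum_levels())
    tibble::tibble(variable = "accesses_per_veteran", level = ft$level,
                   count = ft$count, percent = ft$percent)
  }

  dplyr::bind_rows(c(blocks, list(pillar_block, needs_block, strat_block)))
}

#' Stratified characteristics table with chi-square tests
#'
#' Cross-tabulates each profile variable by the four usage-pattern
#' strata, with within-stratum percentages and a Pearson chi-square
#' p-value per variable.
#'
#' @param registry a [build_registry()] result.
#' @param summaries a [stratify_registry()] result.
#' @return a list with `table` (tibble: variable, level, per-stratum
#'   count and percent columns) and `tests` (tibble: variable,
#'   statistic, df, p_value, low_expected).
#' @export
table_by_stratum <- function(registry, summaries) {
  profiles <- dplyr::left_join(
    registry$profiles,
    summaries[c("hashed_id", "stratum")],
    by = "hashed_id"
  )
  vars <- intersect(
    c("gender", "age_band", "rank", "marital_status", "service_branch",
      "accommodation", "benefits_receipt", "n_dependants"),
    names(profiles)
  )
  rows <- list()
  tests <- list()
  for (v in vars) {
    tab <- crosstab_by_stratum(profiles, v)
    pct <- round_half_up(100 * sweep(tab, 2, colSums(tab), "/"), 1)
    block <- tibble::tibble(variable = v, level = rownames(tab))
    for (s in colnames(tab)) {
      block[[paste0(s, "_count")]] <- as.numeric(tab[, s])
      block[[paste0(s, "_percent")]] <- as.numeric(pct[, s])
    }
    rows[[v]] <- block
    ct <- try(chi_square(tab), silent = TRUE)
    tests[[v]] <- if (inherits(ct, "try-error")) {
      tibble::tibble(variable = v, statistic = NA_real_, df = NA_integer_,
                     p_value = NA_real_, low_expected = NA)
    } else {
      tibble::tibble(variable = v, statistic = ct$statistic, df = ct$df,
                     p_value = ct$p_value, low_expected = ct$low_expected)
    }
  }
  list(table = dplyr::bind_rows(rows), tests = dplyr::bind_rows(tests))
}
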