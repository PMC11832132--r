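#' The twelve Dual Diagnosis need categories
#'
#' Middle layer of the three-layer need aggregation: provider category
#' (layer 1) -> Dual Diagnosis category (layer 2) -> pillar of health
#' (layer 3).
#'
#' @return character vector of the 12 category names.
#' @export
dd_categories <- function() {
  c(
    "family or relationship difficulties",
    "mental health issues",
    "social isolation",
    "substance misuse issues",
    "physical health",
    "history of offending behaviour",
    "learning disability",
    "physical disability",
    "domestic violence",
    "employment problems",
    "homelessness or housing issues",
    "poverty"
  )
}

#' Default assignment of Dual Diagnosis categories to pillars of health
#'
#' Maps each of the twelve layer-2 categories onto the WHO triad of
#' physical, mental and social health. The assignment is an editorial
#' judgement shipped as editable configuration, not a fixed fact:
#' mental covers mental health, substance misuse and learning
#' disability; physical covers physical health and physical disability;
#' the remaining seven categories are social.
#'
#' @return named character vector, names = layer-2 category, value =
#'   pillar (`"physical"`, `"mental"` or `"social"`).
#' @export
default_pillar_map <- function() {
  c(
    "family or relationship difficulties" = "social",
    "mental health issues"                = "mental",
    "social isolation"                    = "social",
    "substance misuse issues"             = "mental",
    "physical health"                     = "physical",
    "history of offending behaviour"      = "social",
    "learning disability"                 = "mental",
    "physical disability"                 = "physical",
    "domestic violence"                   = "social",
    "employment problems"                 = "social",
    "homelessness or housing issues"      = "social",
    "poverty"                             = "social"
  )
}

# provider-vocabulary terms used by the synthetic generator; two terms
# per layer-2 category so that layer-2 collapse across differently
# worded provider records is exercised
synthetic_provider_terms <- function() {
  list(
    "family or relationship difficulties" = c("family breakdown", "relationship support"),
    "mental health issues"                = c("ptsd support", "depression counselling"),
    "social isolation"                    = c("loneliness", "community reintegration"),
    "substance misuse issues"             = c("alcohol misuse", "drug dependency"),
    "physical health"                     = c("medical treatment", "mobility aid"),
    "history of offending behaviour"      = c("ex-offender support", "probation liaison"),
    "learning disability"                 = c("learning support", "literacy help"),
    "physical disability"                 = c("disability adaptation", "wheelchair provision"),
    "domestic violence"                   = c("domestic abuse refuge", "safeguarding referral"),
    "employment problems"                 = c("job seeking", "retraining grant"),
    "homelessness or housing issues"      = c("rent arrears", "emergency housing"),
    "poverty"                             = c("food bank referral", "debt relief grant")
  )
}

#' Default need taxonomy
#'
#' A complete three-layer taxonomy aligned with the synthetic
#' generator's provider vocabulary: each provider term maps to one of
#' the twelve Dual Diagnosis categories, each of which carries a fixed
#' pillar from [default_pillar_map()]. Real deployments replace this
#' with their own mapping file (see [read_taxonomy()]).
#'
#' @param pillar_map named vector assigning each layer-2 category a
#'   pillar; defaults to [default_pillar_map()].
#' @return a tibble with columns `provider_category`, `dd_category`,
#'   `pillar`.
#' @export
default_taxonomy <- function(pillar_map = default_pillar_map()) {
  terms <- synthetic_provider_terms()
  tibble::tibble(
    provider_category = unlist(terms, use.names = FALSE),
    dd_category = rep(names(terms), vapply(terms, length, integer(1))),
    pillar = unname(pillar_map[rep(names(terms), vapply(terms, length, integer(1)))])
  )
}

#' Validate a taxonomy table
#'
#' Checks a provider -> Dual Diagnosis -> pillar mapping for structural
#' violations: layer-2 categories outside the twelve known ones, a
#' layer-2 category assigned to more than one pillar, and duplicated
#' provider keys. Returns a report rather than failing, so callers can
#' surface all problems at once; the pipeline refuses to run on a
#' failing report.
#'
#' @param taxonomy a tibble as produced by [default_taxonomy()] or
#'   [read_taxonomy()].
#' @return a list of class `taxonomy_validation` with elements `valid`
#'   (logical) and `violations` (tibble with `type` and `detail`).
#' @export
validate_taxonomy <- function(taxonomy) {
  violations <- list()
  unknown <- setdiff(unique(taxonomy$dd_category), dd_categories())
  if (length(unknown)) {
    violations <- c(violations, lapply(unknown, function(u) {
      tibble::tibble(type = "unknown_dd_category", detail = u)
    }))
  }
  pillar_counts <- tapply(taxonomy$pillar, taxonomy$dd_category,
                          function(p) length(unique(p)))
  multi <- names(pillar_counts)[pillar_counts > 1]
  if (length(multi)) {
    violations <- c(violations, lapply(multi, function(m) {
      tibble::tibble(type = "dd_category_in_multiple_pillars", detail = m)
    }))
  }
  bad_pillar <- setdiff(unique(taxonomy$pillar),
                        c("physical", "mental", "social"))
  if (length(bad_pillar)) {
    violations <- c(violations, lapply(bad_pillar, function(p) {
      tibble::tibble(type = "unknown_pillar", detail = p)
    }))
  }
  dup <- unique(taxonomy$provider_category[duplicated(taxonomy$provider_category)])
  if (length(dup)) {
    violations <- c(violations, lapply(dup, function(d) {
      tibble::tibble(type = "duplicate_provider_key", detail = d)
    }))
  }
  violations <- if (length(violations)) {
    dplyr::bind_rows(violations)
  } else {
    tibble::tibble(type = character(), detail = character())
  }
  structure(
    list(valid = nrow(violations) == 0, violations = violations),
    class = "taxonomy_validation"
  )
}

#' @export
print.taxonomy_validation <- function(x, ...) {
  if (x$valid) {
    cat("taxonomy valid: 0 violations\n")
  } else {
    cat("taxonomy INVALID:", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}

#' Map provider need categories through the taxonomy
#'
#' Looks each provider category up in the taxonomy and returns both
#' aggregation layers. Categories absent from the taxonomy are routed
#' to an explicit `"unmapped"` bucket (both layers) and counted in the
#' `n_unmapped` attribute; they are never silently coerced or dropped.
#'
#' @param provider_category character vector of raw provider terms.
#' @param taxonomy validated taxonomy tibble.
#' @return a tibble with columns `dd_category` and `pillar`, one row
#'   per input, with attribute `n_unmapped`.
#' @export
map_need <- function(provider_category, taxonomy = default_taxonomy()) {
  idx <- match(provider_category, taxonomy$provider_category)
  out <- tibble::tibble(
    dd_category = ifelse(is.na(idx), "unmapped", taxonomy$dd_category[idx]),
    pillar = ifelse(is.na(idx), "unmapped", taxonomy$pillar[idx])
  )
  attr(out, "n_unmapped") <- sum(is.na(idx))
  out
}

#' Read a taxonomy from a YAML file
#'
#' Expected structure: a `dd_to_pillar` mapping (layer-2 category ->
#' pillar) and a `provider_to_dd` mapping (provider term -> layer-2
#' category). The file is validated with [validate_taxonomy()] and an
#' error is raised on a failing report.
#'
#' @param path path to a YAML taxonomy file.
#' @return a validated taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!all(c("dd_to_pillar", "provider_to_dd") %in% names(spec))) {
    stop_vetlink("taxonomy file needs `dd_to_pillar` and `provider_to_dd`",
                 "vetlink_config_error")
  }
  pillar_map <- unlist(spec$dd_to_pillar)
  provider_map <- unlist(spec$provider_to_dd)
  taxonomy <- tibble::tibble(
    provider_category = names(provider_map),
    dd_category = unname(provider_map),
    pillar = unname(pillar_map[unname(provider_map)])
  )
  report <- validate_taxonomy(taxonomy)
  if (!report$valid) {
    stop_vetlink(
      paste0("invalid taxonomy file: ",
             paste(report$violations$type, report$violations$detail,
                   sep = ": ", collapse = "; ")),
      "vetlink_config_error"
    )
  }
  taxonomy
}

#' Write a taxonomy to a YAML file
#'
#' @param taxonomy taxonomy tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  dd <- unique(taxonomy[c("dd_category", "pillar")])
  yaml::write_yaml(
    list(
      dd_to_pillar = as.list(setNames(dd$pillar, dd$dd_category)),
      provider_to_dd = as.list(setNames(taxonomy$dd_category,
                                        taxonomy$provider_category))
    ),
    path
  )
  invisible(path)
}
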