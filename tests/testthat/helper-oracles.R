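# Independent naive oracles, kept deliberately simple and separate from
# the package's implementation paths.

# per-person usage summary by explicit loops over a (category, year) table
naive_usage <- function(categories, years) {
  pairs <- unique(data.frame(category = categories, year = years))
  yrs <- unique(pairs$year)
  per_cat <- sapply(unique(pairs$category), function(ct) {
    length(unique(pairs$year[pairs$category == ct]))
  })
  list(
    n_access_years = length(yrs),
    n_needs = nrow(pairs),
    max_years_single_need = max(per_cat),
    has_repeated_need = any(per_cat >= 2)
  )
}

# Pearson chi-square by double loop over cells
naive_chisq <- function(observed) {
  total <- sum(observed)
  stat <- 0
  for (i in seq_len(nrow(observed))) {
    for (j in seq_len(ncol(observed))) {
      e <- sum(observed[i, ]) * sum(observed[, j]) / total
      stat <- stat + (observed[i, j] - e)^2 / e
    }
  }
  list(statistic = stat, df = (nrow(observed) - 1) * (ncol(observed) - 1))
}

# truth table for the a-priori classification, written directly from the
# subgroup definitions
truth_table_label <- function(years, needs, repeated) {
  if (years == 1) {
    if (needs == 1) "single_access_single_need" else "single_access_multiple_needs"
  } else {
    if (repeated) "multiple_access_repeated_needs" else "multiple_access_all_new_needs"
  }
}

# tiny hand-built anonymized extract (already hashed), for registry tests
make_anon_extract <- function(hashed_id, provider, provider_category,
                              date, age = 50, gender = "M",
                              role = "veteran") {
  tibble::tibble(
    hashed_id = hashed_id,
    provider = provider,
    provider_category = provider_category,
    date = as.Date(date),
    age_at_event = age,
    gender = gender,
    role = role
  )
}

# partitions equal up to relabeling
same_partition <- function(a, b) {
  all(rowSums(table(a, b) > 0) == 1) && all(colSums(table(a, b) > 0) == 1)
}
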