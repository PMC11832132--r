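#' Z-score a feature matrix
#'
#' Centers each column to mean 0 and scales to variance 1 before
#' Euclidean clustering, so that no count dominates the distance by
#' scale alone. Constant columns carry no distance information and are
#' mapped to 0 with a warning.
#'
#' @param x numeric matrix with at least two rows and no missing
#'   entries.
#' @return the standardized matrix (attributes `center` and `scale`
#'   retained).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    stop_vetlink("standardization needs at least two rows",
                 "vetlink_validation_error")
  }
  if (any(is.na(x))) {
    stop_vetlink("feature matrix has missing entries",
                 "vetlink_validation_error")
  }
  s <- apply(x, 2, sd)
  constant <- s < .Machine$double.eps
  if (any(constant)) {
    warn(sprintf("constant feature column(s) mapped to 0: %s",
                 paste(colnames(x)[constant], collapse = ", ")))
    s[constant] <- 1
  }
  z <- scale(x, center = TRUE, scale = s)
  attr(z, "scaled:scale") <- s
  z
}

# k-means++ seeding: first center uniform, later centers with
# probability proportional to squared distance to the nearest chosen
# center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 <= .Machine$double.eps)) {
      stop_vetlink("fewer distinct points than requested centers",
                   "vetlink_validation_error")
    }
    pick <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Fit k-means with k-means++ seeding and restarts
#'
#' Runs Lloyd's algorithm from `n_restarts` independent k-means++
#' seedings and keeps the solution with the lowest total
#' within-cluster sum of squares. Deterministic under a fixed `seed`.
#'
#' @param x standardized feature matrix.
#' @param k number of clusters (2 <= k <= number of distinct rows).
#' @param seed integer seed.
#' @param n_restarts number of independent seedings (default 10).
#' @return the best `stats::kmeans` fit.
#' @export
kmeans_fit <- function(x, k, seed = 1L, n_restarts = 10) {
  x <- as.matrix(x)
  if (k < 2 || k > nrow(x)) {
    stop_vetlink(sprintf("k = %d outside [2, n = %d]", k, nrow(x)),
                 "vetlink_validation_error")
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      kmeans(x, centers = centers, algorithm = "Lloyd", iter.max = 100)
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Select the number of clusters by mean silhouette
#'
#' For each candidate k, fits k-means (with restarts) and computes the
#' mean Euclidean silhouette width of the partition; returns the k with
#' the largest mean silhouette, ties going to the smallest k.
#' Candidates exceeding the number of distinct rows are dropped
#' (k-means is undefined there); if all rows are identical the
#' silhouette is undefined and an error is raised.
#'
#' @param x standardized feature matrix.
#' @param k_range candidate cluster counts (default `2:8`).
#' @param seed integer seed (each candidate uses a seed derived from
#'   it).
#' @param n_restarts restarts per candidate, see [kmeans_fit()].
#' @return a list of class `k_selection`: `k_selected`,
#'   `silhouette_by_k` (named numeric) and `fits` (the k-means fit per
#'   candidate).
#' @export
select_k <- function(x, k_range = 2:8, seed = 1L, n_restarts = 10) {
  x <- as.matrix(x)
  n_distinct_rows <- nrow(unique(x))
  if (n_distinct_rows < 2) {
    stop_vetlink("all rows identical: silhouette is undefined",
                 "vetlink_validation_error")
  }
  if (min(k_range) < 2 || max(k_range) > nrow(x) - 1) {
    stop_vetlink("k_range must lie within [2, n - 1]",
                 "vetlink_validation_error")
  }
  usable <- k_range[k_range <= n_distinct_rows]
  if (length(usable) < length(k_range)) {
    inform(sprintf(
      "dropping k > %d (number of distinct feature rows): %s",
      n_distinct_rows,
      paste(setdiff(k_range, usable), collapse = ", ")
    ))
  }
  d <- dist(x)
  sil <- setNames(numeric(length(usable)), usable)
  fits <- setNames(vector("list", length(usable)), usable)
  for (i in seq_along(usable)) {
    k <- usable[i]
    fit <- kmeans_fit(x, k, seed = seed + k, n_restarts = n_restarts)
    sil[i] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
    fits[[i]] <- fit
  }
  k_selected <- usable[which.max(sil)]  # which.max takes the first maximum
  structure(
    list(k_selected = k_selected, silhouette_by_k = sil, fits = fits),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat("silhouette-based selection: k =", x$k_selected, "\n")
  print(round(x$silhouette_by_k, 4))
  invisible(x)
}

#' Correspondence between clusters and a-priori strata
#'
#' Cross-tabulates the two partitions, computes the adjusted Rand
#' index, and flags exact correspondence: the contingency table is,
#' up to column permutation, diagonal — every stratum maps to exactly
#' one cluster and every cluster to exactly one stratum.
#'
#' @param clusters cluster labels.
#' @param strata a-priori stratum labels, same length.
#' @return a list of class `cluster_correspondence`: `contingency`,
#'   `ari`, `exact_match`.
#' @export
correspondence <- function(clusters, strata) {
  if (length(clusters) != length(strata)) {
    stop_vetlink("label vectors differ in length",
                 "vetlink_validation_error")
  }
  tab <- table(stratum = strata, cluster = clusters)
  exact <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
  structure(
    list(
      contingency = tab,
      ari = mclust::adjustedRandIndex(clusters, strata),
      exact_match = exact
    ),
    class = "cluster_correspondence"
  )
}

#' @export
print.cluster_correspondence <- function(x, ...) {
  cat("adjusted Rand index:", round(x$ari, 4),
      if (x$exact_match) "(exact correspondence)" else "", "\n")
  print(x$contingency)
  invisible(x)
}

#' Cluster usage summaries and compare with the a-priori strata
#'
#' End-to-end clustering stage: builds the feature triple, z-scores
#' it, selects k by mean silhouette over `k_range`, refits k-means at
#' the selected k, and quantifies the agreement between clusters and
#' the a-priori strata.
#'
#' @param summaries a [stratify_registry()] result (needs a `stratum`
#'   column).
#' @param k_range candidate cluster counts.
#' @param seed integer seed.
#' @param n_restarts restarts per k-means fit.
#' @return a list of class `cluster_result`: `k_selected`, `labels`,
#'   `silhouette_by_k`, `contingency`, `ari`, `exact_match`.
#' @export
cluster_usage <- function(summaries, k_range = 2:8, seed = 1L,
                          n_restarts = 10) {
  z <- standardize(build_features(summaries))
  sel <- select_k(z, k_range = k_range, seed = seed,
                  n_restarts = n_restarts)
  fit <- sel$fits[[as.character(sel$k_selected)]]
  corr <- correspondence(fit$cluster, summaries$stratum)
  structure(
    list(
      k_selected = sel$k_selected,
      labels = fit$cluster,
      silhouette_by_k = sel$silhouette_by_k,
      contingency = corr$contingency,
      ari = corr$ari,
      exact_match = corr$exact_match
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k-means usage clustering: k =", x$k_selected,
      "| ARI =", round(x$ari, 4),
      if (x$exact_match) "| exact stratum correspondence" else "", "\n")
  print(x$contingency)
  invisible(x)
}
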