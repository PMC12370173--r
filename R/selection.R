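#' Choose the number of clusters by the least-drop silhouette rule
#'
#' Evaluates the global silhouette of a k-means clustering for each
#' `k = 2..k_max` and selects the smallest k whose score is within `epsilon`
#' of the best score: the number of groups causing the least drop of the
#' silhouette, preferring fewer groups when scores are comparable.
#'
#' @param X Numeric matrix (records x features).
#' @param k_max Largest number of clusters to try (default 6).
#' @param epsilon Tolerance within which two silhouette scores count as
#'   comparable (default 0.01).
#' @param seed Seed shared (via derived child seeds) by the per-k k-means runs.
#' @param restarts Restarts per k-means run (default 20).
#' @param standardize Z-score columns before clustering (default `TRUE`).
#' @return List with `k` (the selected number of clusters), `scores` (tibble
#'   of k and silhouette), and `low_confidence` (`TRUE` when even the best
#'   silhouette falls below 0.25, i.e. no convincing cluster structure).
#' @export
select_num_clusters <- function(X, k_max = 6, epsilon = 0.01, seed = NULL,
                                restarts = 20, standardize = TRUE) {
  X <- as.matrix(X)
  assert_number(k_max, "k_max", min = 2)
  if (nrow(X) <= k_max) abort("Need more records than `k_max`.")
  if (standardize) X <- standardize_columns(X)
  ks <- 2:k_max
  scores <- vapply(ks, function(k) {
    fit <- kmeans_fit(X, k, seed = if (is.null(seed)) NULL else derive_seed(seed, "k", k),
                      restarts = restarts)
    silhouette_score(X, fit$assignments)$global
  }, numeric(1))
  k_star <- select_k_from_scores(ks, scores, epsilon)
  list(k = k_star,
       scores = tibble(k = ks, silhouette = scores),
       low_confidence = max(scores) < 0.25)
}

# least-drop rule on precomputed scores: smallest k within epsilon of the best
select_k_from_scores <- function(ks, scores, epsilon) {
  stopifnot(length(ks) == length(scores))
  ks[which(scores >= max(scores) - epsilon)[1]]
}

#' Greedy silhouette-guided backward feature elimination
#'
#' Trial-and-error feature pruning for clustering: at each step the single
#' feature whose removal yields the largest increase of the global silhouette
#' (at fixed k) is removed; the loop stops as soon as no removal improves the
#' score by more than `epsilon`. The tolerance matters: the silhouette of
#' well-separated clusters drifts up by a few thousandths whenever any
#' dimension is dropped (within-cluster scatter shrinks faster than
#' separation), so improvements within `epsilon` are treated as comparable
#' scores — the same convention the least-drop rule uses — and do not justify
#' discarding a marker. Ties are resolved toward the first (lowest-index)
#' feature. The returned silhouette trace is monotone increasing by
#' construction.
#'
#' @param X Numeric matrix (records x features), at least 2 columns.
#' @param k Number of clusters held fixed throughout.
#' @param epsilon Minimum silhouette improvement that justifies a removal
#'   (default 0.01).
#' @param seed Seed for the embedded k-means runs.
#' @param feature_names Feature names (default `colnames(X)`).
#' @param restarts Restarts per k-means run (default 20).
#' @param standardize Z-score columns before clustering (default `TRUE`).
#' @return List with `retained` (character vector of surviving features) and
#'   `trace` (tibble with step, removed feature, and silhouette after removal;
#'   step 0 is the full feature set).
#' @export
backward_eliminate <- function(X, k, seed = NULL, epsilon = 0.01,
                               feature_names = colnames(X),
                               restarts = 20, standardize = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) < 2) abort("Need at least 2 features to eliminate from.")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  colnames(X) <- feature_names
  if (standardize) X <- standardize_columns(X)

  score_of <- function(cols) {
    fit <- kmeans_fit(X[, cols, drop = FALSE], k,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, "elim", paste(cols, collapse = ",")),
                      restarts = restarts)
    silhouette_score(X[, cols, drop = FALSE], fit$assignments)$global
  }

  current <- feature_names
  trace <- tibble(step = 0L, removed = NA_character_, silhouette = score_of(current))
  while (length(current) > 1) {
    candidate_scores <- vapply(current, function(f)
      score_of(setdiff(current, f)), numeric(1))
    best <- which.max(candidate_scores) # ties -> first index
    if (candidate_scores[best] <= utils::tail(trace$silhouette, 1) + epsilon) break
    removed <- current[best]
    current <- setdiff(current, removed)
    trace <- dplyr::bind_rows(trace, tibble(step = nrow(trace),
                                            removed = removed,
                                            silhouette = candidate_scores[best]))
  }
  list(retained = current, trace = trace)
}
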