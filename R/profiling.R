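#' Profile one microenvironment condition level
#'
#' Runs the condition-stratified profiling stage for a single level: (1)
#' restrict the table to the records of that level, using only the 16 markers
#' as features (no microenvironment variables enter the feature matrix); (2)
#' z-score and cluster with k-means at K = 2, recording the silhouette and the
#' label-aligned confusion matrix of this blind clustering; (3) rank markers by
#' mutual information against the true cell-line label and retain those
#' strictly above `tau`; (4) re-cluster on the retained markers only and record
#' the post-reduction silhouette and confusion matrix. If no marker passes the
#' threshold the profile is still returned with `no_features = TRUE` and the
#' post-stage fields `NA` — an empty retained set is a reportable outcome.
#'
#' @param table A marker table containing both cell lines at this level.
#' @param variable,level A stratification level (see [condition_levels()]).
#' @param tau Mutual-information retention threshold (default 0.65 nats).
#' @param seed Master seed; stage seeds are derived from it.
#' @param estimator MI estimator (`"knn"` or `"binned"`).
#' @param restarts k-means restarts (default 20).
#' @param log_intensities Log-transform intensity markers in the clustering
#'   feature matrix (default `TRUE`; see [marker_feature_matrix()]).
#' @return An object of class `mps_profile`: list with `variable`, `level`,
#'   `n_records`, `silhouette_pre`, `silhouette_post`, `ranking`
#'   (an `mps_ranking`), `retained`, `confusion_pre`, `confusion_post`,
#'   `no_features`, `seed`.
#' @export
profile_condition <- function(table, variable, level, tau = 0.65, seed = NULL,
                              estimator = "knn", restarts = 20,
                              log_intensities = TRUE) {
  validate_marker_table(table, check_ranges = FALSE)
  envs <- env_ids_for_level(variable, level)
  sub <- dplyr::filter(table, .data$env_id %in% envs)
  if (nrow(sub) == 0) abort(sprintf("No records at level %s = %s.", variable, level))
  counts <- c(sum(sub$cell_line == "invasive"), sum(sub$cell_line == "noninvasive"))
  if (any(counts < 2)) {
    abort(sprintf("Level %s = %s needs >= 2 records of each cell line.", variable, level))
  }
  X <- as.matrix(sub[marker_names()])
  Xs <- marker_feature_matrix(sub, log_intensities = log_intensities)
  truth <- sub$cell_line

  pre_seed <- if (is.null(seed)) NULL else derive_seed(seed, "pre", variable, level)
  fit_pre <- kmeans_fit(Xs, 2, seed = pre_seed, restarts = restarts)
  sil_pre <- silhouette_score(Xs, fit_pre$assignments)$global
  conf_pre <- align_clusters(fit_pre$assignments, truth)

  mi_seed <- if (is.null(seed)) NULL else derive_seed(seed, "mi", variable, level)
  ranking <- rank_features(X, truth, marker_names = marker_names(), tau = tau,
                           estimator = estimator, seed = mi_seed)
  retained <- ranking$marker[ranking$retained]

  if (length(retained) > 0) {
    post_seed <- if (is.null(seed)) NULL else derive_seed(seed, "post", variable, level)
    fit_post <- kmeans_fit(Xs[, retained, drop = FALSE], 2, seed = post_seed,
                           restarts = restarts)
    sil_post <- silhouette_score(Xs[, retained, drop = FALSE], fit_post$assignments)$global
    conf_post <- align_clusters(fit_post$assignments, truth)
  } else {
    sil_post <- NA_real_
    conf_post <- NULL
  }

  structure(
    list(variable = variable, level = as.character(level), n_records = nrow(sub),
         silhouette_pre = sil_pre, silhouette_post = sil_post,
         ranking = ranking, retained = retained,
         confusion_pre = conf_pre, confusion_post = conf_post,
         no_features = length(retained) == 0, seed = seed),
    class = "mps_profile"
  )
}

#' @export
print.mps_profile <- function(x, ...) {
  cat(sprintf("condition profile %s = %s (%d records)\n", x$variable, x$level, x$n_records))
  cat(sprintf("  silhouette pre = %.3f, post = %s; retained %d marker(s)\n",
              x$silhouette_pre,
              if (is.na(x$silhouette_post)) "NA" else sprintf("%.3f", x$silhouette_post),
              length(x$retained)))
  if (x$no_features) cat("  [no marker passed the threshold]\n")
  invisible(x)
}

#' Profile all 12 microenvironment condition levels
#'
#' Applies [profile_condition()] to every level of [condition_levels()] in the
#' fixed order pH, perfusion, hydrogel, gelatin, alginate, with an independent
#' child seed per level derived from the master seed. A failure at any level is
#' re-raised naming the level.
#'
#' @inheritParams profile_condition
#' @return An object of class `mps_profile_set`: list of 12 `mps_profile`s.
#' @export
#' @examples
#' tbl <- normalize_proliferation(generate_markers(synthetic_config(seed = 3)))
#' profiles <- profile_all_conditions(tbl, seed = 3)
profile_all_conditions <- function(table, tau = 0.65, seed = NULL,
                                   estimator = "knn", restarts = 20,
                                   log_intensities = TRUE) {
  levels <- condition_levels()
  profiles <- purrr::pmap(levels, function(variable, level) {
    tryCatch(
      profile_condition(table, variable, level, tau = tau,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, "level", variable, level),
                        estimator = estimator, restarts = restarts,
                        log_intensities = log_intensities),
      error = function(e) {
        abort(sprintf("Profiling failed at level %s = %s: %s",
                      variable, level, conditionMessage(e)))
      })
  })
  structure(profiles, class = "mps_profile_set")
}

#' @export
print.mps_profile_set <- function(x, ...) {
  cat(sprintf("condition profile set: %d levels\n", length(x)))
  for (p in x) {
    cat(sprintf("  %-9s %-7s n=%2d retained=%2d post-errors=%s\n",
                p$variable, p$level, p$n_records, length(p$retained),
                if (is.null(p$confusion_post)) "NA"
                else p$confusion_post$fp + p$confusion_post$fn))
  }
  invisible(x)
}

#' Aggregate marker importance across condition levels
#'
#' Combines the per-level mutual-information scores into a cross-condition
#' importance table: for each marker, the sum of its MI scores over all
#' profiled levels (the combined feature score), the mean score, and the
#' number of levels where the marker passed the retention threshold. Markers
#' are ordered by descending combined score with ties broken by panel order;
#' the ordering is invariant to the order of the input profiles.
#'
#' @param profiles An `mps_profile_set` (or list of `mps_profile`s).
#' @return An object of class `mps_importance`: tibble with columns `marker`,
#'   `combined_score`, `mean_score`, `times_retained`, `rank`.
#' @export
aggregate_importance <- function(profiles) {
  if (length(profiles) == 0) abort("Need at least one profile.")
  panel <- marker_names()
  scores <- purrr::map(profiles, function(p) {
    unname(stats::setNames(p$ranking$score, p$ranking$marker)[panel])
  })
  retained <- purrr::map(profiles, function(p) panel %in% p$retained)
  out <- tibble(
    marker = panel,
    combined_score = Reduce(`+`, scores),
    mean_score = Reduce(`+`, scores) / length(profiles),
    times_retained = Reduce(`+`, lapply(retained, as.integer))
  ) |>
    dplyr::arrange(dplyr::desc(.data$combined_score), match(.data$marker, panel)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("mps_importance", class(out))
  out
}

#' Detect environment-driven behavioural regimes within one cell line
#'
#' Restricts the table to a single cell line across all environments, selects
#' the number of clusters by the least-drop silhouette rule, prunes markers by
#' greedy silhouette-guided backward elimination at the chosen k, and returns
#' the final clustering with assignments joined back onto the environment
#' metadata. When even the best silhouette is below 0.25 the result is flagged
#' low-confidence (no convincing intraphenotype structure).
#'
#' @param table A marker table.
#' @param cell_line `"invasive"` or `"noninvasive"`.
#' @param k_max,epsilon Passed to [select_num_clusters()].
#' @param seed Master seed.
#' @param eliminate Run backward feature elimination at the selected k
#'   (default `TRUE`).
#' @param restarts k-means restarts.
#' @return List with `k`, `scores`, `low_confidence`, `retained`,
#'   `elimination_trace`, `fit` (`mps_kmeans` on the retained markers), and
#'   `assignments` (tibble of env metadata, replicate, cluster).
#' @export
intraphenotype_behaviors <- function(table, cell_line, k_max = 6, epsilon = 0.01,
                                     seed = NULL, eliminate = TRUE, restarts = 20,
                                     log_intensities = TRUE) {
  validate_marker_table(table, check_ranges = FALSE)
  sub <- dplyr::filter(table, .data$cell_line == !!cell_line)
  if (nrow(sub) <= k_max) {
    abort(sprintf("Need more than k_max = %d records of cell line '%s'.", k_max, cell_line))
  }
  X <- marker_feature_matrix(sub, log_intensities = log_intensities)
  sel <- select_num_clusters(X, k_max = k_max, epsilon = epsilon,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, "select", cell_line),
                             restarts = restarts, standardize = FALSE)
  if (eliminate) {
    elim <- backward_eliminate(X, sel$k,
                               seed = if (is.null(seed)) NULL else derive_seed(seed, "elim", cell_line),
                               epsilon = epsilon, restarts = restarts,
                               standardize = FALSE)
    retained <- elim$retained
    trace <- elim$trace
  } else {
    retained <- marker_names()
    trace <- NULL
  }
  fit <- kmeans_fit(X[, retained, drop = FALSE], sel$k,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, "final", cell_line),
                    restarts = restarts)
  assignments <- sub |>
    dplyr::select("env_id", "replicate") |>
    dplyr::left_join(mps_condition_grid(), by = "env_id") |>
    dplyr::mutate(cluster = fit$assignments)
  list(cell_line = cell_line, k = sel$k, scores = sel$scores,
       low_confidence = sel$low_confidence, retained = retained,
       elimination_trace = trace, fit = fit, assignments = assignments)
}
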