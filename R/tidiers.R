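#' Tidy a k-means fit
#'
#' @param x An `mps_kmeans` object.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `size`, and one column per feature
#'   holding the centroid coordinate.
#' @method tidy mps_kmeans
#' @export
tidy.mps_kmeans <- function(x, ...) {
  centers <- as_tibble(as.data.frame(x$centers))
  dplyr::bind_cols(
    tibble(cluster = seq_len(nrow(x$centers)),
           size = tabulate(x$assignments, nrow(x$centers))),
    centers
  )
}

#' @rdname tidy.mps_kmeans
#' @return `glance()`: a one-row tibble with `n`, `k`, `sse`, `n_iter`,
#'   `restarts`.
#' @method glance mps_kmeans
#' @export
glance.mps_kmeans <- function(x, ...) {
  tibble(n = length(x$assignments), k = nrow(x$centers), sse = x$sse,
         n_iter = x$n_iter, restarts = x$restarts)
}

#' Tidy a silhouette report
#'
#' @param x An `mps_silhouette` object.
#' @param ... Unused.
#' @return One row per record with `record`, `cluster` (via names of
#'   `per_cluster`), and `silhouette`.
#' @method tidy mps_silhouette
#' @export
tidy.mps_silhouette <- function(x, ...) {
  tibble(record = seq_along(x$per_sample), silhouette = x$per_sample)
}

#' @rdname tidy.mps_silhouette
#' @method glance mps_silhouette
#' @export
glance.mps_silhouette <- function(x, ...) {
  tibble(global = x$global, n = length(x$per_sample),
         n_clusters = length(x$per_cluster))
}

#' Tidy a correlation matrix into long format
#'
#' @param x An `mps_cor` object.
#' @param ... Unused.
#' @return A tibble with `row`, `column`, `correlation` (NA for undefined
#'   pairs) and `cell_line`.
#' @method tidy mps_cor
#' @export
tidy.mps_cor <- function(x, ...) {
  m <- unclass(x)
  attr(m, "cell_line") <- NULL
  attr(m, "undefined") <- NULL
  as_tibble(as.data.frame(m), rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "column", values_to = "correlation") |>
    dplyr::mutate(cell_line = attr(x, "cell_line"))
}

#' Tidy a feature ranking
#'
#' @param x An `mps_ranking` object.
#' @param ... Unused.
#' @return The underlying tibble (`marker`, `score`, `rank`, `retained`) with
#'   `tau` attached as a column.
#' @method tidy mps_ranking
#' @export
tidy.mps_ranking <- function(x, ...) {
  dplyr::mutate(as_tibble(x), tau = attr(x, "tau"))
}

#' Tidy a condition profile set
#'
#' @param x An `mps_profile_set` object (or single `mps_profile`).
#' @param ... Unused.
#' @return One row per level: silhouettes, retained count, confusion entries
#'   pre/post, and the `no_features` flag.
#' @method tidy mps_profile_set
#' @export
tidy.mps_profile_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), function(p) glance(p))
}

#' @rdname tidy.mps_profile_set
#' @param x An `mps_profile` object.
#' @method glance mps_profile
#' @export
glance.mps_profile <- function(x, ...) {
  conf <- function(cm, which) {
    if (is.null(cm)) {
      tibble("{which}_errors" := NA_integer_, "{which}_accuracy" := NA_real_)
    } else {
      tibble("{which}_errors" := cm$fp + cm$fn, "{which}_accuracy" := cm$accuracy)
    }
  }
  dplyr::bind_cols(
    tibble(variable = x$variable, level = x$level, n_records = x$n_records,
           silhouette_pre = x$silhouette_pre, silhouette_post = x$silhouette_post,
           n_retained = length(x$retained), no_features = x$no_features),
    conf(x$confusion_pre, "pre"), conf(x$confusion_post, "post")
  )
}

#' @importFrom rlang :=
NULL
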