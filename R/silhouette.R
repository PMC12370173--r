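#' Silhouette index of a clustering
#'
#' For each record, cohesion `a_i` is the mean Euclidean distance to the other
#' members of its cluster and separation `b_i` is the smallest mean distance to
#' the members of any other cluster; its silhouette value is
#' `s_i = (b_i - a_i) / max(a_i, b_i)`, with the convention `s_i = 0` for
#' members of singleton clusters. The headline (global) index is the mean of
#' `s_i` over all records and always lies in \[-1, 1\]; per-cluster means are
#' reported alongside.
#'
#' @param X Numeric matrix (records x features).
#' @param assignments Integer cluster labels of length `nrow(X)`; at least two
#'   distinct clusters must be present.
#' @return An object of class `mps_silhouette`: list with `per_sample`,
#'   `per_cluster` (named mean per cluster), and `global`.
#' @export
#' @examples
#' X <- matrix(c(0, 1, 5), ncol = 1)
#' silhouette_score(X, c(1, 1, 2))$global  # 31/60
silhouette_score <- function(X, assignments) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (length(assignments) != N) abort("`assignments` must have one label per record.")
  if (N < 2) abort("Silhouette requires at least 2 records.")
  clusters <- sort(unique(assignments))
  if (length(clusters) < 2) abort("Silhouette is undefined for a single cluster.")

  D <- as.matrix(stats::dist(X))
  sizes <- vapply(clusters, function(g) sum(assignments == g), integer(1))
  # mean distance from each record to each cluster (including its own)
  sums <- vapply(clusters, function(g)
    rowSums(D[, assignments == g, drop = FALSE]), numeric(N))
  s <- numeric(N)
  for (i in seq_len(N)) {
    gi <- match(assignments[i], clusters)
    if (sizes[gi] == 1) {
      s[i] <- 0
      next
    }
    a <- sums[i, gi] / (sizes[gi] - 1)
    b <- min(sums[i, -gi] / sizes[-gi])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  per_cluster <- vapply(clusters, function(g) mean(s[assignments == g]), numeric(1))
  structure(
    list(per_sample = s,
         per_cluster = stats::setNames(per_cluster, clusters),
         global = mean(s)),
    class = "mps_silhouette"
  )
}

#' @export
print.mps_silhouette <- function(x, ...) {
  cat(sprintf("silhouette: global = %.4f over %d records, %d clusters\n",
              x$global, length(x$per_sample), length(x$per_cluster)))
  invisible(x)
}
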