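#' From-scratch k-means clustering
#'
#' Lloyd-style k-means implementing the exact conventions the pipeline relies
#' on: records are assigned to the cluster whose current centroid is nearest in
#' Euclidean distance, with equidistant (ambiguous) points assigned to the
#' lowest cluster index; centroids are then recomputed as cluster means; the
#' loop stops when assignments are identical on two consecutive iterations (or
#' `max_iter` is hit). A cluster left empty after an assignment step is
#' re-seeded at the point currently farthest from its own centroid, so the
#' returned result never has empty clusters. Centroids are initialized by a
#' distance-weighted ("++"-style) draw from the data points; among `restarts`
#' independent initializations the run with the smallest within-cluster sum of
#' squared distances (SSE) wins.
#'
#' @param X Numeric matrix (records x features), all values finite.
#' @param G Number of clusters, `1 <= G <= nrow(X)`.
#' @param seed Integer seed for the initialization draws (`NULL` = current
#'   RNG stream).
#' @param restarts Number of independent initializations (default 20).
#' @param max_iter Safety bound on iterations per restart (default 300).
#' @return An object of class `mps_kmeans`: list with `assignments` (integer
#'   vector in `1..G`), `centers` (G x n matrix), `n_iter`, `sse`, `sse_trace`
#'   (per-iteration SSE of the winning restart, non-increasing), `seed`,
#'   `restarts`.
#' @export
#' @examples
#' X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
#' kmeans_fit(X, 2, seed = 1)
kmeans_fit <- function(X, G, seed = NULL, restarts = 20, max_iter = 300) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  N <- nrow(X)
  if (!all(is.finite(X))) abort("`X` must be finite.")
  assert_number(G, "G", min = 1)
  if (G > N) abort(sprintf("G = %d exceeds the number of records (%d).", G, N))
  G <- as.integer(G)

  best <- NULL
  for (r in seq_len(restarts)) {
    init_seed <- if (is.null(seed)) NULL else derive_seed(seed, "init", r)
    centers <- with_seed_if(init_seed, init_plusplus(X, G))
    res <- lloyd_iterate(X, centers, max_iter)
    if (is.null(best) || res$sse < best$sse - 1e-12) best <- res
  }
  structure(
    list(assignments = best$assignments, centers = best$centers,
         n_iter = best$n_iter, sse = best$sse, sse_trace = best$sse_trace,
         seed = seed, restarts = restarts),
    class = "mps_kmeans"
  )
}

# distance-weighted ("++"-style) choice of G initial centers among data points
init_plusplus <- function(X, G) {
  N <- nrow(X)
  idx <- sample.int(N, 1)
  for (g in seq_len(G - 1)) {
    d2 <- apply(rowwise_sqdist(X, X[idx, , drop = FALSE]), 1, min)
    if (sum(d2) <= 0) {
      remaining <- setdiff(seq_len(N), idx)
      idx <- c(idx, remaining[sample.int(length(remaining), 1)])
    } else {
      idx <- c(idx, sample.int(N, 1, prob = d2 / sum(d2)))
    }
  }
  X[idx, , drop = FALSE]
}

lloyd_iterate <- function(X, centers, max_iter) {
  N <- nrow(X)
  G <- nrow(centers)
  assign_prev <- rep(NA_integer_, N)
  sse_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- rowwise_sqdist(X, centers)
    # ties go to the lowest cluster index
    assignments <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters at the point farthest from its current centroid;
    # the reseeded point is pinned to the cluster so it cannot stay empty
    guard <- 0L
    forced <- FALSE
    repeat {
      empty <- which(tabulate(assignments, G) == 0)
      if (length(empty) == 0) break
      guard <- guard + 1L
      if (guard > 2L * G + 5L) {
        # degenerate data (e.g. coincident points): split the largest cluster
        for (g in empty) {
          donor <- which.max(tabulate(assignments, G))
          assignments[which(assignments == donor)[1]] <- g
        }
        centers <- update_centroids(X, assignments, G)
        d2 <- rowwise_sqdist(X, centers)
        forced <- TRUE
        break
      }
      g <- empty[1]
      far <- which.max(d2[cbind(seq_len(N), assignments)])
      centers[g, ] <- X[far, ]
      d2 <- rowwise_sqdist(X, centers)
      assignments <- max.col(-d2, ties.method = "first")
      assignments[far] <- g
    }
    sse <- sum(d2[cbind(seq_len(N), assignments)])
    if (!forced && length(sse_trace) > 0 && sse > utils::tail(sse_trace, 1) + 1e-8) {
      abort("internal error: k-means SSE increased between iterations.")
    }
    sse_trace <- c(sse_trace, sse)
    if (identical(assignments, assign_prev) || iter >= max_iter) break
    assign_prev <- assignments
    centers <- update_centroids(X, assignments, G)
  }
  # final SSE against the returned centroids (cluster means)
  centers <- update_centroids(X, assignments, G)
  sse <- sum(rowwise_sqdist(X, centers)[cbind(seq_len(N), assignments)])
  list(assignments = assignments, centers = centers, n_iter = iter,
       sse = sse, sse_trace = c(sse_trace, sse))
}

update_centroids <- function(X, assignments, G) {
  centers <- matrix(NA_real_, nrow = G, ncol = ncol(X),
                    dimnames = list(NULL, colnames(X)))
  for (g in seq_len(G)) {
    centers[g, ] <- colMeans(X[assignments == g, , drop = FALSE])
  }
  centers
}

#' @export
print.mps_kmeans <- function(x, ...) {
  cat(sprintf("k-means fit: %d clusters, %d records, SSE = %.6g, %d iteration(s)\n",
              nrow(x$centers), length(x$assignments), x$sse, x$n_iter))
  cat("cluster sizes:", paste(tabulate(x$assignments, nrow(x$centers)), collapse = ", "), "\n")
  invisible(x)
}
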