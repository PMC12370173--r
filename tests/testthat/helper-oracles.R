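# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exhaustive minimum SSE over all nonempty bipartitions of the rows of X
exhaustive_bipartition_sse <- function(X) {
  X <- as.matrix(X)
  N <- nrow(X)
  stopifnot(N <= 12)
  sse_of <- function(rows) {
    if (length(rows) == 0) return(0)
    sub <- X[rows, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  best <- Inf
  for (mask in 1:(2^N - 2)) {
    g1 <- which(bitwAnd(mask, 2^(0:(N - 1))) > 0)
    best <- min(best, sse_of(g1) + sse_of(setdiff(1:N, g1)))
  }
  best
}

# single-pass (streaming) Pearson correlation via running sums
streaming_pearson <- function(a, b) {
  n <- 0; sa <- 0; sb <- 0; saa <- 0; sbb <- 0; sab <- 0
  for (i in seq_along(a)) {
    n <- n + 1
    sa <- sa + a[i]; sb <- sb + b[i]
    saa <- saa + a[i]^2; sbb <- sbb + b[i]^2; sab <- sab + a[i] * b[i]
  }
  (n * sab - sa * sb) / sqrt((n * saa - sa^2) * (n * sbb - sb^2))
}

# analytic mutual information (nats) between a balanced binary label and a
# feature drawn from N(0,1) / N(delta,1), by numerical integration
gaussian_mixture_mi <- function(delta) {
  integrand <- function(x) {
    d0 <- 0.5 * dnorm(x)
    d1 <- 0.5 * dnorm(x, mean = delta)
    p <- d0 / (d0 + d1)
    h <- -(p * log(p) + (1 - p) * log(1 - p))
    h[!is.finite(h)] <- 0
    (d0 + d1) * h
  }
  log(2) - stats::integrate(integrand, -12, 12 + delta, rel.tol = 1e-10)$value
}

# well-separated planted blobs in 2 dimensions
make_blobs <- function(n_per, centers, sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g)
      cbind(rnorm(n_per, centers[g, 1], sd), rnorm(n_per, centers[g, 2], sd))))
    list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# minimal valid marker table built by hand (not via the generator)
tiny_marker_table <- function(n_rep = 1, seed = 42) {
  design <- expand.grid(cell_line = c("invasive", "noninvasive"),
                        env_id = 1:12, replicate = seq_len(n_rep),
                        stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    info <- marker_info()
    for (j in seq_len(nrow(info))) {
      design[[info$marker[j]]] <- if (info$type[j] == "pct") {
        runif(nrow(design), 5, 95)
      } else {
        exp(rnorm(nrow(design), log(100), 0.5))
      }
    }
  })
  tibble::as_tibble(design)
}
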