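#' Derive a reproducible child seed from a master seed
#'
#' Stage and level seeds are derived as a stable string hash of the master seed
#' together with an arbitrary set of labels, so that adding a new stage to a run
#' never perturbs the random streams of existing stages.
#'
#' @param seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the stage, condition
#'   level, replicate, etc.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "profile", "pH", 6.5)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(c(format(seed, scientific = FALSE), vapply(list(...), function(x)
    paste(format(x, scientific = FALSE), collapse = ","), character(1))),
    collapse = "|")
  mod <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.integer(seed)) %% mod
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% mod
  }
  as.integer(h %% (mod - 1L) + 1L)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
# A NULL seed runs the code against the current stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Column z-score standardization; zero-variance columns are mapped to 0 rather
# than NaN so constant markers (e.g. normalized day-1 proliferation) stay inert
# in distance computations.
standardize_columns <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu, "-")
  keep <- s > 0
  Xs[, keep] <- sweep(Xs[, keep, drop = FALSE], 2, s[keep], "/")
  Xs[, !keep] <- 0
  Xs
}

# squared Euclidean distances between rows of X (N x n) and rows of C (G x n)
rowwise_sqdist <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

assert_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name, format(min)))
  }
  invisible(x)
}
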