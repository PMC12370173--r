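test_that("a perfectly separating balanced feature approaches the label entropy", {
  withr::with_seed(21, {
    x <- c(rnorm(36, 0, 0.3), rnorm(36, 50, 0.3))
    y <- rep(c(0, 1), each = 36)
  })
  for (est in c("knn", "binned")) {
    mi <- mutual_information(x, y, estimator = est, seed = 1)
    expect_equal(as.numeric(mi), log(2), tolerance = 0.1)
  }
})

test_that("an independent feature scores near zero", {
  low <- 0
  for (s in 1:40) {
    withr::with_seed(s, {
      x <- rnorm(72)
      y <- rep(c(0, 1), each = 36)
    })
    low <- low + (as.numeric(mutual_information(x, y, seed = s)) < 0.1)
  }
  expect_gte(low / 40, 0.95)
})

test_that("knn and binned estimators agree with the integration oracle", {
  truth <- gaussian_mixture_mi(4)
  knn <- numeric(10); binned <- numeric(10)
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      x <- c(rnorm(100, 0), rnorm(100, 4))
      y <- rep(c(0, 1), each = 100)
    })
    knn[s] <- mutual_information(x, y, "knn", seed = s)
    binned[s] <- mutual_information(x, y, "binned")
  }
  expect_lt(abs(mean(knn) - truth), 0.15)
  expect_lt(abs(mean(binned) - truth), 0.15)
  expect_lt(mean(abs(knn - binned)), 0.15)
})

test_that("the knn estimate is invariant under monotone transforms", {
  withr::with_seed(31, {
    x <- c(rlnorm(30, 0, 1), rlnorm(30, 2, 1))
    y <- rep(c(0, 1), each = 30)
  })
  a <- as.numeric(mutual_information(x, y, seed = 4))
  b <- as.numeric(mutual_information(log(x + 1), y, seed = 4))
  expect_equal(a, b, tolerance = 0.05)
})

test_that("degenerate inputs behave as documented", {
  y <- rep(c(0, 1), each = 10)
  expect_equal(as.numeric(mutual_information(rep(3, 20), y)), 0)
  expect_error(mutual_information(rnorm(20), rep(1, 20)), "Both label classes")
  expect_error(mutual_information(rnorm(5), c(0, 1, 0, 1)), "equal length")
  # negative raw estimates clip to zero and record the clip
  mi <- mutual_information(rnorm(40), rep(c(0, 1), 20), seed = 2)
  expect_gte(as.numeric(mi), 0)
})

test_that("ranking orders, thresholds strictly, and flags empty retention", {
  withr::with_seed(41, {
    n <- 60
    y <- rep(c("invasive", "noninvasive"), each = n / 2)
    X <- cbind(strong = ifelse(y == "invasive", 10, 0) + rnorm(n, 0, 0.2),
               weak = ifelse(y == "invasive", 1, 0) + rnorm(n),
               none = rnorm(n))
  })
  r <- rank_features(X, y, tau = 0.65, seed = 3)
  expect_equal(r$marker, c("strong", "weak", "none"))
  expect_equal(r$retained, c(TRUE, FALSE, FALSE))
  expect_false(attr(r, "no_features"))

  # strict threshold: retention requires score strictly above tau
  r_at <- rank_features(X, y, tau = max(r$score), seed = 3)
  expect_false(any(r_at$retained))

  # all-constant columns: zero scores, empty retained set, flag raised
  Xc <- matrix(5, nrow = 20, ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  rc <- rank_features(Xc, rep(c(0, 1), 10), seed = 1)
  expect_equal(rc$score, c(0, 0, 0))
  expect_true(attr(rc, "no_features"))
  # ties broken by column index
  expect_equal(rc$marker, c("a", "b", "c"))
})

test_that("adding noise columns never changes existing scores", {
  withr::with_seed(51, {
    y <- rep(c(0, 1), each = 25)
    X1 <- cbind(f1 = y * 3 + rnorm(50), f2 = rnorm(50))
    X2 <- cbind(X1, junk = rnorm(50))
  })
  r1 <- rank_features(X1, y, seed = 9)
  r2 <- rank_features(X2, y, seed = 9)
  expect_equal(r1$score[r1$marker == "f1"], r2$score[r2$marker == "f1"])
  expect_equal(r1$score[r1$marker == "f2"], r2$score[r2$marker == "f2"])
})

test_that("balanced two-class scores respect the entropy ceiling", {
  tbl <- generate_markers(synthetic_config(seed = 13))
  r <- rank_features(as.matrix(tbl[marker_names()]), tbl$cell_line, seed = 13)
  expect_true(all(r$score <= 0.75))
})
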