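default_table <- function(seed) {
  normalize_proliferation(generate_markers(synthetic_config(seed = seed)))
}

test_that("a profiled acidic-pH level recovers the phenotypes without error", {
  tbl <- default_table(3)
  p <- profile_condition(tbl, "pH", "6.5", seed = 3)
  expect_s3_class(p, "mps_profile")
  expect_equal(p$n_records, 24)
  expect_false(p$no_features)
  expect_equal(p$confusion_post$fp, 0)
  expect_equal(p$confusion_post$fn, 0)
  # retained markers are a subset of the planted discriminative set
  truth <- planted_truth(synthetic_config(), "pH", "6.5")
  expect_true(all(p$retained %in% truth))
})

test_that("profiling guards degenerate subsets", {
  tbl <- default_table(1)
  only_inv <- dplyr::filter(tbl, cell_line == "invasive")
  expect_error(profile_condition(only_inv, "pH", "6.5", seed = 1), "each cell line")
  expect_error(profile_condition(tbl, "pH", "9.9", seed = 1), "level")
})

test_that("a null design yields an empty retained set with the flag raised", {
  cfg <- synthetic_config(seed = 8, effect_scale = 0)
  tbl <- normalize_proliferation(generate_markers(cfg))
  p <- profile_condition(tbl, "pH", "6.5", seed = 8)
  expect_true(p$no_features)
  expect_length(p$retained, 0)
  expect_true(is.na(p$silhouette_post))
  expect_null(p$confusion_post)
})

test_that("all 12 condition levels produce profiles in the fixed order", {
  tbl <- default_table(4)
  ps <- profile_all_conditions(tbl, seed = 4)
  expect_length(ps, 12)
  td <- tidy(ps)
  expect_equal(td$variable, condition_levels()$variable)
  expect_equal(td$level, condition_levels()$level)
  expect_equal(td$n_records,
               c(48, 24, 48, 24, 18, 18, 18, 18, 36, 36, 36, 36))
  expect_error(profile_all_conditions(tbl[0, ], seed = 1), "pH")
})

test_that("feature reduction improves silhouette and confusion on planted data", {
  improved_sil <- 0; improved_conf <- 0; n <- 0
  for (s in 1:5) {
    ps <- profile_all_conditions(default_table(s), seed = s)
    for (p in ps) {
      if (p$no_features) next
      n <- n + 1
      improved_sil <- improved_sil + (p$silhouette_post >= p$silhouette_pre)
      improved_conf <- improved_conf +
        (p$confusion_post$fp + p$confusion_post$fn <=
           p$confusion_pre$fp + p$confusion_pre$fn)
    }
  }
  expect_gte(improved_sil / n, 0.9)
  expect_gte(improved_conf / n, 0.9)
})

test_that("acidic pH retains a superset of the neutral-static high tier", {
  # the moderate tier is planted to be active only under stress conditions
  supersets <- 0
  for (s in 1:8) {
    tbl <- default_table(s)
    p65 <- profile_condition(tbl, "pH", "6.5", seed = derive_seed(s, "a"))
    p74 <- profile_condition(tbl, "pH", "7.4", seed = derive_seed(s, "b"))
    truth65 <- planted_truth(synthetic_config(), "pH", "6.5")
    truth74 <- planted_truth(synthetic_config(), "pH", "7.4")
    supersets <- supersets + (length(truth74) < length(truth65) &&
                                all(p74$retained %in% truth74) &&
                                all(p65$retained %in% truth65))
  }
  expect_gte(supersets / 8, 0.75)
})

test_that("aggregation sums scores, counts retention, and is order-invariant", {
  tbl <- default_table(6)
  ps <- profile_all_conditions(tbl, seed = 6)
  agg <- aggregate_importance(ps)
  expect_equal(nrow(agg), 16)
  expect_true(all(agg$combined_score >= 0))
  expect_true(all(agg$times_retained <= 12))
  expect_equal(agg$combined_score, sort(agg$combined_score, decreasing = TRUE))

  # manual check of one marker's combined score
  m <- agg$marker[1]
  manual <- sum(vapply(ps, function(p) p$ranking$score[p$ranking$marker == m],
                       numeric(1)))
  expect_equal(agg$combined_score[1], manual)

  perm <- withr::with_seed(1, sample(12))
  agg2 <- aggregate_importance(unclass(ps)[perm])
  expect_equal(as.data.frame(agg), as.data.frame(agg2))

  # single profile: aggregate order equals that profile's own order
  one <- aggregate_importance(ps[1])
  expect_equal(one$marker, ps[[1]]$ranking$marker)
})

test_that("dominant markers rank first in the aggregate", {
  fake_profile <- function(scores, retained) {
    structure(list(variable = "pH", level = "6.5",
                   ranking = tibble::tibble(marker = marker_names(),
                                            score = scores,
                                            rank = seq_len(16),
                                            retained = marker_names() %in% retained),
                   retained = retained),
              class = "mps_profile")
  }
  hi <- rep(0.1, 16); hi[marker_names() == "cd44_mfi"] <- 0.9
  profiles <- list(fake_profile(hi, "cd44_mfi"), fake_profile(hi, "cd44_mfi"))
  agg <- aggregate_importance(profiles)
  expect_equal(agg$marker[1], "cd44_mfi")
  expect_equal(agg$times_retained[agg$marker == "cd44_mfi"], 2)
})

test_that("intraphenotype analysis finds the two planted environment regimes", {
  tbl <- default_table(2)
  for (cl in c("invasive", "noninvasive")) {
    res <- intraphenotype_behaviors(tbl, cl, seed = 2, eliminate = FALSE)
    expect_equal(res$k, 2)
    # cluster split tracks the stress/baseline environment regime
    stress <- res$assignments$ph < 7 | res$assignments$perfusion == "dynamic"
    split <- table(stress, res$assignments$cluster)
    expect_gte(sum(apply(split, 2, max)) / nrow(res$assignments), 0.9)
  }
})

test_that("a single-regime design is flagged low-confidence at minimal k", {
  cfg <- synthetic_config(seed = 5, env_response = matrix(0, 16, 12))
  tbl <- normalize_proliferation(generate_markers(cfg))
  res <- intraphenotype_behaviors(tbl, "noninvasive", seed = 5, eliminate = FALSE)
  expect_equal(res$k, 2) # minimal-k rule on flat scores
  expect_true(res$low_confidence)
})

test_that("intraphenotype elimination keeps regime-informative markers", {
  tbl <- default_table(7)
  res <- intraphenotype_behaviors(tbl, "noninvasive", seed = 7, eliminate = TRUE)
  expect_true(all(diff(res$elimination_trace$silhouette) > 0))
  expect_true(length(res$retained) >= 1)
  expect_equal(sort(unique(res$assignments$cluster)), seq_len(res$k))
})
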