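test_that("generator reproduces the study design deterministically", {
  cfg <- synthetic_config(seed = 11)
  tbl <- generate_markers(cfg)
  expect_equal(nrow(tbl), 72) # 2 lines x 12 environments x 3 replicates
  expect_equal(length(unique(tbl$env_id)), 12)
  expect_equal(sort(unique(tbl$cell_line)), c("invasive", "noninvasive"))
  expect_identical(as.data.frame(tbl), as.data.frame(generate_markers(cfg)))

  # different seed, different values
  other <- generate_markers(synthetic_config(seed = 12))
  expect_false(isTRUE(all.equal(tbl$cd44_mfi, other$cd44_mfi)))
})

test_that("observation-scale invariants hold for every marker type", {
  tbl <- generate_markers(synthetic_config(seed = 5, replicates = 5))
  info <- marker_info()
  for (j in seq_len(nrow(info))) {
    v <- tbl[[info$marker[j]]]
    if (info$type[j] == "pct") {
      expect_true(all(v >= 0 & v <= 100), label = info$marker[j])
    } else {
      expect_true(all(v > 0), label = info$marker[j])
    }
  }
})

test_that("adding replicates extends the table without reshuffling", {
  t3 <- generate_markers(synthetic_config(seed = 9, replicates = 3))
  t5 <- generate_markers(synthetic_config(seed = 9, replicates = 5))
  key <- function(d) d[d$replicate <= 3, ]
  expect_equal(as.data.frame(key(t5)), as.data.frame(t3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("null configuration produces no cell-line differences (t-test oracle)", {
  # all effects off: per-marker two-sample t between lines should look null
  n_sig <- 0; n_tot <- 0
  for (s in 1:25) {
    cfg <- synthetic_config(seed = s, effect_scale = 0,
                            env_response = matrix(0, 16, 12))
    tbl <- generate_markers(cfg)
    inv <- tbl$cell_line == "invasive"
    for (m in marker_names()) {
      p <- stats::t.test(tbl[[m]][inv], tbl[[m]][!inv])$p.value
      n_tot <- n_tot + 1
      n_sig <- n_sig + (p < 0.01)
    }
  }
  expect_lt(n_sig / n_tot, 0.05)
})

test_that("planted truth reflects tier activity per condition level", {
  cfg <- synthetic_config()
  info <- marker_info()
  high <- info$marker[info$tier == "high"]
  moderate <- info$marker[info$tier == "moderate"]

  expect_setequal(planted_truth(cfg, "pH", "6.5"), c(high, moderate))
  expect_setequal(planted_truth(cfg, "perfusion", "dynamic"), c(high, moderate))
  # pH 7.4 mixes static and dynamic environments: only the high tier is
  # uniformly discriminative there
  expect_setequal(planted_truth(cfg, "pH", "7.4"), high)
  expect_setequal(planted_truth(cfg, "hydrogel", "So-L"), high)

  null_cfg <- synthetic_config(effect_scale = 0)
  expect_length(planted_truth(null_cfg, "pH", "6.5"), 0)
  expect_error(planted_truth(cfg, "pH", "5"), "level")
})

test_that("config validation rejects malformed tier maps", {
  bad_map <- stats::setNames(rep("high", 15), marker_names()[1:15])
  expect_error(synthetic_config(tier_map = bad_map), "16 markers")
  bad_map <- stats::setNames(rep("huge", 16), marker_names())
  expect_error(synthetic_config(tier_map = bad_map), "high")
  expect_error(synthetic_config(effect_size = list(high = -1, moderate = 1, low = 0)),
               "non-negative")
  expect_error(synthetic_config(env_response = matrix(0, 3, 3)), "16 x 12")
})

test_that("larger planted effects raise downstream MI scores (monotonicity)", {
  # monotone in expectation over seeds: compare a high-tier marker's MI at
  # effect scales 0, 0.5 and 1 averaged over seeds
  mean_mi <- function(scale) {
    mean(vapply(1:8, function(s) {
      tbl <- generate_markers(synthetic_config(seed = s, effect_scale = scale))
      as.numeric(mutual_information(tbl$vimentin_mfi,
                                    tbl$cell_line == "invasive", seed = s))
    }, numeric(1)))
  }
  m0 <- mean_mi(0); m05 <- mean_mi(0.5); m1 <- mean_mi(1)
  expect_lt(m0, m05)
  expect_lt(m05, m1)
})
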