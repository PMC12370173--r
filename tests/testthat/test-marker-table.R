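test_that("marker schema enumerates the 16-readout panel", {
  info <- marker_info()
  expect_equal(nrow(info), 16)
  expect_equal(sum(info$type == "prolif"), 4)
  expect_equal(sum(info$type == "mfi"), 5)
  expect_equal(sum(info$type == "pct"), 7)
  expect_setequal(unique(info$tier), c("high", "moderate", "low"))
  expect_equal(marker_names(), info$marker)
})

test_that("CSV write/read round trip preserves every value", {
  tbl <- tiny_marker_table(n_rep = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_table(tbl, path)
  back <- read_marker_table(path)
  expect_equal(nrow(back), 72)
  expect_equal(as.data.frame(back[marker_names()]),
               as.data.frame(tbl[marker_names()]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$cell_line, tbl$cell_line)
  expect_equal(back$env_id, tbl$env_id)
})

test_that("schema violations are reported by name and location", {
  tbl <- tiny_marker_table()
  path <- withr::local_tempfile(fileext = ".csv")

  write_marker_table(dplyr::select(tbl, -"vimentin_pos_pct"), path,
                     schema_check = FALSE)
  expect_error(read_marker_table(path), "vimentin_pos_pct")

  tbl_bad <- tbl
  tbl_bad$cd44_mfi <- as.character(tbl_bad$cd44_mfi)
  tbl_bad$cd44_mfi[3] <- "not-a-number"
  readr::write_csv(tbl_bad, path)
  expect_error(read_marker_table(path), "cd44_mfi.*row 3|row 3.*cd44_mfi")

  tbl_bad <- tbl
  tbl_bad$env_id[1] <- 99L
  readr::write_csv(tbl_bad, path)
  expect_error(read_marker_table(path), "env_id")
})

test_that("rows with missing marker values are rejected with a diagnostic", {
  tbl <- tiny_marker_table()
  tbl$aldh_pos_pct[c(2, 5)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  expect_warning(back <- read_marker_table(path), "2, 5")
  expect_equal(nrow(back), nrow(tbl) - 2)
})

test_that("day-1 normalization divides later days and constants day 1", {
  tbl <- tiny_marker_table()[1, ]
  tbl$prolif_day1 <- 2; tbl$prolif_day4 <- 4
  tbl$prolif_day7 <- 6; tbl$prolif_day14 <- 8
  out <- normalize_proliferation(tbl)
  expect_equal(unlist(out[1, c("prolif_day1", "prolif_day4", "prolif_day7",
                               "prolif_day14")], use.names = FALSE),
               c(1, 2, 3, 4))

  tbl[c("prolif_day1", "prolif_day4", "prolif_day7", "prolif_day14")] <- 5.5
  out <- normalize_proliferation(tbl)
  expect_equal(unlist(out[1, c("prolif_day1", "prolif_day4", "prolif_day7",
                               "prolif_day14")], use.names = FALSE),
               c(1, 1, 1, 1))

  # untouched markers stay untouched
  full <- tiny_marker_table()
  out <- normalize_proliferation(full)
  other <- setdiff(marker_names(), paste0("prolif_day", c(1, 4, 7, 14)))
  expect_equal(out[other], full[other])

  bad <- tiny_marker_table()
  bad$prolif_day1[4] <- 0
  expect_error(normalize_proliferation(bad), "row\\(s\\): 4")
})

test_that("feature matrix log-transforms intensities and z-scores columns", {
  tbl <- tiny_marker_table(n_rep = 2)
  X <- marker_feature_matrix(tbl)
  expect_equal(dim(X), c(48, 16))
  expect_equal(unname(colMeans(X)), rep(0, 16), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 16), tolerance = 1e-12)

  # log transform changes intensity ordering-preserving geometry only
  raw <- marker_feature_matrix(tbl, log_intensities = FALSE, standardize = FALSE)
  logd <- marker_feature_matrix(tbl, log_intensities = TRUE, standardize = FALSE)
  expect_equal(logd[, "cd44_mfi"], log(raw[, "cd44_mfi"]))
  expect_equal(logd[, "aldh_pos_pct"], raw[, "aldh_pos_pct"])

  # constant columns become inert zeros, not NaN
  tbl2 <- normalize_proliferation(tbl)
  X2 <- marker_feature_matrix(tbl2)
  expect_true(all(X2[, "prolif_day1"] == 0))
})
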