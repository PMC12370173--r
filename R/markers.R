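#' The 16-marker panel measured in each MPS condition
#'
#' Metadata for the sixteen cellular readouts recorded per (cell line,
#' microenvironment, replicate): Alamar-blue proliferation at days 1/4/7/14,
#' breast cancer stem-cell markers (CD44, CD24, CD44v6 median fluorescence
#' intensity; CD44+, CD24+, CD44+/CD24-, CD44v6+, ALDH+ percent positive),
#' and EMT markers (Vimentin and E-cadherin MFI and percent positive).
#'
#' @return A tibble with columns `marker` (column name used in tables),
#'   `label` (display label), `type` (`"prolif"`, `"mfi"` or `"pct"`), and
#'   `tier` (default planted importance tier: `"high"`, `"moderate"`, `"low"`).
#' @export
#' @examples
#' marker_info()
marker_info <- function() {
  tibble(
    marker = c("prolif_day1", "prolif_day4", "prolif_day7", "prolif_day14",
               "cd44_mfi", "cd24_mfi", "cd44v6_mfi",
               "cd44_pos_pct", "cd24_pos_pct", "cd44pos_cd24neg_pct",
               "cd44v6_pos_pct", "aldh_pos_pct",
               "vimentin_mfi", "ecadherin_mfi",
               "vimentin_pos_pct", "ecadherin_pos_pct"),
    label = c("Proliferation (day 1)", "Proliferation (day 4)",
              "Proliferation (day 7)", "Proliferation (day 14)",
              "CD44 (MFI)", "CD24 (MFI)", "CD44v6 (MFI)",
              "CD44+ (%)", "CD24+ (%)", "CD44+/CD24- (%)",
              "CD44v6+ (%)", "ALDH+ (%)",
              "Vimentin (MFI)", "E-cadherin (MFI)",
              "Vimentin+ (%)", "E-cadherin+ (%)"),
    type = c("prolif", "prolif", "prolif", "prolif",
             "mfi", "mfi", "mfi",
             "pct", "pct", "pct", "pct", "pct",
             "mfi", "mfi", "pct", "pct"),
    tier = c("low", "low", "low", "low",
             "high", "moderate", "high",
             "high", "moderate", "moderate", "high", "low",
             "high", "moderate", "high", "moderate")
  )
}

#' @rdname marker_info
#' @export
marker_names <- function() marker_info()$marker

meta_columns <- function() c("cell_line", "env_id", "replicate")

#' Validate a marker table against the dataset schema
#'
#' Checks that the table carries the three metadata columns (`cell_line`,
#' `env_id`, `replicate`) and the 16 marker columns, that cell lines are
#' `"invasive"`/`"noninvasive"`, env_ids reference the 12-condition grid,
#' percentages lie in \[0, 100\] and MFI/proliferation readouts are positive.
#'
#' @param table A data frame.
#' @param check_ranges Also check marker value ranges (default `TRUE`).
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_marker_table <- function(table, check_ranges = TRUE) {
  missing <- setdiff(c(meta_columns(), marker_names()), names(table))
  if (length(missing) > 0) {
    abort(paste0("Marker table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(table$cell_line %in% c("invasive", "noninvasive"))) {
    abort("`cell_line` must be 'invasive' or 'noninvasive'.")
  }
  if (!all(table$env_id %in% mps_condition_grid()$env_id)) {
    bad <- unique(setdiff(table$env_id, mps_condition_grid()$env_id))
    abort(paste0("Unknown env_id value(s): ", paste(bad, collapse = ", ")))
  }
  info <- marker_info()
  for (j in seq_len(nrow(info))) {
    v <- table[[info$marker[j]]]
    if (!is.numeric(v)) {
      abort(sprintf("Marker column '%s' is not numeric.", info$marker[j]))
    }
    if (check_ranges && info$type[j] == "pct" && any(v < 0 | v > 100, na.rm = TRUE)) {
      abort(sprintf("Percentage marker '%s' has values outside [0, 100].", info$marker[j]))
    }
    if (check_ranges && info$type[j] != "pct" && any(v <= 0, na.rm = TRUE)) {
      abort(sprintf("Intensity marker '%s' has non-positive values.", info$marker[j]))
    }
  }
  invisible(table)
}

#' Read and write marker tables as CSV
#'
#' `read_marker_table()` parses a wide CSV (one row per cell line x
#' microenvironment x replicate) into a validated tibble. Rows with any missing
#' marker value are dropped with a diagnostic listing the offending rows;
#' non-numeric marker cells and missing columns raise errors naming the
#' row/column. `write_marker_table()` writes the complementary format; a
#' read/write round trip preserves all values at the full printed precision.
#'
#' @param path Path of the CSV file.
#' @param schema_check Validate schema and value ranges (default `TRUE`).
#' @return `read_marker_table()` returns a tibble with metadata and the 16
#'   marker columns; `write_marker_table()` returns `path` invisibly.
#' @export
read_marker_table <- function(path, schema_check = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(c(meta_columns(), marker_names()), names(raw))
  if (length(missing) > 0) {
    abort(paste0("File '", path, "' is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("env_id", "replicate", marker_names())) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value '%s' in column '%s', row %d of '%s'.",
                    vals[bad[1]], col, bad[1], path))
    }
    raw[[col]] <- num
  }
  incomplete <- which(!stats::complete.cases(raw[marker_names()]))
  if (length(incomplete) > 0) {
    warn(paste0("Dropping ", length(incomplete), " row(s) with missing marker values: ",
                paste(incomplete, collapse = ", ")))
    raw <- raw[-incomplete, ]
  }
  out <- raw |>
    dplyr::mutate(env_id = as.integer(.data$env_id),
                  replicate = as.integer(.data$replicate)) |>
    as_tibble()
  if (schema_check) validate_marker_table(out)
  out
}

#' @param table A marker table (see [read_marker_table()]).
#' @rdname read_marker_table
#' @export
write_marker_table <- function(table, path, schema_check = TRUE) {
  if (schema_check) validate_marker_table(table)
  cols <- c(intersect(c(meta_columns(), marker_names()), names(table)),
            setdiff(names(table), c(meta_columns(), marker_names())))
  readr::write_csv(table[cols], path, progress = FALSE)
  invisible(path)
}

#' Clustering feature matrix of a marker table
#'
#' Extracts the 16-marker matrix used for distance-based analyses. Intensity
#' readouts (MFI and proliferation) are log-normal in flow-cytometry practice
#' and span orders of magnitude, so they are log-transformed by default;
#' percentage markers are kept on their natural scale. Columns are then
#' z-scored (zero-variance columns map to 0 so constant markers stay inert in
#' Euclidean distances). Mutual-information ranking is invariant to these
#' monotone transforms; clustering is not, which is why they matter here.
#'
#' @param table A marker table.
#' @param log_intensities Log-transform MFI/proliferation markers
#'   (default `TRUE`).
#' @param standardize Z-score all columns (default `TRUE`); set to `FALSE`
#'   for raw-scale distances.
#' @return A numeric matrix (records x 16 markers).
#' @export
marker_feature_matrix <- function(table, log_intensities = TRUE, standardize = TRUE) {
  validate_marker_table(table, check_ranges = FALSE)
  X <- as.matrix(table[marker_names()])
  if (log_intensities) {
    intens <- marker_info()$marker[marker_info()$type != "pct"]
    if (any(X[, intens] <= 0)) {
      abort("Intensity markers must be positive for the log transform.")
    }
    X[, intens] <- log(X[, intens])
  }
  if (standardize) X <- standardize_columns(X)
  X
}

#' Normalize proliferation readouts by their day-1 reading
#'
#' Divides the day-4/7/14 Alamar-blue intensities of each record by the same
#' record's day-1 intensity and replaces the day-1 column by the constant 1,
#' leaving all other markers untouched. The day-1 column is retained (as a
#' constant) so that the marker panel keeps its printed 16-column layout.
#'
#' @param table A marker table with raw proliferation intensities.
#' @return The table with normalized proliferation columns.
#' @export
#' @examples
#' tbl <- generate_markers(synthetic_config(seed = 1))
#' normalize_proliferation(tbl)
normalize_proliferation <- function(table) {
  days <- c("prolif_day1", "prolif_day4", "prolif_day7", "prolif_day14")
  missing <- setdiff(days, names(table))
  if (length(missing) > 0) {
    abort(paste0("Table is missing proliferation column(s): ",
                 paste(missing, collapse = ", ")))
  }
  d1 <- table$prolif_day1
  bad <- which(!is.finite(d1) | d1 <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Day-1 proliferation must be positive; offending row(s): %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  table |>
    dplyr::mutate(
      prolif_day4 = .data$prolif_day4 / d1,
      prolif_day7 = .data$prolif_day7 / d1,
      prolif_day14 = .data$prolif_day14 / d1,
      prolif_day1 = 1
    )
}
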