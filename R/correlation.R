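#' Sample Pearson correlation between two vectors
#'
#' The sample Pearson coefficient: centered cross-product over the product of
#' centered norms, lying in \[-1, 1\]. Zero-variance input is an error, not a
#' silent 0 — an undefined correlation must be surfaced explicitly.
#'
#' @param a,b Numeric vectors of equal length (at least 2), each with nonzero
#'   variance.
#' @return A single number in `[-1, 1]`.
#' @export
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2) abort("Need at least 2 observations.")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("Inputs must be finite.")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("Correlation is undefined for a zero-variance input.")
  }
  stats::cor(a, b)
}

#' Marker and marker-environment correlation matrix for one cell line
#'
#' Restricts a marker table to one cell line and computes the symmetric
#' Pearson correlation matrix over the 16 markers together with the 5 numeric
#' microenvironment features (expanded per record through
#' [encode_environment()]). Zero-variance columns (e.g. normalized day-1
#' proliferation, or an environment feature constant within the subset) are
#' reported as an explicit `NA` sentinel row/column — not as 0 — and listed in
#' the `undefined` attribute.
#'
#' @param table A marker table covering at least 2 records of `cell_line`
#'   spanning at least 2 environments.
#' @param cell_line `"invasive"` or `"noninvasive"`.
#' @param scheme Environment encoding scheme (see [encode_environment()]).
#' @return An object of class `mps_cor`: the (16 + 5) x (16 + 5) correlation
#'   matrix with unit diagonal, plus attributes `cell_line`, `undefined`.
#' @export
correlation_matrix <- function(table, cell_line, scheme = "numeric_default") {
  validate_marker_table(table, check_ranges = FALSE)
  sub <- dplyr::filter(table, .data$cell_line == !!cell_line)
  if (nrow(sub) < 2) abort(sprintf("Need at least 2 records of cell line '%s'.", cell_line))
  if (length(unique(sub$env_id)) < 2) {
    abort("Need records spanning at least 2 environments.")
  }
  M <- cbind(as.matrix(sub[marker_names()]), encode_environment(sub$env_id, scheme))
  sds <- apply(M, 2, stats::sd)
  undefined <- colnames(M)[sds == 0]
  if (length(undefined) > 0) {
    inform(paste0("Zero-variance column(s) marked undefined: ",
                  paste(undefined, collapse = ", ")))
  }
  R <- suppressWarnings(stats::cor(M))
  R[!is.finite(R)] <- NA_real_
  diag(R) <- 1
  structure(R, cell_line = cell_line, undefined = undefined,
            class = c("mps_cor", class(R)))
}

#' @export
print.mps_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation matrix (%s cell line): %d x %d labels\n",
              attr(x, "cell_line"), nrow(x), ncol(x)))
  und <- attr(x, "undefined")
  if (length(und) > 0) cat("undefined (zero-variance):", paste(und, collapse = ", "), "\n")
  invisible(x)
}
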