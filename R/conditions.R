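#' The 12-condition breast-specific microenvironment design grid
#'
#' Builds the fixed grid of twelve engineered tumor-microenvironment conditions
#' used throughout the pipeline: four alginate/gelatin hydrogel classes
#' (So-L, So-H, St-L, St-H; mean Young's moduli 1.8, 2.4, 6.1 and 10.1 kPa),
#' each cultured at pH 7.4 static, pH 6.5 static, and pH 7.4 dynamic
#' (perfused). The combination pH 6.5 + dynamic is not part of the design.
#'
#' @return A tibble with 12 rows and columns `env_id`, `hydrogel`,
#'   `young_modulus_kpa`, `alginate_pct`, `gelatin_pct`, `ph`, `perfusion`.
#'   The function is pure: repeated calls return identical tibbles.
#' @export
#' @examples
#' mps_condition_grid()
mps_condition_grid <- function() {
  hydrogel <- c("So-L", "So-H", "St-L", "St-H")
  modulus <- c(`So-L` = 1.8, `So-H` = 2.4, `St-L` = 6.1, `St-H` = 10.1)
  alginate <- c(`So-L` = 1.5, `So-H` = 1.5, `St-L` = 3, `St-H` = 3)
  gelatin <- c(`So-L` = 1, `So-H` = 3, `St-L` = 1, `St-H` = 3)
  # per hydrogel: pH 7.4 static, pH 6.5 static, pH 7.4 dynamic (design order)
  ph <- c(7.4, 6.5, 7.4)
  perfusion <- c("static", "static", "dynamic")
  grid <- tidyr::crossing(hydrogel = factor(hydrogel, levels = hydrogel),
                          slot = 1:3) |>
    dplyr::arrange(.data$hydrogel, .data$slot) |>
    dplyr::mutate(
      env_id = dplyr::row_number(),
      hydrogel = as.character(.data$hydrogel),
      young_modulus_kpa = unname(modulus[.data$hydrogel]),
      alginate_pct = unname(alginate[.data$hydrogel]),
      gelatin_pct = unname(gelatin[.data$hydrogel]),
      ph = ph[.data$slot],
      perfusion = perfusion[.data$slot]
    ) |>
    dplyr::select("env_id", "hydrogel", "young_modulus_kpa", "alginate_pct",
                  "gelatin_pct", "ph", "perfusion")
  grid
}

#' Numeric encoding of microenvironment conditions
#'
#' Encodes each condition as a length-5 numeric feature vector
#' `(young_modulus_kpa, gelatin_pct, alginate_pct, ph, perfusion)` with
#' perfusion coded static = 0, dynamic = 1. This is the `u` vector paired with
#' each marker record when correlating markers against microenvironment
#' features. The encoding is injective over the 12 design conditions.
#'
#' @param env A data frame with the columns produced by [mps_condition_grid()]
#'   (one or more rows), or a vector of `env_id`s to look up in the grid.
#' @param scheme Encoding scheme; only `"numeric_default"` is defined.
#' @return A numeric matrix with one row per condition and columns
#'   `stiffness_kpa`, `gelatin_pct`, `alginate_pct`, `ph`, `perfusion`.
#' @export
#' @examples
#' encode_environment(1)                   # So-L, pH 7.4, static
#' encode_environment(mps_condition_grid())
encode_environment <- function(env, scheme = "numeric_default") {
  if (!identical(scheme, "numeric_default")) {
    abort(sprintf("Unknown encoding scheme '%s'.", scheme))
  }
  grid <- mps_condition_grid()
  if (is.numeric(env)) {
    if (!all(env %in% grid$env_id)) {
      abort("`env` contains env_id values outside 1..12.")
    }
    env <- grid[match(env, grid$env_id), ]
  }
  required <- c("young_modulus_kpa", "gelatin_pct", "alginate_pct", "ph", "perfusion")
  missing <- setdiff(required, names(env))
  if (length(missing) > 0) {
    abort(paste0("`env` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(env$perfusion %in% c("static", "dynamic"))) {
    abort("`perfusion` must be 'static' or 'dynamic'.")
  }
  out <- cbind(
    stiffness_kpa = env$young_modulus_kpa,
    gelatin_pct = env$gelatin_pct,
    alginate_pct = env$alginate_pct,
    ph = env$ph,
    perfusion = as.numeric(env$perfusion == "dynamic")
  )
  rownames(out) <- if ("env_id" %in% names(env)) as.character(env$env_id) else NULL
  out
}

#' Enumerate the condition-stratification levels
#'
#' The profiling pipeline is run once per microenvironment condition level:
#' pH (7.4, 6.5), perfusion (static, dynamic), hydrogel class (So-L, So-H,
#' St-L, St-H), gelatin content (low, high), and alginate content (low, high) —
#' 12 levels in total, in that fixed order.
#'
#' @return A tibble with columns `variable` and `level` (both character).
#' @export
condition_levels <- function() {
  tibble(
    variable = c("pH", "pH", "perfusion", "perfusion",
                 "hydrogel", "hydrogel", "hydrogel", "hydrogel",
                 "gelatin", "gelatin", "alginate", "alginate"),
    level = c("7.4", "6.5", "static", "dynamic",
              "So-L", "So-H", "St-L", "St-H",
              "low", "high", "low", "high")
  )
}

#' Environments belonging to a stratification level
#'
#' @param variable One of `"pH"`, `"perfusion"`, `"hydrogel"`, `"gelatin"`,
#'   `"alginate"`.
#' @param level The level of that variable (see [condition_levels()]).
#' @return An integer vector of `env_id`s.
#' @export
#' @examples
#' env_ids_for_level("pH", "6.5")
env_ids_for_level <- function(variable, level) {
  grid <- mps_condition_grid()
  level <- as.character(level)
  ids <- switch(variable,
    pH = grid$env_id[abs(grid$ph - as.numeric(level)) < 1e-9],
    perfusion = grid$env_id[grid$perfusion == level],
    hydrogel = grid$env_id[grid$hydrogel == level],
    gelatin = grid$env_id[grid$gelatin_pct == if (level == "low") 1 else if (level == "high") 3 else NA],
    alginate = grid$env_id[grid$alginate_pct == if (level == "low") 1.5 else if (level == "high") 3 else NA],
    abort(sprintf("Unknown stratification variable '%s'.", variable))
  )
  if (length(ids) == 0) {
    abort(sprintf("Unknown level '%s' for variable '%s'.", level, variable))
  }
  ids
}
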