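#' Configuration for the synthetic marker-table generator
#'
#' The generator emulates the study design the pipeline assumes: 2 cell lines
#' (invasive / noninvasive) x 12 microenvironments x `replicates` independent
#' replicates, with the 16-marker panel of [marker_info()]. Marker values are
#' drawn on a latent Gaussian scale — latent mean + shared environment response
#' + a phenotype effect applied to the invasive line only + N(0, `noise_sd`)
#' noise — and then mapped to the observation scale: intensity-type markers
#' (MFI, raw proliferation) through an exponential link (positive,
#' right-skewed), percentage markers through a logistic link scaled to
#' \[0, 100\].
#'
#' Markers are split into planted importance tiers. High-tier markers
#' (Vimentin, CD44-family) separate the cell lines in every environment;
#' moderate-tier markers (CD24-type, E-cadherin) separate them only in
#' "stress" environments (pH 6.5 or dynamic perfusion); low-tier markers
#' (proliferation, ALDH+) never do. Independently of the cell line, stress
#' environments shift a set of regime markers (proliferation day 4/7/14,
#' ALDH+) in both lines, planting two environment-driven behavioural regimes
#' within each cell line.
#'
#' @param replicates Number of independent replicates per cell line and
#'   environment (default 3, matching averages of N = 3 experiments).
#' @param seed Master seed; every random draw in the generator derives from it.
#' @param effect_size Named list of standardized latent mean separations
#'   between cell lines per tier (defaults: high 4.0, moderate 2.5, low 0).
#' @param effect_scale Scalar multiplier applied to all tier effects (used for
#'   sensitivity/recovery analyses; default 1).
#' @param noise_sd Latent-scale noise standard deviation (default 1).
#' @param tier_map Named character vector mapping each of the 16 markers to a
#'   tier in `{"high", "moderate", "low"}`; defaults to `marker_info()$tier`.
#' @param env_response 16 x 12 numeric matrix of latent mean shifts (markers x
#'   environments) shared by both cell lines; defaults to
#'   [default_env_response()].
#' @return An object of class `mps_synth_config`.
#' @export
synthetic_config <- function(replicates = 3,
                             seed = 1,
                             effect_size = list(high = 4.0, moderate = 2.5, low = 0),
                             effect_scale = 1,
                             noise_sd = 1,
                             tier_map = NULL,
                             env_response = NULL) {
  info <- marker_info()
  if (is.null(tier_map)) {
    tier_map <- stats::setNames(info$tier, info$marker)
  }
  if (!setequal(names(tier_map), info$marker) || anyDuplicated(names(tier_map)) > 0) {
    abort("`tier_map` must name each of the 16 markers exactly once.")
  }
  if (!all(tier_map %in% c("high", "moderate", "low"))) {
    abort("`tier_map` values must be 'high', 'moderate' or 'low'.")
  }
  if (!all(c("high", "moderate", "low") %in% names(effect_size)) ||
      any(unlist(effect_size) < 0)) {
    abort("`effect_size` must give non-negative values for tiers high/moderate/low.")
  }
  stopifnot(replicates >= 1, noise_sd > 0, effect_scale >= 0)
  if (is.null(env_response)) env_response <- default_env_response()
  env_response <- as.matrix(env_response)
  if (!identical(dim(env_response), c(16L, 12L))) {
    abort("`env_response` must be a 16 x 12 matrix (markers x environments).")
  }
  structure(
    list(replicates = as.integer(replicates), seed = as.integer(seed),
         effect_size = effect_size, effect_scale = effect_scale,
         noise_sd = noise_sd, tier_map = tier_map[info$marker],
         env_response = env_response),
    class = "mps_synth_config"
  )
}

#' Default shared environment response
#'
#' Latent mean shifts applied in both cell lines: stress environments (pH 6.5
#' or dynamic perfusion) shift proliferation day 4/7/14 and ALDH+ (%) by 4
#' latent units, planting two clearly separated environment-driven regimes per
#' cell line — as distinguishable as the high-tier phenotype separation.
#'
#' @param shift Latent shift applied in stress environments (default 4).
#' @param markers Markers carrying the regime response.
#' @return A 16 x 12 numeric matrix (markers x environments).
#' @export
default_env_response <- function(shift = 4,
                                 markers = c("prolif_day4", "prolif_day7",
                                             "prolif_day14", "aldh_pos_pct")) {
  grid <- mps_condition_grid()
  stress <- grid$ph < 7 | grid$perfusion == "dynamic"
  m <- matrix(0, nrow = 16, ncol = 12,
              dimnames = list(marker_names(), as.character(grid$env_id)))
  m[markers, stress] <- shift
  m
}

# latent baseline per marker: sets realistic observation-scale locations
latent_baseline <- function() {
  info <- marker_info()
  base <- numeric(nrow(info))
  base[info$type == "mfi"] <- log(100)       # MFI around 100 a.u.
  base[info$type == "pct"] <- qnorm(0.2) / 0.5 # baseline ~ 20% positive region
  base[info$marker == "prolif_day1"] <- log(1000)
  base[info$marker == "prolif_day4"] <- log(1400)
  base[info$marker == "prolif_day7"] <- log(1800)
  base[info$marker == "prolif_day14"] <- log(2100)
  stats::setNames(base, info$marker)
}

# environments where the moderate tier separates the cell lines
stress_environments <- function() {
  grid <- mps_condition_grid()
  grid$env_id[grid$ph < 7 | grid$perfusion == "dynamic"]
}

# per-(marker, env) phenotype effect for the invasive line, given a config
effect_matrix <- function(config) {
  grid <- mps_condition_grid()
  tiers <- config$tier_map
  eff <- matrix(0, nrow = 16, ncol = 12,
                dimnames = list(marker_names(), as.character(grid$env_id)))
  stress <- grid$env_id %in% stress_environments()
  for (j in seq_len(16)) {
    tier <- tiers[j]
    size <- config$effect_size[[tier]] * config$effect_scale
    active <- if (tier == "moderate") stress else if (tier == "high") rep(TRUE, 12) else rep(FALSE, 12)
    eff[j, active] <- size
  }
  eff
}

#' Generate a synthetic marker table
#'
#' Draws a full design (2 cell lines x 12 environments x replicates) from the
#' latent model described in [synthetic_config()]. All randomness flows from
#' the config's master seed; each record's noise stream is derived from
#' (seed, cell line, environment, replicate), so increasing `replicates`
#' extends the table without reshuffling existing records, and the same seed
#' always reproduces the same table.
#'
#' @param config An [synthetic_config()] object.
#' @return A validated marker table tibble with `N = 2 * 12 * replicates`
#'   rows; the config is attached as attribute `"config"`.
#' @export
#' @examples
#' tbl <- generate_markers(synthetic_config(seed = 7))
#' nrow(tbl)  # 72
generate_markers <- function(config) {
  if (!inherits(config, "mps_synth_config")) {
    abort("`config` must be created by synthetic_config().")
  }
  info <- marker_info()
  base <- latent_baseline()
  eff <- effect_matrix(config)
  design <- tidyr::crossing(cell_line = c("invasive", "noninvasive"),
                            env_id = 1:12,
                            replicate = seq_len(config$replicates))
  rows <- purrr::pmap(design, function(cell_line, env_id, replicate) {
    mu <- base + config$env_response[, env_id]
    if (cell_line == "invasive") mu <- mu + eff[, env_id]
    eps <- with_seed_if(derive_seed(config$seed, "record", cell_line, env_id, replicate),
                        rnorm(16, 0, config$noise_sd))
    z <- mu + eps
    obs <- ifelse(info$type == "pct", 100 * plogis(0.5 * z), exp(z))
    stats::setNames(as.list(obs), info$marker)
  })
  out <- dplyr::bind_cols(design, dplyr::bind_rows(rows)) |>
    dplyr::arrange(.data$cell_line, .data$env_id, .data$replicate)
  validate_marker_table(out)
  attr(out, "config") <- config
  out
}

#' Markers recoverably discriminative at a stratification level
#'
#' Returns the planted ground truth for feature-recovery tests: the markers
#' whose configured cell-line effect is strictly positive in every environment
#' of the given condition level. High-tier markers are recoverable at every
#' level; moderate-tier markers only at levels entirely composed of stress
#' environments (e.g. pH 6.5, dynamic).
#'
#' @param config An [synthetic_config()] object.
#' @param variable,level A stratification level (see [condition_levels()]).
#' @return A character vector of marker names.
#' @export
#' @examples
#' planted_truth(synthetic_config(), "pH", "6.5")
planted_truth <- function(config, variable, level) {
  if (!inherits(config, "mps_synth_config")) {
    abort("`config` must be created by synthetic_config().")
  }
  envs <- env_ids_for_level(variable, level)
  eff <- effect_matrix(config)
  active <- apply(eff[, as.character(envs), drop = FALSE] > 0, 1, all)
  marker_names()[active]
}
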