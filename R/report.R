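#' Read a run configuration from YAML
#'
#' A run configuration names either an input CSV (`input`) or a synthetic
#' generator configuration (`synthetic`, with any of the [synthetic_config()]
#' fields), plus the analysis settings `seed`, `tau`, `k_max`, `epsilon`,
#' `estimator`. Exactly one of `input` / `synthetic` must be present.
#'
#' @param path Path of a YAML file.
#' @return A named list with validated fields and defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_input <- !is.null(cfg$input)
  has_synth <- !is.null(cfg$synthetic)
  if (has_input == has_synth) {
    abort("Config must set exactly one of `input` or `synthetic`.")
  }
  defaults <- list(seed = 1, tau = 0.65, k_max = 6, epsilon = 0.01,
                   estimator = "knn")
  out <- modifyList(defaults, cfg)
  if (!out$estimator %in% c("knn", "binned")) {
    abort("`estimator` must be 'knn' or 'binned'.")
  }
  out
}

#' Write a synthetic dataset with its planted truth to disk
#'
#' Generates a marker table from a synthetic configuration and writes the
#' dataset CSV, the planted truth per condition level (JSON), and an echo of
#' the configuration (YAML) into `out_dir`. Rerunning with the same config is
#' byte-identical.
#'
#' @param config An [synthetic_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
simulate_markers_files <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- generate_markers(config)
  paths <- list(
    dataset = file.path(out_dir, "markers.csv"),
    truth = file.path(out_dir, "planted_truth.json"),
    config = file.path(out_dir, "synthetic_config.yaml")
  )
  write_marker_table(tbl, paths$dataset)
  truth <- condition_levels() |>
    dplyr::mutate(markers = purrr::map2(.data$variable, .data$level,
                                        ~ planted_truth(config, .x, .y)))
  jsonlite::write_json(
    stats::setNames(truth$markers, paste(truth$variable, truth$level, sep = "=")),
    paths$truth, pretty = TRUE)
  yaml::write_yaml(config_as_list(config), paths$config)
  invisible(paths)
}

config_as_list <- function(config) {
  list(replicates = config$replicates, seed = config$seed,
       effect_size = config$effect_size, effect_scale = config$effect_scale,
       noise_sd = config$noise_sd, tier_map = as.list(config$tier_map),
       env_response = apply(config$env_response, 2, as.numeric, simplify = FALSE))
}

#' Run the full profiling pipeline and write a reproducible report
#'
#' Assembles every stage on one dataset: per-cell-line correlation matrices,
#' per-cell-line intraphenotype behaviour detection, the 12 condition-level
#' profiles, and the cross-condition importance aggregation. Raw proliferation
#' readouts are day-1-normalized first (disable with `normalize = FALSE` if
#' the table is already normalized). Results are written as one JSON report
#' plus tidy CSVs; every artifact embeds the master seed and a config hash,
#' and rerunning with the same inputs and seed reproduces all files
#' byte-for-byte.
#'
#' @param table A marker table; alternatively pass `config` to generate one.
#' @param config Optional [synthetic_config()]; exactly one of `table`/
#'   `config` must be given.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for all stochastic stages.
#' @param tau,k_max,epsilon,estimator,restarts Analysis settings (see
#'   [profile_condition()], [select_num_clusters()]).
#' @param normalize Apply [normalize_proliferation()] first (default `TRUE`).
#' @return Invisibly, a list with all in-memory results (`correlations`,
#'   `intraphenotype`, `profiles`, `aggregate`) and the file paths written.
#' @export
run_profiling_report <- function(table = NULL, config = NULL, out_dir,
                                 seed = 1, tau = 0.65, k_max = 6,
                                 epsilon = 0.01, estimator = "knn",
                                 restarts = 20, normalize = TRUE) {
  if (is.null(table) == is.null(config)) {
    abort("Provide exactly one of `table` or `config`.")
  }
  if (is.null(table)) table <- generate_markers(config)
  validate_marker_table(table, check_ranges = FALSE)
  if (normalize) table <- normalize_proliferation(table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lines <- c("invasive", "noninvasive")
  correlations <- purrr::map(stats::setNames(lines, lines), function(cl)
    suppressMessages(correlation_matrix(table, cl)))
  intraphenotype <- purrr::map(stats::setNames(lines, lines), function(cl)
    intraphenotype_behaviors(table, cl, k_max = k_max, epsilon = epsilon,
                             seed = derive_seed(seed, "intra", cl),
                             restarts = restarts))
  profiles <- profile_all_conditions(table, tau = tau,
                                     seed = derive_seed(seed, "profiles"),
                                     estimator = estimator, restarts = restarts)
  aggregate <- aggregate_importance(profiles)

  settings <- list(seed = seed, tau = tau, k_max = k_max, epsilon = epsilon,
                   estimator = estimator, restarts = restarts,
                   normalize = normalize)
  config_hash <- derive_seed(seed, "confighash", paste(names(settings),
                                                       unlist(settings), collapse = ";"))
  report <- list(
    settings = settings,
    config_hash = config_hash,
    n_records = nrow(table),
    correlations = purrr::map(correlations, function(R) {
      list(labels = colnames(R), values = unclass(R),
           undefined = attr(R, "undefined"))
    }),
    intraphenotype = purrr::map(intraphenotype, function(b) {
      list(cell_line = b$cell_line, k = b$k, scores = b$scores,
           low_confidence = b$low_confidence, retained = b$retained)
    }),
    profiles = purrr::map(unclass(profiles), profile_as_list),
    aggregate = as.data.frame(aggregate)
  )

  paths <- list(
    report = file.path(out_dir, "report.json"),
    aggregate = file.path(out_dir, "aggregate_importance.csv"),
    rankings = file.path(out_dir, "condition_rankings.csv"),
    assignments = file.path(out_dir, "dataset_with_assignments.csv")
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  readr::write_csv(as.data.frame(aggregate), paths$aggregate, progress = FALSE)
  rankings <- purrr::map_dfr(unclass(profiles), function(p)
    dplyr::mutate(as_tibble(p$ranking), variable = p$variable, level = p$level,
                  .before = 1))
  readr::write_csv(rankings, paths$rankings, progress = FALSE)
  with_assign <- table
  for (cl in lines) {
    col <- paste0("intraphenotype_cluster_", cl)
    with_assign[[col]] <- NA_integer_
    with_assign[[col]][with_assign$cell_line == cl] <-
      intraphenotype[[cl]]$fit$assignments
  }
  readr::write_csv(with_assign, paths$assignments, progress = FALSE)

  invisible(list(correlations = correlations, intraphenotype = intraphenotype,
                 profiles = profiles, aggregate = aggregate,
                 settings = settings, paths = paths))
}

profile_as_list <- function(p) {
  conf <- function(cm) if (is.null(cm)) NULL else
    list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn, accuracy = cm$accuracy)
  list(variable = p$variable, level = p$level, n_records = p$n_records,
       silhouette_pre = p$silhouette_pre, silhouette_post = p$silhouette_post,
       ranking = as.data.frame(p$ranking), retained = p$retained,
       confusion_pre = conf(p$confusion_pre), confusion_post = conf(p$confusion_post),
       no_features = p$no_features)
}
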