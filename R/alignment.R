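#' Align unsupervised cluster labels with the true phenotype labels
#'
#' Two-cluster assignments carry no inherent class identity; both possible
#' cluster-to-class mappings are evaluated and the one maximizing accuracy is
#' returned together with the resulting 2x2 confusion matrix. By construction
#' the aligned accuracy is at least 0.5. At exactly equal accuracy the
#' identity mapping (cluster 1 -> invasive) is preferred. The invasive
#' phenotype is the positive class throughout.
#'
#' @param assignments Cluster labels with exactly 2 distinct values.
#' @param truth True labels: `"invasive"`/`"noninvasive"`, or a binary vector
#'   where the larger value (or `TRUE`) marks the invasive class.
#' @return An object of class `mps_confusion`: list with `tp`, `fn`, `fp`,
#'   `tn`, `accuracy`, and `mapping` (`"identity"` or `"swap"`).
#' @export
#' @examples
#' align_clusters(c(1, 1, 2, 2), c("invasive", "invasive", "noninvasive", "noninvasive"))
align_clusters <- function(assignments, truth) {
  if (length(assignments) != length(truth)) {
    abort("`assignments` and `truth` must have equal length.")
  }
  a_vals <- sort(unique(assignments))
  if (length(a_vals) != 2) abort("`assignments` must contain exactly 2 clusters.")
  pos <- truth_is_invasive(truth)
  if (length(unique(pos)) != 2) abort("`truth` must contain both classes.")

  conf_for <- function(cluster_pos) {
    pred_pos <- assignments == cluster_pos
    list(tp = sum(pred_pos & pos), fn = sum(!pred_pos & pos),
         fp = sum(pred_pos & !pos), tn = sum(!pred_pos & !pos))
  }
  identity <- conf_for(a_vals[1])
  swap <- conf_for(a_vals[2])
  acc <- function(cm) (cm$tp + cm$tn) / length(pos)
  use_identity <- acc(identity) >= acc(swap)
  cm <- if (use_identity) identity else swap
  structure(
    c(cm, list(accuracy = acc(cm), mapping = if (use_identity) "identity" else "swap")),
    class = "mps_confusion"
  )
}

truth_is_invasive <- function(truth) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth)
    if (!all(truth %in% c("invasive", "noninvasive"))) {
      abort("Character `truth` must be 'invasive'/'noninvasive'.")
    }
    truth == "invasive"
  } else {
    vals <- sort(unique(truth))
    if (length(vals) != 2) abort("`truth` must be binary.")
    truth == vals[2]
  }
}

#' @export
print.mps_confusion <- function(x, ...) {
  cat(sprintf("confusion (invasive = positive, %s mapping):\n", x$mapping))
  cat(sprintf("  tp = %d  fp = %d\n  fn = %d  tn = %d  accuracy = %.3f\n",
              x$tp, x$fp, x$fn, x$tn, x$accuracy))
  invisible(x)
}
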