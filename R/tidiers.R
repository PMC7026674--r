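# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PAM clustering result
#' @param x A `pam_result`.
#' @param ... Ignored.
#' @return Tibble `sample_id`, `cluster`, `silhouette`, `is_medoid`.
#' @export
tidy.pam_result <- function(x, ...) {
  tibble::tibble(
    sample_id = names(x$assignment),
    cluster = unname(x$assignment),
    silhouette = unname(x$per_sample_silhouette),
    is_medoid = names(x$assignment) %in% x$medoid_ids
  )
}

#' @rdname tidy.pam_result
#' @export
glance.pam_result <- function(x, ...) {
  tibble::tibble(k = x$k, mean_silhouette = x$mean_silhouette,
                 total_cost = x$total_cost)
}

#' Tidy a hierarchical-classification evaluation report
#' @param x An `hmc_eval_report`.
#' @param ... Ignored.
#' @return Tibble `node`, `auprc`, `feature_set`, `protocol`.
#' @export
tidy.hmc_eval_report <- function(x, ...) {
  tibble::tibble(node = names(x$auprc_per_node),
                 auprc = unname(x$auprc_per_node),
                 feature_set = x$feature_set, protocol = x$protocol)
}

#' @rdname tidy.hmc_eval_report
#' @export
glance.hmc_eval_report <- function(x, ...) {
  tibble::tibble(feature_set = x$feature_set, protocol = x$protocol,
                 n = x$n, auprc_bar = x$auprc_bar,
                 n_dropped = length(x$dropped_samples), seed = x$seed)
}

#' Tidy a PCT forest (Genie3 importances)
#' @param x A `pct_forest`.
#' @param ... Ignored.
#' @return Tibble `feature`, `genie3_score`.
#' @export
tidy.pct_forest <- function(x, ...) genie3_importance(x)
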