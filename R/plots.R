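# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   facet_wrap labs theme_minimal coord_flip geom_hline
#' @export
ggplot2::autoplot

#' Silhouette plot of a PAM result
#' @param object A `pam_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pam_result <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$silhouette)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot(df, aes(x = .data$rank, y = .data$silhouette,
                 fill = factor(.data$cluster))) +
    geom_col(width = 1) +
    geom_hline(yintercept = object$mean_silhouette, linetype = "dashed") +
    labs(x = NULL, y = "silhouette width", fill = "cluster",
         title = sprintf("PAM, k = %d (mean silhouette %.3f)",
                         object$k, object$mean_silhouette)) +
    theme_minimal()
}

#' Per-node AUPRC bars for one or more evaluation reports
#'
#' With a single report, plots its per-node AUPRC; pass extra reports via
#' `...` to compare feature sets side by side (the display mirroring the
#' delta-AUPRC reading: bars extending beyond the host-only bar are the
#' microbial contribution).
#'
#' @param object An `hmc_eval_report`.
#' @param ... Further `hmc_eval_report` objects.
#' @return A ggplot.
#' @export
autoplot.hmc_eval_report <- function(object, ...) {
  more <- Filter(function(o) inherits(o, "hmc_eval_report"), list(...))
  df <- dplyr::bind_rows(lapply(c(list(object), more), tidy))
  ggplot(df, aes(x = .data$auprc, y = .data$node, fill = .data$feature_set)) +
    geom_col(position = "dodge") +
    labs(x = "AUPRC", y = "diagnosis group", fill = NULL) +
    theme_minimal()
}

#' Precision-recall curve plot
#' @param curve A [pr_curve()] tibble.
#' @return A ggplot.
#' @export
plot_pr_curve <- function(curve) {
  ggplot(curve, aes(x = .data$recall, y = .data$precision)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "recall", y = "precision") +
    theme_minimal()
}

#' Silhouette-by-k profile from [select_k()]
#' @param by_k The `by_k` tibble of a [select_k()] result.
#' @return A ggplot.
#' @export
plot_silhouette_by_k <- function(by_k) {
  ggplot(by_k, aes(x = .data$k, y = .data$mean_silhouette)) +
    geom_line() + geom_point() +
    labs(x = "number of clusters k", y = "mean silhouette width") +
    theme_minimal()
}
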