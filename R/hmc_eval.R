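# Evaluation of hierarchical classifiers: per-node precision-recall curves
# and AUPRC, micro-averaged pooled AUPRC-bar, out-of-bag / k-fold protocols,
# and delta-AUPRC contrasts against a host-factors-only baseline.

#' Precision-recall curve
#'
#' One point per distinct score threshold (predict positive iff
#' score >= threshold), scanned from the highest threshold down; the point
#' with zero predicted positives is skipped.
#'
#' @param scores Numeric prediction scores.
#' @param truth Binary ground truth (>= 1 positive required).
#' @return Tibble `threshold`, `recall`, `precision`, recall non-decreasing.
#' @export
pr_curve <- function(scores, truth) {
  truth <- as.numeric(truth)
  if (sum(truth) == 0) abort("pr_curve: no positive samples.")
  stopifnot(length(scores) == length(truth))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last_of_threshold <- which(!duplicated(s, fromLast = TRUE))
  tibble::tibble(
    threshold = s[last_of_threshold],
    recall = tp[last_of_threshold] / sum(truth),
    precision = tp[last_of_threshold] /
      (tp[last_of_threshold] + fp[last_of_threshold])
  )
}

#' Area under a precision-recall curve
#'
#' Linear (trapezoidal) interpolation in (recall, precision) over the
#' achievable curve points, left-anchored at (0, precision of the first
#' point).
#'
#' @param curve A [pr_curve()] tibble.
#' @return Area in `[0, 1]`.
#' @export
auprc <- function(curve) {
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

#' Micro-averaged pooled precision-recall curve
#'
#' Pools (score, truth) pairs across hierarchy nodes: at each threshold the
#' pooled precision and recall use summed TP/FP/positives over nodes. The
#' root node is excluded by default (always positive, uninformative).
#'
#' @param scores_by_node Named list of score vectors per hierarchy node.
#' @param truth_by_node Named list of binary truth vectors, same shape.
#' @param exclude_root Name of the root node to drop, or `NULL`.
#' @return List with `curve` (tibble) and `auprc_bar`.
#' @export
pooled_pr <- function(scores_by_node, truth_by_node, exclude_root = NULL) {
  keep <- names(scores_by_node)
  if (!is.null(exclude_root)) keep <- setdiff(keep, exclude_root)
  keep <- keep[vapply(truth_by_node[keep], function(t) sum(t) > 0, logical(1))]
  if (length(keep) == 0) abort("pooled_pr: no node with positives.")
  s <- unlist(scores_by_node[keep], use.names = FALSE)
  y <- unlist(truth_by_node[keep], use.names = FALSE)
  curve <- pr_curve(s, y)
  list(curve = curve, auprc_bar = auprc(curve))
}

#' Evaluate a PCT forest on hierarchical diagnosis labels
#'
#' Trains a [train_pct_forest()] on the given feature matrix and scores every
#' sample either out-of-bag (each sample scored only by the trees whose
#' bootstrap excluded it; never-OOB samples are dropped and logged) or by
#' stratified k-fold cross-validation. Reports per-node AUPRC for every
#' non-root hierarchy node with at least one positive, and the pooled
#' micro-averaged AUPRC-bar.
#'
#' @param features Numeric matrix/data frame, samples x features.
#' @param leaves Diagnosis leaf per sample (hierarchy node names).
#' @param hierarchy A [build_hierarchy()] result (default
#'   [diagnosis_hierarchy()]).
#' @param feature_set Label stored in the report (e.g. `"HostBacteria"`).
#' @param protocol `"oob"` or `"kfold"`.
#' @param k Folds for `"kfold"` (stratified by leaf; default 10).
#' @param w0 Hierarchy weight base (see [node_weights()]).
#' @param n_trees,mtry,min_leaf Forest parameters.
#' @param seed Integer seed.
#' @return Object of class `hmc_eval_report`: `feature_set`, `protocol`,
#'   `auprc_per_node` (named), `auprc_bar`, `scores`, `truth`,
#'   `dropped_samples`, `seed`, and the fitted `forest` (OOB protocol only).
#' @export
evaluate_hmc <- function(features, leaves, hierarchy = diagnosis_hierarchy(),
                         feature_set = "features", protocol = c("oob", "kfold"),
                         k = 10L, w0 = 0.75, n_trees = 100L, mtry = NULL,
                         min_leaf = 2L, seed = 1L) {
  protocol <- match.arg(protocol)
  x <- as.matrix(features)
  y <- label_matrix(leaves, hierarchy)
  w <- node_weights(hierarchy, w0)
  n <- nrow(x)
  dropped <- character(0)
  forest <- NULL

  if (protocol == "oob") {
    forest <- train_pct_forest(x, y, w, n_trees = n_trees, mtry = mtry,
                               min_leaf = min_leaf, seed = seed)
    scores <- matrix(NA_real_, n, ncol(y), dimnames = list(rownames(x), colnames(y)))
    oob_trees <- lapply(seq_len(n), function(i)
      which(vapply(forest$oob, function(o) i %in% o, logical(1))))
    all_pred <- lapply(seq_len(n_trees), function(b)
      predict_pct_tree(forest$trees[[b]], x))
    for (i in seq_len(n)) {
      tb <- oob_trees[[i]]
      if (length(tb) == 0) next
      acc <- 0
      for (b in tb) acc <- acc + all_pred[[b]][i, ]
      scores[i, ] <- acc / length(tb)
    }
    never <- which(rowSums(is.na(scores)) > 0)
    dropped <- rownames(x)[never] %||% as.character(never)
    keep <- setdiff(seq_len(n), never)
    scores <- scores[keep, , drop = FALSE]
    y <- y[keep, , drop = FALSE]
  } else {
    folds <- with_seed(split_seed(seed, 1, salt = 7L), {
      f <- integer(n)
      for (lev in unique(leaves)) {
        idx <- which(leaves == lev)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    })
    scores <- matrix(NA_real_, n, ncol(y), dimnames = list(rownames(x), colnames(y)))
    for (fold in seq_len(k)) {
      test <- which(folds == fold)
      if (length(test) == 0) next
      train <- setdiff(seq_len(n), test)
      fit <- train_pct_forest(x[train, , drop = FALSE], y[train, , drop = FALSE],
                              w, n_trees = n_trees, mtry = mtry,
                              min_leaf = min_leaf,
                              seed = split_seed(seed, fold))
      scores[test, ] <- predict(fit, x[test, , drop = FALSE])
    }
  }

  root <- hierarchy_root(hierarchy)
  nodes <- setdiff(colnames(y), root)
  auprc_per_node <- numeric(0)
  scores_by_node <- list(); truth_by_node <- list()
  for (node in nodes) {
    if (sum(y[, node]) == 0) next  # zero-positive nodes reported as absent
    auprc_per_node[node] <- auprc(pr_curve(scores[, node], y[, node]))
    scores_by_node[[node]] <- scores[, node]
    truth_by_node[[node]] <- y[, node]
  }
  pooled <- pooled_pr(scores_by_node, truth_by_node)

  structure(list(feature_set = feature_set, protocol = protocol,
                 auprc_per_node = auprc_per_node,
                 auprc_bar = pooled$auprc_bar, pooled_curve = pooled$curve,
                 scores = scores, truth = y, dropped_samples = dropped,
                 n = nrow(scores), seed = seed, forest = forest),
            class = "hmc_eval_report")
}

#' @export
print.hmc_eval_report <- function(x, ...) {
  cat(sprintf("<hmc_eval_report> %s (%s, n = %d): AUPRC-bar %.3f\n",
              x$feature_set, x$protocol, x$n, x$auprc_bar))
  print(round(x$auprc_per_node, 3))
  invisible(x)
}

#' Node-wise AUPRC gain over a baseline report
#'
#' delta(node) = AUPRC(report) - AUPRC(baseline); positive values mean the
#' report's feature set carries information about that diagnosis group
#' beyond the baseline's. Nodes absent from either report are absent from
#' the output.
#'
#' @param report,baseline `hmc_eval_report` objects from the same protocol
#'   and sample set.
#' @return Named numeric vector of AUPRC differences.
#' @export
delta_auprc <- function(report, baseline) {
  if (!identical(report$protocol, baseline$protocol)) {
    abort("delta_auprc: protocol mismatch between reports.")
  }
  nodes <- intersect(names(report$auprc_per_node), names(baseline$auprc_per_node))
  report$auprc_per_node[nodes] - baseline$auprc_per_node[nodes]
}
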