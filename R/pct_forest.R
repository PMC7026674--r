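# Predictive clustering trees (PCTs) for hierarchical multi-label
# classification, Random Forest ensembles thereof, and Genie3 attribute
# importance. A PCT is a decision tree grown to minimise the weighted
# variance of hierarchy label vectors within its nodes; a leaf predicts the
# mean label vector (prototype) of the training samples reaching it.

#' Weighted variance of a set of label vectors
#'
#' Var(S) = (1/|S|) sum_s d(v_s, v_bar)^2 with the weighted squared
#' Euclidean label distance d^2(a, b) = sum_c w_c (a_c - b_c)^2. Zero iff
#' all vectors are identical.
#'
#' @param vectors Numeric matrix, samples x hierarchy nodes.
#' @param weights Positive weight per node (see [node_weights()]).
#' @return Non-negative scalar.
#' @export
weighted_variance <- function(vectors, weights) {
  v <- as.matrix(vectors)
  if (nrow(v) == 0) abort("weighted_variance: empty set.")
  m2 <- colMeans(v * v)
  m1 <- colMeans(v)
  sum(weights * (m2 - m1 * m1))
}

#' Best variance-reducing split at a tree node
#'
#' Scans candidate numeric features; thresholds are midpoints between
#' consecutive distinct sorted values. Maximises
#' reduction = Var(S) - sum_part (|part|/|S|) Var(part); ties go to the
#' lowest feature index, then the lowest threshold. Returns `NULL` when the
#' labels are already homogeneous or no split respects `min_leaf`. A split
#' with zero reduction on an impure node is still returned (forest
#' convention: growth continues to the size limit, so conjunctive patterns
#' like XOR are resolved by deeper splits).
#'
#' @param features Numeric matrix (samples at this node x features).
#' @param vectors Label matrix aligned with `features` rows.
#' @param weights Node weights.
#' @param candidates Column indices to consider (default all).
#' @param min_leaf Minimum samples per child.
#' @return List `feature` (column index), `threshold`, `reduction`, or `NULL`.
#' @export
best_split <- function(features, vectors, weights, candidates = NULL,
                       min_leaf = 1L) {
  x_all <- as.matrix(features)
  y <- as.matrix(vectors)
  n <- nrow(x_all)
  if (n < 2) return(NULL)
  if (is.null(candidates)) candidates <- seq_len(ncol(x_all))
  candidates <- sort(candidates)
  var_total <- weighted_variance(y, weights)
  if (var_total <= 1e-15) return(NULL)

  t1 <- colSums(y); t2 <- colSums(y * y)
  tot2w <- sum(weights * t2)
  best <- NULL
  for (j in candidates) {
    x <- x_all[, j]
    ord <- order(x)
    xs <- x[ord]
    valid_pos <- which(xs[-n] < xs[-1])
    valid_pos <- valid_pos[valid_pos >= min_leaf & (n - valid_pos) >= min_leaf]
    if (length(valid_pos) == 0) next
    ys <- y[ord, , drop = FALSE]
    s1 <- apply(ys, 2, cumsum)
    s2 <- apply(ys * ys, 2, cumsum)
    i <- valid_pos
    q2 <- as.vector(s2 %*% weights)[i]
    qs <- as.vector((s1 * s1) %*% weights)[i]
    cross <- as.vector(s1 %*% (weights * t1))[i]
    var_l <- q2 / i - qs / (i * i)
    ni <- n - i
    var_r <- (tot2w - q2) / ni -
      (sum(weights * t1 * t1) - 2 * cross + qs) / (ni * ni)
    red <- pmax(var_total - (i / n) * var_l - (ni / n) * var_r, 0)
    b <- which.max(red)
    if (is.null(best) || red[b] > best$reduction + 1e-12) {
      pos <- i[b]
      best <- list(feature = j, threshold = (xs[pos] + xs[pos + 1]) / 2,
                   reduction = red[b])
    }
  }
  best
}

# Recursive tree growth; returns a flat list of node records.
grow_nodes <- function(x, y, weights, idx, min_leaf, max_depth, mtry, depth,
                       tree_env) {
  ni <- length(idx)
  proto <- colMeans(y[idx, , drop = FALSE])
  var_here <- weighted_variance(y[idx, , drop = FALSE], weights)
  make_leaf <- function() {
    tree_env$nodes[[length(tree_env$nodes) + 1]] <-
      list(leaf = TRUE, n = ni, prototype = proto)
    length(tree_env$nodes)
  }
  if (ni < 2 * min_leaf || var_here <= 1e-15 || depth >= max_depth) {
    return(make_leaf())
  }
  p <- ncol(x)
  cand <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
  sp <- best_split(x[idx, , drop = FALSE], y[idx, , drop = FALSE], weights,
                   candidates = cand, min_leaf = min_leaf)
  if (is.null(sp)) return(make_leaf())
  go_left <- x[idx, sp$feature] <= sp$threshold
  me <- length(tree_env$nodes) + 1
  tree_env$nodes[[me]] <- list(leaf = FALSE, n = ni, feature = sp$feature,
                               threshold = sp$threshold,
                               reduction = sp$reduction, prototype = proto)
  left <- grow_nodes(x, y, weights, idx[go_left], min_leaf, max_depth, mtry,
                     depth + 1, tree_env)
  right <- grow_nodes(x, y, weights, idx[!go_left], min_leaf, max_depth, mtry,
                      depth + 1, tree_env)
  tree_env$nodes[[me]]$left <- left
  tree_env$nodes[[me]]$right <- right
  me
}

#' Grow a single predictive clustering tree
#'
#' Recursive [best_split()] with an optional random candidate-feature subset
#' per node (`mtry`); growth stops at homogeneous labels, fewer than
#' `2 * min_leaf` samples, or no positive-reduction split.
#'
#' @param features Numeric matrix, samples x features.
#' @param vectors Label matrix, samples x hierarchy nodes.
#' @param weights Node weights.
#' @param min_leaf Minimum samples per leaf (default 2).
#' @param max_depth Depth cap (default unlimited).
#' @param mtry Candidate features per node (default all). Uses the current
#'   RNG state when `mtry < ncol(features)`.
#' @return List of class `pct_tree` with `nodes` (flat node list) and
#'   `node_names` (hierarchy node order of the prototypes).
#' @export
grow_pct <- function(features, vectors, weights, min_leaf = 2L,
                     max_depth = Inf, mtry = ncol(features)) {
  x <- as.matrix(features); y <- as.matrix(vectors)
  stopifnot(nrow(x) == nrow(y))
  env <- new.env()
  env$nodes <- list()
  grow_nodes(x, y, weights, seq_len(nrow(x)), min_leaf, max_depth, mtry, 0, env)
  structure(list(nodes = env$nodes, node_names = colnames(y)),
            class = "pct_tree")
}

# Route every row of x through a tree; returns matrix rows x label nodes.
predict_pct_tree <- function(tree, x) {
  n <- nrow(x)
  q <- length(tree$nodes[[1]]$prototype)
  out <- matrix(NA_real_, n, q, dimnames = list(rownames(x), tree$node_names))
  recurse <- function(node_id, rows) {
    node <- tree$nodes[[node_id]]
    if (isTRUE(node$leaf)) {
      out[rows, ] <<- matrix(node$prototype, length(rows), q, byrow = TRUE)
      return(invisible())
    }
    go_left <- x[rows, node$feature] <= node$threshold
    if (any(go_left)) recurse(node$left, rows[go_left])
    if (any(!go_left)) recurse(node$right, rows[!go_left])
  }
  recurse(1, seq_len(n))
  out
}

#' Train a Random Forest of predictive clustering trees
#'
#' Each tree is grown on a bootstrap sample (with replacement, same n) with
#' a fresh random `mtry`-sized candidate-feature subset per tree node;
#' out-of-bag sample indices are recorded per tree. Deterministic under a
#' fixed seed.
#'
#' @param features Numeric matrix or data frame, samples x features. Missing
#'   values are mean-imputed (training means).
#' @param vectors Label matrix (see [label_matrix()]).
#' @param weights Node weights (see [node_weights()]).
#' @param n_trees Ensemble size (default 100).
#' @param mtry Candidate features per split (default `ceiling(sqrt(p))`).
#' @param min_leaf Minimum samples per leaf (default 2).
#' @param bootstrap Draw bootstrap samples (default TRUE); with FALSE every
#'   tree sees all samples.
#' @param seed Integer seed.
#' @return Object of class `pct_forest`.
#' @export
train_pct_forest <- function(features, vectors, weights,
                             n_trees = 100L, mtry = NULL, min_leaf = 2L,
                             bootstrap = TRUE, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  }
  y <- as.matrix(vectors)
  n <- nrow(x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(x)))
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  with_seed(seed, {
    for (b in seq_len(n_trees)) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      oob[[b]] <- setdiff(seq_len(n), idx)
      trees[[b]] <- grow_pct(x[idx, , drop = FALSE], y[idx, , drop = FALSE],
                             weights, min_leaf = min_leaf, mtry = mtry)
    }
  })
  structure(list(trees = trees, oob = oob, n_trees = n_trees, mtry = mtry,
                 min_leaf = min_leaf, weights = weights,
                 feature_names = colnames(x) %||% paste0("f", seq_len(ncol(x))),
                 node_names = colnames(y),
                 train_means = colMeans(x), seed = seed),
            class = "pct_forest")
}

#' @export
print.pct_forest <- function(x, ...) {
  cat(sprintf("<pct_forest> %d trees, mtry %d, %d features, %d label nodes\n",
              x$n_trees, x$mtry, length(x$feature_names),
              length(x$node_names)))
  invisible(x)
}

#' Predict hierarchy-node probabilities from a PCT forest
#'
#' The forest prediction is the arithmetic mean of the leaf prototypes of
#' its trees; since every prototype satisfies child <= parent, so does the
#' average.
#'
#' @param object A `pct_forest`.
#' @param newdata Numeric matrix/data frame of features (missing values
#'   imputed with training means).
#' @param trees Optional integer subset of trees to average (used for
#'   out-of-bag scoring).
#' @param ... Ignored.
#' @return Matrix samples x hierarchy nodes of probabilities in `[0, 1]`.
#' @export
predict.pct_forest <- function(object, newdata, trees = NULL, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- object$train_means[j]
    }
  }
  use <- trees %||% seq_len(object$n_trees)
  acc <- 0
  for (b in use) acc <- acc + predict_pct_tree(object$trees[[b]], x)
  acc / length(use)
}

#' Genie3 attribute importance from a PCT forest
#'
#' score(f) = (1/n_trees) * sum over every internal node splitting on f of
#' (samples at the node x variance reduction of the split). Features never
#' used by any tree score 0.
#'
#' @param forest A `pct_forest`.
#' @return Tibble `feature`, `genie3_score`, sorted descending.
#' @export
genie3_importance <- function(forest) {
  p <- length(forest$feature_names)
  score <- numeric(p)
  for (tree in forest$trees) {
    for (node in tree$nodes) {
      if (!isTRUE(node$leaf)) {
        score[node$feature] <- score[node$feature] + node$n * node$reduction
      }
    }
  }
  tibble::tibble(feature = forest$feature_names,
                 genie3_score = score / forest$n_trees) |>
    dplyr::arrange(dplyr::desc(.data$genie3_score))
}
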