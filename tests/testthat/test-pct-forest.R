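h <- diagnosis_hierarchy()
w <- node_weights(h)

test_that("weighted variance matches its closed form and a double-loop oracle", {
  y <- label_matrix(c("CD", "CD", "CD"), h)
  expect_equal(weighted_variance(y, w), 0)

  # two samples differing only at one depth-2 node (IBD on the CD vs
  # Infection paths they share HP/Subject? construct directly): vectors equal
  # everywhere except node "IBD" -> Var = w0^2 * 0.25
  v1 <- setNames(c(1, 1, 1, 0, 0, 0, 0, 0, 0), h$nodes)
  v2 <- v1; v2[["IBD"]] <- 1 - v1[["IBD"]]
  expect_equal(weighted_variance(rbind(v1, v2), w), 0.75^2 * 0.25)

  # brute-force oracle: Var(S) = (1/2n^2) sum_ij d^2(vi, vj)
  set.seed(17)
  for (rep in 1:5) {
    y <- matrix(runif(6 * 9), 6, 9, dimnames = list(NULL, h$nodes))
    d2 <- 0
    for (i in 1:6) for (j in 1:6) d2 <- d2 + sum(w * (y[i, ] - y[j, ])^2)
    expect_equal(weighted_variance(y, w), d2 / (2 * 36), tolerance = 1e-12)
  }
})

test_that("best split maximizes variance reduction (exhaustive oracle, small instances)", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    x <- matrix(round(runif(n * 3), 2), n, 3)
    y <- label_matrix(sample(c("CD", "UC", "NHC", "Tumor"), n, replace = TRUE), h)
    ours <- best_split(x, y, w)
    brute <- brute_best_split(x, y, w)
    if (is.null(brute)) {
      expect_null(ours)
    } else {
      expect_equal(ours$reduction, brute$reduction, tolerance = 1e-10)
    }
  }
})

test_that("a perfectly separating feature is chosen with reduction = Var(S)", {
  x <- cbind(sep = c(0, 0, 0, 1, 1, 1), noise = c(0.4, 0.1, 0.9, 0.3, 0.8, 0.2))
  y <- label_matrix(rep(c("NHC", "CD"), each = 3), h)
  sp <- best_split(x, y, w)
  expect_equal(sp$feature, 1)
  expect_equal(sp$reduction, weighted_variance(y, w), tolerance = 1e-12)

  # homogeneous labels: no split
  expect_null(best_split(x, label_matrix(rep("CD", 6), h), w))
})

test_that("tree growth handles homogeneous, XOR and memorization cases", {
  # homogeneous labels -> single-leaf tree with the shared prototype
  x <- matrix(runif(8), 4, 2)
  y <- label_matrix(rep("UC", 4), h)
  tr <- grow_pct(x, y, w)
  expect_length(tr$nodes, 1)
  expect_equal(tr$nodes[[1]]$prototype, label_vector("UC", h))

  # XOR labels on two binary features: depth-2 tree, zero leaf variance
  xx <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  yy <- label_matrix(c("NHC", "CD", "CD", "NHC"), h)
  tx <- grow_pct(xx, yy, w, min_leaf = 1)
  pred <- dysbiotyper:::predict_pct_tree(tx, xx)
  expect_equal(unname(pred), unname(yy), tolerance = 1e-12)

  # fully grown tree memorizes its training labels
  set.seed(3)
  xm <- matrix(runif(20 * 3), 20, 3)
  ym <- label_matrix(sample(c("CD", "UC", "Other", "NHC"), 20, replace = TRUE), h)
  tm <- grow_pct(xm, ym, w, min_leaf = 1)
  expect_equal(unname(dysbiotyper:::predict_pct_tree(tm, xm)), unname(ym),
               tolerance = 1e-12)
})

test_that("forests are deterministic and degenerate to a single tree", {
  set.seed(6)
  x <- matrix(runif(30 * 4), 30, 4)
  leaves <- sample(c("CD", "NHC", "Tumor"), 30, replace = TRUE)
  y <- label_matrix(leaves, h)

  f1 <- train_pct_forest(x, y, w, n_trees = 5, seed = 11)
  f2 <- train_pct_forest(x, y, w, n_trees = 5, seed = 11)
  expect_identical(predict(f1, x), predict(f2, x))

  # n_trees = 1, no bootstrap, mtry = p reproduces the plain PCT
  f0 <- train_pct_forest(x, y, w, n_trees = 1, mtry = 4, bootstrap = FALSE,
                         seed = 1)
  t0 <- grow_pct(x, y, w)
  expect_equal(predict(f0, x), dysbiotyper:::predict_pct_tree(t0, x),
               tolerance = 1e-12)
})

test_that("forest predictions are hierarchy-consistent and average tree prototypes", {
  set.seed(9)
  x <- matrix(runif(40 * 5), 40, 5)
  y <- label_matrix(sample(c("CD", "UC", "Infection", "NHC"), 40, replace = TRUE), h)
  f <- train_pct_forest(x, y, w, n_trees = 20, seed = 2)
  newx <- matrix(runif(200 * 5), 200, 5)
  pred <- predict(f, newx)
  expect_true(all(pred >= 0 & pred <= 1))
  for (node in setdiff(h$nodes, "Subject")) {
    expect_true(all(pred[, node] <= pred[, h$parent[[node]]] + 1e-12))
  }
  # 2-tree forest prediction is the hand average of its trees
  f2 <- train_pct_forest(x, y, w, n_trees = 2, seed = 3)
  byhand <- (dysbiotyper:::predict_pct_tree(f2$trees[[1]], newx) +
               dysbiotyper:::predict_pct_tree(f2$trees[[2]], newx)) / 2
  expect_equal(predict(f2, newx), byhand, tolerance = 1e-12)
})

test_that("separable data yields low out-of-bag error", {
  set.seed(14)
  n <- 200
  leaves <- sample(c("CD", "NHC", "Tumor"), n, replace = TRUE)
  x <- cbind(f1 = (leaves == "CD") + rnorm(n, 0, 0.05),
             f2 = (leaves == "Tumor") + rnorm(n, 0, 0.05),
             noise = runif(n))
  y <- label_matrix(leaves, h)
  f <- train_pct_forest(x, y, w, n_trees = 50, seed = 4)
  # score OOB and threshold at 0.5
  err <- 0; total <- 0
  for (i in seq_len(n)) {
    tb <- which(vapply(f$oob, function(o) i %in% o, logical(1)))
    if (length(tb) == 0) next
    p <- colMeans(do.call(rbind, lapply(tb, function(b)
      dysbiotyper:::predict_pct_tree(f$trees[[b]], x[i, , drop = FALSE])[1, ])))
    err <- err + sum((p >= 0.5) != (y[i, ] == 1))
    total <- total + length(p)
  }
  expect_lt(err / total, 0.1)
})

test_that("Genie3 importances satisfy definition, conservation and noise behavior", {
  set.seed(21)
  x <- cbind(sig = rep(c(0, 1), each = 10), noise = runif(20))
  y <- label_matrix(rep(c("NHC", "CD"), each = 10), h)
  # single tree, single split: score = n x reduction of that split
  f1 <- train_pct_forest(x, y, w, n_trees = 1, mtry = 2, bootstrap = FALSE, seed = 1)
  imp <- genie3_importance(f1)
  root_node <- f1$trees[[1]]$nodes[[1]]
  expect_equal(imp$genie3_score[imp$feature == "sig"],
               root_node$n * root_node$reduction)
  expect_equal(imp$genie3_score[imp$feature == "noise"], 0)

  # conservation: total score = mean over trees of sum(n x reduction)
  f <- train_pct_forest(matrix(runif(120), 30, 4),
                        label_matrix(sample(c("CD", "UC", "NHC"), 30, TRUE), h),
                        w, n_trees = 10, seed = 5)
  per_tree <- vapply(f$trees, function(tr)
    sum(vapply(tr$nodes, function(nd)
      if (isTRUE(nd$leaf)) 0 else nd$n * nd$reduction, numeric(1))), numeric(1))
  imp2 <- genie3_importance(f)
  expect_equal(sum(imp2$genie3_score), mean(per_tree), tolerance = 1e-10)
  expect_true(all(imp2$genie3_score >= 0))
})
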