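test_that("PR curve enumerates thresholds from the top and matches hand values", {
  curve <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(curve$recall, c(0.5, 0.5, 1.0, 1.0))
  expect_equal(curve$precision, c(1.0, 0.5, 2 / 3, 0.5))

  # perfect separation passes through (1, 1)
  perf <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(perf$recall == 1 & perf$precision == 1))

  # constant scores collapse to a single point (1, prevalence)
  const <- pr_curve(rep(0.5, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(nrow(const), 1)
  expect_equal(const$recall, 1)
  expect_equal(const$precision, 0.3)
  expect_error(pr_curve(c(1, 2), c(0, 0)), "no positive")
})

test_that("AUPRC matches closed forms and the dense-threshold oracle", {
  expect_equal(auprc(pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))), 1.0)
  expect_equal(auprc(pr_curve(rep(1, 10), c(rep(1, 4), rep(0, 6)))), 0.4)

  hand <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(auprc(hand), dense_auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               tolerance = 1e-9)
  set.seed(77)
  for (rep in 1:20) {
    s <- round(runif(15), 2)
    t <- rbinom(15, 1, 0.4)
    if (sum(t) == 0) t[1] <- 1
    expect_equal(auprc(pr_curve(s, t)), dense_auprc(s, t), tolerance = 1e-9)
  }
})

test_that("pooled micro-averaged curve satisfies identity and duplication invariance", {
  s <- c(0.9, 0.4, 0.6, 0.2); t <- c(1, 0, 1, 0)
  single <- pooled_pr(list(a = s), list(a = t))
  expect_equal(single$auprc_bar, auprc(pr_curve(s, t)))

  dup <- pooled_pr(list(a = s, b = s), list(a = t, b = t))
  expect_equal(dup$auprc_bar, single$auprc_bar, tolerance = 1e-12)

  # two-node toy with hand-counted pooled TP/FP at each threshold
  sa <- c(0.9, 0.1); ta <- c(1, 0)
  sb <- c(0.8, 0.9); tb <- c(0, 1)
  pooled <- pooled_pr(list(a = sa, b = sb), list(a = ta, b = tb))
  # thresholds 0.9: preds {a1, b2}: TP=2 FP=0 -> prec 1, rec 1
  expect_equal(pooled$curve$precision[1], 1)
  expect_equal(pooled$curve$recall[1], 1)
  expect_equal(pooled$auprc_bar, 1)

  # node ordering is irrelevant
  swapped <- pooled_pr(list(b = sb, a = sa), list(b = tb, a = ta))
  expect_equal(swapped$auprc_bar, pooled$auprc_bar)
})

test_that("leave-one-out protocol scores every sample exactly once", {
  set.seed(15)
  leaves <- rep(c("CD", "NHC", "Tumor"), each = 4)
  x <- cbind(f = (leaves == "CD") + rnorm(12, 0, 0.1),
             g = (leaves == "Tumor") + rnorm(12, 0, 0.1))
  rep_loo <- evaluate_hmc(x, leaves, protocol = "kfold", k = 12, n_trees = 5,
                          seed = 8)
  expect_equal(rep_loo$n, 12)
  expect_true(all(!is.na(rep_loo$scores)))
  expect_length(rep_loo$dropped_samples, 0)
})

test_that("informative features raise AUPRC over shuffled labels", {
  set.seed(25)
  n <- 90
  leaves <- sample(c("CD", "NHC", "Other"), n, replace = TRUE)
  x <- cbind(f = (leaves != "NHC") + rnorm(n, 0, 0.2), noise = runif(n))
  rep_inf <- evaluate_hmc(x, leaves, n_trees = 30, seed = 2)
  expect_gt(rep_inf$auprc_per_node[["HP"]], 0.9)

  # shuffled labels: per-node AUPRC near node prevalence
  x_shuf <- x[sample(n), ]
  rep_null <- evaluate_hmc(x_shuf, leaves, n_trees = 30, seed = 3)
  for (node in c("HP", "NHC")) {
    prev <- mean(rep_null$truth[, node])
    expect_lt(abs(rep_null$auprc_per_node[[node]] - prev), 0.15)
  }
})

test_that("delta AUPRC subtracts node-wise and enforces matching protocols", {
  set.seed(33)
  leaves <- rep(c("CD", "NHC"), each = 10)
  x <- cbind(f = rnorm(20))
  r1 <- evaluate_hmc(x, leaves, n_trees = 10, seed = 1)
  expect_equal(unname(delta_auprc(r1, r1)),
               rep(0, length(r1$auprc_per_node)))
  r2 <- evaluate_hmc(x, leaves, protocol = "kfold", k = 5, n_trees = 10, seed = 1)
  expect_error(delta_auprc(r1, r2), "protocol mismatch")
})

test_that("OOB and k-fold estimates agree on stable synthetic data", {
  set.seed(44)
  n <- 150
  leaves <- sample(c("CD", "NHC", "Tumor"), n, replace = TRUE)
  x <- cbind(f1 = (leaves == "CD") + rnorm(n, 0, 0.3),
             f2 = (leaves == "Tumor") + rnorm(n, 0, 0.3),
             f3 = runif(n))
  oob <- evaluate_hmc(x, leaves, protocol = "oob", n_trees = 40, seed = 6)
  kf <- evaluate_hmc(x, leaves, protocol = "kfold", k = 10, n_trees = 40, seed = 6)
  expect_lt(abs(oob$auprc_bar - kf$auprc_bar), 0.1)
})

test_that("tidiers return well-formed tibbles", {
  set.seed(50)
  leaves <- rep(c("CD", "NHC"), each = 8)
  x <- cbind(f = (leaves == "CD") + rnorm(16, 0, 0.2))
  r <- evaluate_hmc(x, leaves, n_trees = 10, seed = 1, feature_set = "HostOnly")
  td <- tidy(r)
  expect_true(all(c("node", "auprc", "feature_set") %in% names(td)))
  gl <- glance(r)
  expect_equal(gl$feature_set, "HostOnly")
  expect_true(gl$auprc_bar >= 0 && gl$auprc_bar <= 1)
})
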