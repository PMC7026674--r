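# Shared fixtures and independent oracles, all built in code.

# Tiny OTU table with explicit counts and a two-rank taxonomy.
toy_table <- function(counts = rbind(s1 = c(5, 3, 2), s2 = c(1, 1, 8)),
                      orders = c("A", "A", "B")) {
  colnames(counts) <- paste0("Otu", seq_len(ncol(counts)))
  otu_table(counts, tibble::tibble(
    otu_id = colnames(counts), kingdom = "Bacteria",
    order = orders, genus = colnames(counts)
  ))
}

# Random symmetric distance matrix with zero diagonal.
random_dist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
  d
}

# Two well-separated "blobs" in distance space.
blob_dist <- function(n1 = 4, n2 = 4, within = 0.1, between = 0.9, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  d <- matrix(between + runif(n * n, 0, 0.05), n, n)
  d <- (d + t(d)) / 2
  d[1:n1, 1:n1] <- within
  d[(n1 + 1):n, (n1 + 1):n] <- within
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
  d
}

# Exhaustive-minimum PAM cost over all C(N, k) medoid sets.
brute_pam_cost <- function(d, k) {
  n <- nrow(d)
  sets <- utils::combn(n, k)
  min(apply(sets, 2, function(med) sum(apply(d[, med, drop = FALSE], 1, min))))
}

# Exhaustive best split: enumerate every (feature, midpoint threshold) pair.
# Mirrors best_split() semantics: NULL iff labels homogeneous or no valid
# position; zero-reduction splits on impure nodes are returned.
brute_best_split <- function(x, y, w, min_leaf = 1) {
  n <- nrow(x)
  var_tot <- weighted_variance(y, w)
  if (var_tot <= 1e-15) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    for (thr in (vals[-length(vals)] + vals[-1]) / 2) {
      left <- x[, j] <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      red <- max(0, var_tot -
        (sum(left) / n) * weighted_variance(y[left, , drop = FALSE], w) -
        (sum(!left) / n) * weighted_variance(y[!left, , drop = FALSE], w))
      if (is.null(best) || red > best$reduction + 1e-12) {
        best <- list(feature = j, threshold = thr, reduction = red)
      }
    }
  }
  best
}

# Structured small instance: k tight blobs (metric, clearly clustered).
structured_dist <- function(n, k, seed) {
  set.seed(seed)
  centers <- matrix(runif(k * 2, 0, 10), k, 2)
  assign <- rep_len(seq_len(k), n)
  x <- centers[assign, ] + matrix(rnorm(n * 2, 0, 0.3), n, 2)
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
  d
}

# Dense-threshold numeric AUPRC oracle: trapezoid over a fine threshold grid.
dense_auprc <- function(scores, truth) {
  grid <- sort(unique(c(scores, scores - 1e-9, min(scores) - 1)), decreasing = TRUE)
  pts <- do.call(rbind, lapply(grid, function(t) {
    pred <- scores >= t
    if (sum(pred) == 0) return(NULL)
    c(recall = sum(pred & truth == 1) / sum(truth),
      precision = sum(pred & truth == 1) / sum(pred))
  }))
  r <- c(0, pts[, "recall"])
  p <- c(pts[1, "precision"], pts[, "precision"])
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

# Small metadata frame for exclusion tests.
make_meta <- function(n, hospitalized = FALSE) {
  tibble::tibble(
    subject_id = sprintf("x%03d", seq_len(n)),
    hospitalized = hospitalized,
    age = 50, gender = "F", antibiotic = FALSE
  )
}

# Reduced cohort for fast pipeline tests.
small_cohort_config <- function(seed = 1) {
  cohort_config(
    n_per_group = c(NHC = 30, CD = 5, UC = 6, Infection = 6, Tumor = 5, Other = 8),
    seed = seed
  )
}
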