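# Diversity, dissimilarity and permutation statistics.

#' Shannon diversity index (natural log)
#'
#' @param counts Non-negative vector of category counts (or a matrix; rows
#'   are samples).
#' @return H = -sum p_i ln p_i over nonzero entries, in nats.
#' @export
shannon_index <- function(counts) {
  if (is.matrix(counts)) return(apply(counts, 1, shannon_index))
  if (sum(counts) <= 0) abort("shannon_index: all-zero vector.")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y), computed with
#' [vegan::vegdist()].
#'
#' @param abund Non-negative matrix (samples x taxa) with positive row sums,
#'   or an [otu_table()].
#' @return Symmetric distance matrix with zero diagonal and sample-id dimnames.
#' @export
bray_curtis <- function(abund) {
  m <- if (inherits(abund, "otu_table")) abund$counts else as.matrix(abund)
  if (any(rowSums(m) <= 0)) abort("bray_curtis: zero-sum sample row.")
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0), all(is.finite(d)))
  d
}

as_dist_matrix <- function(dist) {
  d <- as.matrix(dist)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  stopifnot(nrow(d) == ncol(d))
  d
}

amova_F <- function(d2, groups) {
  N <- nrow(d2)
  k <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  (ss_among / (k - 1)) / (ss_within / (N - k))
}

#' Analysis of molecular variance (distance-based AMOVA)
#'
#' Partitions pairwise squared distances among vs within groups and assesses
#' the F-like ratio by permutation of group labels, with the +1 correction so
#' p is never exactly 0.
#'
#' @param dist Distance matrix (`dist` or square matrix).
#' @param groups Group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return Tibble with `statistic`, `p_value`, `n_permutations`, `seed`.
#' @export
amova <- function(dist, groups, n_perm = 999, seed = 1L) {
  d <- as_dist_matrix(dist)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  tab <- table(groups)
  if (length(tab) < 2) abort("amova: need >= 2 groups.")
  if (any(tab < 2)) abort("amova: singleton group.")
  d2 <- d^2
  f_obs <- amova_F(d2, groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      amova_F(d2, sample(groups)) >= f_obs, logical(1)))
  })
  tibble::tibble(statistic = f_obs, p_value = (exceed + 1) / (n_perm + 1),
                 n_permutations = n_perm, seed = seed)
}

#' Sequential PERMANOVA on a distance matrix
#'
#' Thin wrapper over [vegan::adonis2()] with sequential (Type I,
#' order-as-given) partitioning and free permutation of observations.
#'
#' @param dist Distance matrix or `dist`.
#' @param covariates Data frame of factors/numerics, one row per sample, in
#'   the order terms should enter the model.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble with one row per term: `term`, `statistic` (pseudo-F),
#'   `r_squared`, `p_value`, `n_permutations`, `seed`, plus a final
#'   `joint` row summing the term R-squareds.
#' @export
permanova <- function(dist, covariates, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(as_dist_matrix(dist))
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v)) < 2) abort(sprintf("permanova: constant covariate `%s`.", nm))
  }
  form <- stats::as.formula(paste("d ~", paste(names(covariates), collapse = " + ")))
  fit <- with_seed(seed, vegan::adonis2(form, data = covariates,
                                        permutations = n_perm, by = "terms"))
  terms_idx <- seq_len(nrow(fit) - 2)
  res <- tibble::tibble(
    term = rownames(fit)[terms_idx],
    statistic = fit$F[terms_idx],
    r_squared = fit$R2[terms_idx],
    p_value = fit$`Pr(>F)`[terms_idx],
    n_permutations = n_perm, seed = seed
  )
  dplyr::bind_rows(res, tibble::tibble(
    term = "joint", statistic = NA_real_, r_squared = sum(res$r_squared),
    p_value = NA_real_, n_permutations = n_perm, seed = seed
  ))
}

#' Permutation test of multivariate dispersion (medoid-based)
#'
#' Per-sample dispersion is the distance to the group medoid (the member
#' minimizing summed within-group distances). The statistic is the
#' difference of group mean dispersions for two groups, or the one-way
#' ANOVA F of dispersions for more; p by permutation of group labels.
#'
#' @inheritParams amova
#' @return Tibble with `statistic`, `p_value`, `n_permutations`, `seed`,
#'   plus `group_means` (list column of per-group mean dispersions).
#' @export
dispersion_test <- function(dist, groups, n_perm = 999, seed = 1L) {
  d <- as_dist_matrix(dist)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) abort("dispersion_test: need >= 2 groups.")
  if (any(tab < 2)) abort("dispersion_test: singleton group.")

  disp_stat <- function(g) {
    disp <- numeric(length(g))
    for (lev in unique(g)) {
      idx <- which(g == lev)
      med <- idx[which.min(colSums(d[idx, idx, drop = FALSE]))]
      disp[idx] <- d[idx, med]
    }
    means <- tapply(disp, g, mean)
    stat <- if (length(means) == 2) abs(diff(means)) else {
      summary(stats::aov(disp ~ factor(g)))[[1]]$`F value`[1]
    }
    list(stat = stat, means = means)
  }
  obs <- disp_stat(groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      disp_stat(sample(groups))$stat >= obs$stat, logical(1)))
  })
  tibble::tibble(statistic = unname(obs$stat),
                 p_value = (exceed + 1) / (n_perm + 1),
                 n_permutations = n_perm, seed = seed,
                 group_means = list(obs$means))
}

#' Pearson correlation with pairwise deletion of missing values
#'
#' @param x,y Numeric vectors of equal length; pairs with any `NA` are
#'   dropped (>= 3 complete pairs required).
#' @return Tibble with `r`, `p_value` (two-sided, t transform with n-2 df)
#'   and `n` (complete pairs used).
#' @export
pearson_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("pearson_corr: need >= 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("pearson_corr: zero variance.")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
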