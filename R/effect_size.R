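# LEfSe-style differential abundance: Kruskal-Wallis screen plus a
# bootstrapped linear-discriminant effect size on per-million abundances.
# This is a reimplementation of the algorithm's spirit, not a bit-compatible
# port: no subclass (Wilcoxon) stage is applied because the pipeline defines
# no subclasses.

#' Kruskal-Wallis rank test with all-tied guard
#'
#' Standard tie-corrected H with p from the chi-square distribution with
#' (k - 1) df. When every observation is identical the tie correction is
#' degenerate; H is then defined as 0 with p = 1.
#'
#' @param values Numeric vector.
#' @param classes Class label per value (>= 2 classes).
#' @return Tibble with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(values, classes) {
  classes <- factor(classes)
  if (nlevels(classes) < 2) abort("kruskal_wallis: need >= 2 classes.")
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, p_value = 1))
  }
  kt <- stats::kruskal.test(values, classes)
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value)
}

# One bootstrap round of the two-class discriminant effect size.
# Returns a per-feature effect: mean of (a) the between-class displacement
# along the (ridge-regularised) Fisher direction attributed to each feature
# and (b) the raw class-mean difference.
fisher_round_effect <- function(x, cls) {
  lv <- levels(cls)
  x1 <- x[cls == lv[1], , drop = FALSE]
  x2 <- x[cls == lv[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  sw <- ((nrow(x1) - 1) * stats::cov(x1) + (nrow(x2) - 1) * stats::cov(x2)) /
    (nrow(x1) + nrow(x2) - 2)
  eps <- max(1e-6 * mean(diag(sw)), 1e-12)
  w <- solve(sw + diag(eps, ncol(x)), m1 - m2)
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(m1 - m2)
  w_unit <- w / nw
  delta_proj <- sum(w_unit * (m1 - m2))
  (delta_proj * w_unit + (m1 - m2)) / 2
}

#' Bootstrapped linear-discriminant effect size (two classes)
#'
#' For each bootstrap round a fraction of samples per class is subsampled
#' without replacement and a one-dimensional Fisher discriminant (ridge
#' epsilon for stability) is fitted on all features jointly. The per-feature
#' effect in a round is the mean of the discriminant-attributed class-mean
#' difference and the raw class-mean difference; the final score is
#' log10(1 + mean absolute effect over rounds).
#'
#' @param abund_per_million Matrix samples x features, each row summing to 1e6.
#' @param classes Factor with exactly 2 levels, one per sample.
#' @param n_boot Bootstrap rounds (default 30).
#' @param boot_fraction Fraction of each class subsampled per round (default 2/3).
#' @param seed Integer seed.
#' @return Tibble with `feature`, `lda_score` (log10 scale, >= 0) and
#'   `direction` (+1 if the first class has the higher mean).
#' @export
lda_effect_size <- function(abund_per_million, classes, n_boot = 30,
                            boot_fraction = 2 / 3, seed = 1L) {
  x <- as.matrix(abund_per_million)
  cls <- factor(classes)
  if (nlevels(cls) != 2) abort("lda_effect_size: exactly 2 classes required.")
  if (any(table(cls) < 2)) abort("lda_effect_size: each class needs >= 2 samples.")
  idx_by_class <- split(seq_len(nrow(x)), cls)
  effects <- with_seed(seed, {
    rounds <- lapply(seq_len(n_boot), function(b) {
      sub <- unlist(lapply(idx_by_class, function(idx)
        sample(idx, max(2, ceiling(boot_fraction * length(idx))))))
      fisher_round_effect(x[sub, , drop = FALSE], cls[sub])
    })
    do.call(rbind, rounds)
  })
  mean_abs <- colMeans(abs(effects))
  raw_diff <- colMeans(x[cls == levels(cls)[1], , drop = FALSE]) -
    colMeans(x[cls == levels(cls)[2], , drop = FALSE])
  tibble::tibble(
    feature = colnames(x) %||% paste0("f", seq_along(mean_abs)),
    lda_score = unname(log10(1 + mean_abs)),
    direction = unname(sign(raw_diff))
  )
}

#' LEfSe-style differential abundance analysis
#'
#' Per-feature Kruskal-Wallis screen at `alpha`; surviving features are
#' scored by [lda_effect_size()] (one-vs-rest per class when there are more
#' than two classes, keeping each feature's maximum score). A feature passes
#' when its screen p-value is below `alpha` and its score reaches
#' `lda_cutoff`.
#'
#' @param relabund Relative-abundance matrix (rows are samples, rows sum to
#'   1) or an [otu_table()] of counts (converted internally).
#' @param classes Class label per sample.
#' @param alpha Kruskal-Wallis screening level (default 0.05).
#' @param lda_cutoff Minimum log10 effect size to call a feature (default 2).
#' @param n_boot,boot_fraction,seed Passed to [lda_effect_size()].
#' @return Tibble sorted by descending score: `feature`, `enriched_class`,
#'   `kw_p`, `lda_score`, `passes`.
#' @export
lefse <- function(relabund, classes, alpha = 0.05, lda_cutoff = 2.0,
                  n_boot = 30, boot_fraction = 2 / 3, seed = 1L) {
  if (inherits(relabund, "otu_table")) relabund <- relative_abundance(relabund)
  x <- as.matrix(relabund)
  cls <- factor(classes)
  if (nlevels(cls) < 2) abort("lefse: need >= 2 classes.")
  xpm <- x * 1e6

  kw <- purrr::map_dfr(seq_len(ncol(xpm)), function(j) {
    kruskal_wallis(xpm[, j], cls)
  })
  features <- colnames(xpm) %||% paste0("f", seq_len(ncol(xpm)))
  class_means <- vapply(levels(cls), function(lev)
    colMeans(xpm[cls == lev, , drop = FALSE]), numeric(ncol(xpm)))
  class_means <- matrix(class_means, ncol = nlevels(cls),
                        dimnames = list(features, levels(cls)))
  enriched <- levels(cls)[max.col(class_means, ties.method = "first")]

  survivors <- which(kw$p_value < alpha)
  scores <- rep(0, ncol(xpm))
  if (length(survivors) > 0) {
    xs <- xpm[, survivors, drop = FALSE]
    if (nlevels(cls) == 2) {
      es <- lda_effect_size(xs, cls, n_boot, boot_fraction, seed)
      scores[survivors] <- es$lda_score
    } else {
      per_class <- lapply(seq_len(nlevels(cls)), function(ci) {
        if (sum(cls == levels(cls)[ci]) < 2) return(rep(0, ncol(xs)))
        ovr <- factor(ifelse(cls == levels(cls)[ci], levels(cls)[ci], "rest"),
                      levels = c(levels(cls)[ci], "rest"))
        lda_effect_size(xs, ovr, n_boot, boot_fraction,
                        split_seed(seed, ci))$lda_score
      })
      scores[survivors] <- do.call(pmax, per_class)
    }
  }
  tibble::tibble(
    feature = features, enriched_class = enriched, kw_p = kw$p_value,
    lda_score = scores,
    passes = kw$p_value < alpha & scores >= lda_cutoff
  ) |>
    dplyr::arrange(dplyr::desc(.data$lda_score))
}
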