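# Partitioning around medoids (exact enumeration for small search spaces,
# deterministic Kaufman-Rousseeuw BUILD + SWAP otherwise), silhouette widths
# and silhouette-guided choice of k.

#' Partitioning around medoids
#'
#' Deterministic k-medoids minimising the total cost (sum of distances of
#' samples to their medoid). When the medoid search space is small
#' (`choose(N, k) <= exact_limit`) the optimal medoid set is found by
#' exhaustive enumeration; otherwise the classic greedy BUILD seeding plus
#' steepest-descent SWAP (medoid exchange until no swap lowers the cost) is
#' used. Both paths are seed-free: ties are broken by input order, so the
#' result depends only on the distance matrix.
#'
#' @param dist Distance matrix (`dist` or square symmetric matrix).
#' @param k Number of clusters, `2 <= k < N`.
#' @param exact_limit Largest number of candidate medoid sets for which the
#'   exhaustive search is used (default 10000); set to 0 to force BUILD+SWAP.
#' @return List of class `pam_result`: `k`, `medoid_ids`, `assignment`
#'   (integer cluster per sample, named), `total_cost`, `per_sample_silhouette`,
#'   `mean_silhouette`.
#' @export
pam_cluster <- function(dist, k, exact_limit = 10000) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (k < 2 || k >= n) abort("pam_cluster: need 2 <= k < number of samples.")

  if (choose(n, k) <= exact_limit) {
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2, function(med)
      sum(row_mins(d[, med, drop = FALSE])))
    medoids <- sets[, which.min(costs)]
    return(finish_pam(d, medoids, k))
  }

  # BUILD: greedy seeding.
  medoids <- which.min(colSums(d))
  dn1 <- d[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gains <- colSums(pmax(dn1 - d[, cand, drop = FALSE], 0))
    best <- cand[which.max(gains)]
    medoids <- c(medoids, best)
    dn1 <- pmin(dn1, d[, best])
  }

  # SWAP: steepest descent; total cost is monotone non-increasing.
  cost <- sum(dn1)
  repeat {
    best_delta <- 0; best_swap <- NULL
    for (mi in seq_along(medoids)) {
      m <- medoids[mi]
      others <- medoids[-mi]
      e <- if (length(others) == 1) d[, others] else
        apply(d[, others, drop = FALSE], 1, min)
      cand <- setdiff(seq_len(n), medoids)
      new_costs <- colSums(pmin(d[, cand, drop = FALSE], e))
      deltas <- new_costs - cost
      j <- which.min(deltas)
      if (deltas[j] < best_delta - 1e-12) {
        best_delta <- deltas[j]
        best_swap <- c(mi, cand[j])
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    dn1 <- apply(d[, medoids, drop = FALSE], 1, min)
    new_cost <- sum(dn1)
    stopifnot(new_cost <= cost + 1e-9)
    cost <- new_cost
  }

  finish_pam(d, medoids, k)
}

row_mins <- function(m) do.call(pmin, as.data.frame(m))

finish_pam <- function(d, medoids, k) {
  n <- nrow(d)
  medoids <- medoids[order(medoids)]
  assignment <- apply(d[, medoids, drop = FALSE], 1, which.min)
  names(assignment) <- rownames(d)
  sil <- silhouette_widths(d, assignment)
  structure(list(
    k = k, medoid_ids = rownames(d)[medoids], assignment = assignment,
    total_cost = sum(d[cbind(seq_len(n), medoids[assignment])]),
    per_sample_silhouette = sil$widths, mean_silhouette = sil$mean
  ), class = "pam_result")
}

#' @export
print.pam_result <- function(x, ...) {
  cat(sprintf("<pam_result> k = %d, total cost %.4f, mean silhouette %.3f\n",
              x$k, x$total_cost, x$mean_silhouette))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Silhouette widths for a clustering
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean distance to the
#' sample's own cluster (excluding itself) and b(i) the smallest mean
#' distance to any other cluster. Samples in singleton clusters get s = 0.
#'
#' @param dist Distance matrix.
#' @param assignment Integer/character cluster label per sample (>= 2 clusters).
#' @return List with `widths` (named numeric) and `mean`.
#' @export
silhouette_widths <- function(dist, assignment) {
  d <- as_dist_matrix(dist)
  cl <- as.integer(factor(assignment))
  if (length(unique(cl)) < 2) abort("silhouette_widths: need >= 2 clusters.")
  n <- nrow(d)
  sizes <- tabulate(cl)
  # mean distance from each sample to each cluster (including self in own)
  msum <- vapply(seq_len(max(cl)), function(g)
    rowSums(d[, cl == g, drop = FALSE]), numeric(n))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[own] == 1) { widths[i] <- 0; next }
    a <- msum[i, own] / (sizes[own] - 1)
    b <- min(msum[i, -own] / sizes[-own])
    widths[i] <- (b - a) / max(a, b)
  }
  names(widths) <- rownames(d)
  list(widths = widths, mean = mean(widths))
}

#' Choose k by mean silhouette
#'
#' Runs [pam_cluster()] for each k in `k_min:k_max` and returns the k with
#' the highest mean silhouette width (ties to the smaller k).
#'
#' @param dist Distance matrix.
#' @param k_min,k_max Range of k to scan (`k_max < N`).
#' @return List: `best_k`, `result` (the winning `pam_result`), `by_k`
#'   (tibble `k`, `mean_silhouette`, `total_cost`).
#' @export
select_k <- function(dist, k_min = 2, k_max = 10) {
  d <- as_dist_matrix(dist)
  if (k_max >= nrow(d)) abort("select_k: k_max must be < number of samples.")
  fits <- lapply(k_min:k_max, function(k) pam_cluster(d, k))
  by_k <- tibble::tibble(
    k = k_min:k_max,
    mean_silhouette = vapply(fits, `[[`, numeric(1), "mean_silhouette"),
    total_cost = vapply(fits, `[[`, numeric(1), "total_cost")
  )
  best <- which.max(by_k$mean_silhouette)
  list(best_k = by_k$k[best], result = fits[[best]], by_k = by_k)
}
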