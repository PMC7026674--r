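# End-to-end orchestration: simulate or load a cohort, preprocess, type the
# community (PAM on Bray-Curtis), characterize the resulting clusters, run
# the four-feature-set hierarchical-classification experiment, and bundle
# the results.

#' Configuration for the full analysis
#'
#' @param simulate If `TRUE`, generate the cohort from `cohort`; otherwise
#'   `input` must give paths.
#' @param cohort A [cohort_config()] used when `simulate = TRUE`.
#' @param input Named list of paths (`bact_shared`, `bact_taxonomy`,
#'   `fungi_shared`, `fungi_taxonomy`, `metadata`) when `simulate = FALSE`.
#' @param exclusion_rules Optional tibble of [exclusion_rule()] rows.
#' @param depth_bact,depth_fungi Rarefaction depths (reads/sample); defaults
#'   3000 and 1000.
#' @param rare_threshold Dataset-wide rare-OTU cutoff (fraction).
#' @param k_range `c(min, max)` clusters scanned by [select_k()].
#' @param lefse_alpha,lda_cutoff LEfSe screen level and score cutoff.
#' @param n_trees,w0,protocol Forest size, hierarchy weight base and
#'   evaluation protocol for [evaluate_hmc()].
#' @param seed Global seed; per-stage substreams are derived from it.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(simulate = TRUE, cohort = cohort_config(),
                            input = NULL, exclusion_rules = NULL,
                            depth_bact = 3000L, depth_fungi = 1000L,
                            rare_threshold = 1e-4, k_range = c(2L, 10L),
                            lefse_alpha = 0.05, lda_cutoff = 2,
                            n_trees = 100L, w0 = 0.75,
                            protocol = c("oob", "kfold"), seed = 1L) {
  protocol <- match.arg(protocol)
  if (simulate && !is.null(input)) {
    abort("exactly one of `simulate` or `input` may be active.")
  }
  if (!simulate && is.null(input)) abort("`input` paths required when simulate = FALSE.")
  structure(list(simulate = simulate, cohort = cohort, input = input,
                 exclusion_rules = exclusion_rules,
                 depth_bact = depth_bact, depth_fungi = depth_fungi,
                 rare_threshold = rare_threshold, k_range = k_range,
                 lefse_alpha = lefse_alpha, lda_cutoff = lda_cutoff,
                 n_trees = n_trees, w0 = w0, protocol = protocol,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 4294967291)
}

#' Chi-square test of proportion homogeneity across groups
#'
#' @param counts 2 x k matrix: first row "yes" counts, second row "no"
#'   counts, one column per group. Continuity correction is applied for
#'   2 x 2 tables.
#' @return List with `statistic`, `p_value`, `percentages` (per-column "yes"
#'   percentage, rounded half away from zero to 1 decimal) and
#'   `small_sample` flag (TRUE when any expected cell < 1; the test still
#'   runs).
#' @export
proportion_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("proportion_test: counts must be non-negative integers.")
  }
  if (any(colSums(counts) == 0)) abort("proportion_test: empty group column.")
  pct <- round_half_up(100 * counts[1, ] / colSums(counts), 1)
  if (ncol(counts) < 2 || nrow(counts) != 2) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                percentages = pct, small_sample = FALSE))
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = ncol(counts) == 2))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       percentages = pct, small_sample = any(expected < 1))
}

# Host-factor feature block: age numeric, gender/antibiotic as 0/1.
host_features <- function(metadata) {
  m <- cbind(age = metadata$age,
             gender_f = as.numeric(metadata$gender == "F"),
             antibiotic = as.numeric(metadata$antibiotic))
  rownames(m) <- metadata$subject_id
  m
}

#' Assemble a feature matrix for one feature set
#'
#' @param metadata Subject metadata (rows define sample order).
#' @param bact_rel,fungi_rel Relative-abundance matrices (rows = subjects).
#' @param feature_set One of `"HostOnly"`, `"HostBacteria"`, `"HostFungi"`,
#'   `"HostBoth"`.
#' @return Numeric matrix; microbial columns are prefixed `b_` / `f_`.
#' @export
assemble_features <- function(metadata, bact_rel = NULL, fungi_rel = NULL,
                              feature_set = c("HostOnly", "HostBacteria",
                                              "HostFungi", "HostBoth")) {
  feature_set <- match.arg(feature_set)
  x <- host_features(metadata)
  add <- function(x, block, prefix) {
    block <- block[metadata$subject_id, , drop = FALSE]
    colnames(block) <- paste0(prefix, colnames(block))
    cbind(x, block)
  }
  if (feature_set %in% c("HostBacteria", "HostBoth")) x <- add(x, bact_rel, "b_")
  if (feature_set %in% c("HostFungi", "HostBoth")) x <- add(x, fungi_rel, "f_")
  x
}

#' Run the full dysbiosis-typing and classification analysis
#'
#' Fixed stage order: subject exclusion, rare-OTU filtering, rarefaction,
#' Bray-Curtis distances, silhouette-guided PAM (with the largest cluster
#' split by hospitalization status for reporting), cluster characterization
#' (Shannon diversity, antibiotic proportions, inflammation markers, taxon
#' correlations), LEfSe contrasts, and the four-feature-set hierarchical
#' classification experiment with delta-AUPRC against the host-only
#' baseline and Genie3 attribute ranking. Rerunning with the same config is
#' bit-identical.
#'
#' @param config An [analysis_config()].
#' @return List of class `dysbiosis_report`; see the package vignette for
#'   the bundle contents.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed

  # Stage 1: data
  data <- if (config$simulate) {
    cc <- config$cohort; cc$seed <- seed
    generate_cohort(cc)
  } else {
    list(bact = read_shared(config$input$bact_shared, config$input$bact_taxonomy),
         fungi = read_shared(config$input$fungi_shared, config$input$fungi_taxonomy),
         metadata = read_metadata(config$input$metadata))
  }

  # Stage 2: exclusions
  excl <- exclude_subjects(data$metadata, config$exclusion_rules)
  meta <- excl$retained
  bact <- data$bact[rownames(data$bact$counts) %in% meta$subject_id, ]
  fungi <- data$fungi[rownames(data$fungi$counts) %in% meta$subject_id, ]

  # Stage 3: rare-OTU filter then rarefaction (fixed order)
  bact <- filter_rare_otus(bact, config$rare_threshold)
  fungi <- filter_rare_otus(fungi, config$rare_threshold)
  rb <- rarefy(bact, config$depth_bact, seed = split_seed(seed, 1, salt = 3L))
  rf <- rarefy(fungi, config$depth_fungi, seed = split_seed(seed, 2, salt = 3L))
  preprocessing <- list(exclusion_log = excl$log,
                        dropped_bact = rb$dropped, dropped_fungi = rf$dropped)
  bact <- rb$table; fungi <- rf$table
  meta <- meta[meta$subject_id %in% rownames(bact$counts), ]
  bact <- bact[meta$subject_id, ]

  # Stage 4: community typing on the bacterial Bray-Curtis matrix
  bact_rel <- relative_abundance(bact)
  d <- bray_curtis(bact_rel)
  sel <- select_k(d, config$k_range[1], config$k_range[2])
  weak_structure <- max(sel$by_k$mean_silhouette) < 0.3
  # relabel clusters by decreasing size: C1 is the largest
  sizes <- table(sel$result$assignment)
  relabel <- setNames(paste0("C", rank(-as.vector(sizes), ties.method = "first")),
                      names(sizes))
  cluster <- unname(relabel[as.character(sel$result$assignment)])
  meta$cluster <- cluster
  meta$cluster_group <- ifelse(meta$cluster == "C1",
                               ifelse(meta$hospitalized, "C1(HP)", "C1(NHC)"),
                               meta$cluster)

  # Stage 5: cluster characterization
  shannon <- shannon_index(bact$counts)
  grp <- meta$cluster_group
  kw_shannon <- kruskal_wallis(shannon, grp)
  pairs <- utils::combn(sort(unique(grp)), 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(pr) {
    sel_i <- grp %in% pr
    wt <- suppressWarnings(stats::wilcox.test(shannon[grp == pr[1]],
                                              shannon[grp == pr[2]]))
    tibble::tibble(group1 = pr[1], group2 = pr[2], p_value = wt$p.value)
  })
  pw$p_adj <- stats::p.adjust(pw$p_value, method = "BH")

  ab_tab <- vapply(sort(unique(grp)), function(g)
    c(sum(meta$antibiotic[grp == g]), sum(!meta$antibiotic[grp == g])),
    numeric(2))
  ab_test <- proportion_test(ab_tab)

  hp <- meta$hospitalized
  inflammation <- purrr::map_dfr(c("crp", "leukocytes", "neutrophils"), function(v) {
    ok <- hp & !is.na(meta[[v]])
    if (length(unique(meta$cluster_group[ok])) < 2) {
      return(tibble::tibble(marker = v, statistic = NA_real_, p_value = NA_real_))
    }
    kw <- kruskal_wallis(meta[[v]][ok], meta$cluster_group[ok])
    tibble::tibble(marker = v, statistic = kw$statistic, p_value = kw$p_value)
  })

  genus <- aggregate_taxa(bact, "genus")
  genus_rel <- relative_abundance(genus)
  ent <- if ("Enterococcus" %in% colnames(genus_rel)) genus_rel[, "Enterococcus"] else NULL
  corr_ent_crp <- if (!is.null(ent) && sum(hp & !is.na(meta$crp)) >= 3) {
    pearson_corr(ent[hp], meta$crp[hp])
  }
  orders <- relative_abundance(aggregate_taxa(bact, "order"))
  corr_orders <- if (all(c("Enterobacteriales", "Lactobacillales") %in% colnames(orders))) {
    pearson_corr(orders[, "Enterobacteriales"], orders[, "Lactobacillales"])
  }

  # Stage 6: LEfSe contrasts
  lefse_hp <- lefse(bact_rel, ifelse(hp, "HP", "NHC"),
                    alpha = config$lefse_alpha, lda_cutoff = config$lda_cutoff,
                    seed = split_seed(seed, 3, salt = 5L))
  lefse_clusters <- lefse(bact_rel, meta$cluster,
                          alpha = config$lefse_alpha,
                          lda_cutoff = config$lda_cutoff,
                          seed = split_seed(seed, 4, salt = 5L))

  # Stage 7: hierarchical classification over the four feature sets
  shared_ids <- intersect(meta$subject_id, rownames(fungi$counts))
  meta_h <- meta[meta$subject_id %in% shared_ids, ]
  fungi_rel <- relative_abundance(fungi[shared_ids, ])
  bact_rel_h <- bact_rel[shared_ids, , drop = FALSE]
  hier <- diagnosis_hierarchy()
  feature_sets <- c("HostOnly", "HostBacteria", "HostFungi", "HostBoth")
  reports <- lapply(feature_sets, function(fs) {
    evaluate_hmc(assemble_features(meta_h, bact_rel_h, fungi_rel, fs),
                 leaves = meta_h$diagnosis_leaf, hierarchy = hier,
                 feature_set = fs, protocol = config$protocol,
                 n_trees = config$n_trees, w0 = config$w0,
                 seed = split_seed(seed, match(fs, feature_sets), salt = 11L))
  })
  names(reports) <- feature_sets
  deltas <- lapply(reports[-1], delta_auprc, baseline = reports$HostOnly)
  genie3 <- if (!is.null(reports$HostBoth$forest)) {
    genie3_importance(reports$HostBoth$forest)
  }

  structure(list(
    seed = seed, config_hash = config_hash(config),
    preprocessing = preprocessing,
    clustering = list(select_k = sel$by_k, best_k = sel$best_k,
                      result = sel$result, weak_structure = weak_structure,
                      assignment = tibble::tibble(
                        subject_id = meta$subject_id,
                        cluster = meta$cluster,
                        cluster_group = meta$cluster_group)),
    cluster_stats = list(
      shannon = tibble::tibble(subject_id = meta$subject_id,
                               cluster_group = grp, shannon = shannon),
      shannon_kw = kw_shannon, shannon_pairwise = pw,
      antibiotic = list(percentages = ab_test$percentages,
                        statistic = ab_test$statistic,
                        p_value = ab_test$p_value,
                        significant = !is.na(ab_test$p_value) &&
                          ab_test$p_value < 0.05),
      inflammation = inflammation,
      corr_enterococcus_crp = corr_ent_crp,
      corr_enterobacteriales_lactobacillales = corr_orders),
    lefse = list(hp_vs_nhc = lefse_hp, clusters = lefse_clusters),
    hmc = list(reports = reports, delta_auprc = deltas, genie3 = genie3),
    metadata = meta
  ), class = "dysbiosis_report")
}

#' @export
print.dysbiosis_report <- function(x, ...) {
  cat("<dysbiosis_report>\n")
  cat(sprintf("  best k = %d (mean silhouette %.3f)%s\n",
              x$clustering$best_k, x$clustering$result$mean_silhouette,
              if (x$clustering$weak_structure) " [weak structure]" else ""))
  cat("  antibiotic % by cluster group:",
      paste(names(x$cluster_stats$antibiotic$percentages),
            x$cluster_stats$antibiotic$percentages, sep = "=", collapse = ", "),
      "\n")
  cat("  AUPRC-bar by feature set:",
      paste(names(x$hmc$reports),
            sprintf("%.3f", vapply(x$hmc$reports, `[[`, numeric(1), "auprc_bar")),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
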