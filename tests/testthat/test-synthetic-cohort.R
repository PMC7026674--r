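test_that("default cohort has one metadata record per subject and 283 subjects", {
  coh <- generate_cohort(cohort_config(seed = 3))
  expect_equal(nrow(coh$metadata), 283)
  expect_equal(nrow(coh$bact$counts), 283)
  expect_equal(nrow(coh$fungi$counts), 283)
  expect_equal(anyDuplicated(coh$metadata$subject_id), 0L)
  expect_equal(coh$metadata$hospitalized, coh$metadata$diagnosis_leaf != "NHC")
  # controls carry no inflammation markers; patients always do
  expect_true(all(is.na(coh$metadata$crp[!coh$metadata$hospitalized])))
  expect_true(all(!is.na(coh$metadata$crp[coh$metadata$hospitalized])))
  # counts sum to the drawn depth, inside the configured ranges
  expect_true(all(rowSums(coh$bact$counts) >= 3000 &
                    rowSums(coh$bact$counts) <= 10000))
  expect_true(all(rowSums(coh$fungi$counts) >= 900 &
                    rowSums(coh$fungi$counts) <= 4000))
  # all controls sit in the healthy-like state C1
  expect_true(all(coh$metadata$true_cluster[!coh$metadata$hospitalized] == "C1"))
})

test_that("fixed seed reproduces the cohort bit-exactly and extra subjects do not perturb earlier draws", {
  a <- generate_cohort(cohort_config(seed = 11))
  b <- generate_cohort(cohort_config(seed = 11))
  expect_identical(a$bact$counts, b$bact$counts)
  expect_identical(a$fungi$counts, b$fungi$counts)
  expect_identical(a$metadata, b$metadata)

  cfg_small <- cohort_config(n_per_group = c(NHC = 10), seed = 11)
  cfg_big <- cohort_config(n_per_group = c(NHC = 20), seed = 11)
  small <- generate_cohort(cfg_small)
  big <- generate_cohort(cfg_big)
  expect_identical(small$bact$counts, big$bact$counts[1:10, ])
})

test_that("unknown diagnosis leaf with nonzero count is a configuration error", {
  expect_error(cohort_config(n_per_group = c(NHC = 5, Mystery = 3)),
               "unknown diagnosis leaf")
})

test_that("antibiotic frequency per leaf is recovered within 3 binomial SDs", {
  cfg <- cohort_config(seed = 21)
  coh <- generate_cohort(cfg)
  for (leaf in names(cfg$n_per_group)) {
    n <- cfg$n_per_group[[leaf]]
    p <- cfg$antibiotic_prob[[leaf]]
    obs <- sum(coh$metadata$antibiotic[coh$metadata$diagnosis_leaf == leaf])
    expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9,
              label = sprintf("antibiotic count for %s", leaf))
  }
})

test_that("default effects rank Enterococcus C3 > C2 >= C1 and Enterobacteriaceae C2 > C1", {
  # clusters forced to be large so per-cluster means are stable (n >= 40 each)
  cfg <- cohort_config(
    n_per_group = c(CD = 30, UC = 30, Infection = 30, Tumor = 30, Other = 30),
    cluster_probs = list(antibiotic = c(C1 = 1, C2 = 1, C3 = 1) / 3,
                         no_antibiotic = c(C1 = 1, C2 = 1, C3 = 1) / 3),
    seed = 5
  )
  coh <- generate_cohort(cfg)
  rel <- relative_abundance(coh$bact)
  cl <- coh$metadata$true_cluster
  expect_true(all(table(cl) >= 40))
  ent <- tapply(rel[, "Enterococcus"], cl, mean)
  expect_gt(ent[["C3"]], ent[["C2"]])
  expect_gte(ent[["C2"]], ent[["C1"]])
  entero <- tapply(rel[, "Escherichia/Shigella"] + rel[, "Enterobacteriaceae_other"],
                   cl, mean)
  expect_gt(entero[["C2"]], entero[["C1"]])
})

test_that("zero effect matrices make the clusters compositionally exchangeable", {
  cfg <- cohort_config(
    n_per_group = c(CD = 20, UC = 20, Infection = 20),
    cluster_probs = list(antibiotic = c(C1 = 1, C2 = 1, C3 = 1) / 3,
                         no_antibiotic = c(C1 = 1, C2 = 1, C3 = 1) / 3),
    effect_bact = default_effects_bact(names(default_base_profile_bact())) * 0,
    seed = 9
  )
  coh <- generate_cohort(cfg)
  d <- bray_curtis(relative_abundance(coh$bact))
  cl <- coh$metadata$true_cluster
  same <- outer(cl, cl, "==")
  ut <- upper.tri(d)
  stat_obs <- mean(d[ut & !same]) - mean(d[ut & same])
  set.seed(1)
  perm <- replicate(499, {
    p <- sample(cl)
    sp <- outer(p, p, "==")
    mean(d[ut & !sp]) - mean(d[ut & sp])
  })
  p_val <- (sum(abs(perm) >= abs(stat_obs)) + 1) / 500
  expect_gt(p_val, 0.01)
})

test_that("sample_inflammation follows its linear model in the noise-free limit", {
  cfg <- cohort_config(crp_model = c(intercept = 4, slope = 0, sd = 0))
  r <- sample_inflammation(0.7, "C1", cfg)
  expect_equal(r[["crp"]], 4)

  cfg2 <- cohort_config(crp_model = c(intercept = 4, slope = 10, sd = 0))
  expect_equal(sample_inflammation(1, "C1", cfg2)[["crp"]], 14)
  expect_equal(sample_inflammation(0, "C1", cfg2)[["crp"]], 4)

  # the C3 shift applies only to C3 subjects
  cfg3 <- cohort_config(leuko_model = c(baseline = 6, c3_shift = 5, sd = 0),
                        neutro_model = c(baseline = 4, c3_shift = 3, sd = 0))
  expect_equal(sample_inflammation(0.1, "C3", cfg3)[["leukocytes"]], 11)
  expect_equal(sample_inflammation(0.1, "C1", cfg3)[["leukocytes"]], 6)
})
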