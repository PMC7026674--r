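test_that("first-match exclusion reproduces disjoint criterion counts (197 -> 162)", {
  # 197 control records engineered so the seven criteria match 6,2,1,6,13,1,6
  # subjects respectively (disjoint by first-match accounting).
  meta <- make_meta(197)
  meta$missing_info <- FALSE
  meta$age <- 50
  meta$surgery_3mo <- FALSE
  meta$hospitalized_3mo <- FALSE
  meta$gi_infection_3mo <- FALSE
  meta$ibd <- FALSE
  meta$low_reads <- FALSE
  meta$missing_info[1:6] <- TRUE
  meta$age[7:8] <- 85
  meta$surgery_3mo[9] <- TRUE
  meta$hospitalized_3mo[10:15] <- TRUE
  meta$gi_infection_3mo[16:28] <- TRUE
  meta$ibd[29] <- TRUE
  meta$low_reads[30:35] <- TRUE
  # overlap: subject 7 also flagged low_reads; first-match keeps it under age
  meta$low_reads[7] <- TRUE

  rules <- dplyr::bind_rows(
    exclusion_rule("missing information", "missing_info", "is_true"),
    exclusion_rule("age over 80", "age", "gt", 80),
    exclusion_rule("recent GI surgery", "surgery_3mo", "is_true"),
    exclusion_rule("recently hospitalized", "hospitalized_3mo", "is_true"),
    exclusion_rule("recent GI infection", "gi_infection_3mo", "is_true"),
    exclusion_rule("diagnosed IBD", "ibd", "is_true"),
    exclusion_rule("insufficient reads", "low_reads", "is_true")
  )
  res <- exclude_subjects(meta, rules)
  expect_equal(nrow(res$retained), 162)
  expect_equal(res$log$n_excluded, c(6L, 2L, 1L, 6L, 13L, 1L, 6L))
  expect_equal(sum(res$log$n_excluded), 197 - nrow(res$retained))
})

test_that("empty rule list retains everyone; unknown field errors", {
  meta <- make_meta(5)
  res <- exclude_subjects(meta, NULL)
  expect_equal(nrow(res$retained), 5)
  expect_equal(nrow(res$log), 0)
  expect_error(
    exclude_subjects(meta, exclusion_rule("bad", "no_such_field", "gt", 1)),
    "unknown metadata field")
})

test_that("rare-OTU filter uses a strict dataset-wide threshold", {
  # OTU2 and OTU3 have 1 read each; grand total 10,000 puts them exactly at
  # 0.01% -> retained ("less than" is strict)
  tab <- toy_table(rbind(s1 = c(9990, 1, 1), s2 = c(8, 0, 0)))
  expect_equal(ncol(filter_rare_otus(tab)$counts), 3)
  # doubling the grand total pushes them below the threshold -> removed
  tab2 <- toy_table(rbind(s1 = c(19990, 1, 1), s2 = c(8, 0, 0)))
  expect_equal(colnames(filter_rare_otus(tab2)$counts), "Otu1")
  # nothing near the threshold: identity
  tab3 <- toy_table(rbind(s1 = c(50, 30, 20), s2 = c(10, 10, 10)))
  expect_identical(filter_rare_otus(tab3)$counts, tab3$counts)
})

test_that("rarefaction drops shallow samples and conserves depth exactly", {
  tab <- toy_table(rbind(s1 = c(600, 400, 0), s2 = c(100, 50, 49),
                         s3 = c(300, 100, 100)))
  res <- rarefy(tab, depth = 500, seed = 4)
  expect_equal(res$dropped, "s2")
  expect_true(all(rowSums(res$table$counts) == 500))
  # a sample already at the target depth comes back unchanged
  expect_equal(res$table$counts["s3", ], tab$counts["s3", ])
  # deterministic under a fixed seed
  res2 <- rarefy(tab, depth = 500, seed = 4)
  expect_identical(res$table$counts, res2$table$counts)
})

test_that("rarefaction matches hypergeometric moments (without replacement)", {
  tab <- toy_table(rbind(s1 = c(600, 400, 0)))
  n_rep <- 2000
  draws <- vapply(seq_len(n_rep), function(s)
    rarefy(tab, 500, seed = s)$table$counts[1, 1], numeric(1))
  mu <- 500 * 0.6                                  # 300
  sd_hyper <- sqrt(500 * 0.6 * 0.4 * (1000 - 500) / 999)
  expect_lt(abs(mean(draws) - mu), 3 * sd_hyper / sqrt(n_rep))
  # a with-replacement scheme would have variance 500*.6*.4, ~2x larger
  expect_lt(var(draws), 500 * 0.6 * 0.4 * 0.75)
})

test_that("relative abundance rows sum to one and match the counts/rowsum oracle", {
  expect_equal(relative_abundance(rbind(a = c(3, 1, 0)))[1, ],
               c(0.75, 0.25, 0), ignore_attr = TRUE)
  set.seed(2)
  m <- matrix(rpois(60, 5) + 1, 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
  rel <- relative_abundance(m)
  expect_equal(rowSums(rel), rep(1, 6), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rel, m / rowSums(m), tolerance = 1e-15)
  expect_error(relative_abundance(rbind(c(0, 0))), "zero-sum")
})

test_that("taxonomic aggregation sums counts by rank and conserves row totals", {
  tab <- toy_table(rbind(s1 = c(5, 3, 2), s2 = c(1, 1, 8)),
                   orders = c("A", "A", "B"))
  agg <- aggregate_taxa(tab, "order")
  expect_equal(sort(colnames(agg$counts)), c("A", "B"))
  expect_equal(agg$counts[, "A"], c(s1 = 8, s2 = 2))
  expect_equal(agg$counts[, "B"], c(s1 = 2, s2 = 8))
  expect_equal(rowSums(agg$counts), rowSums(tab$counts))
  # unclassified-at-rank OTUs pool into "unclassified"
  tab2 <- toy_table(orders = c("A", NA, "B"))
  agg2 <- aggregate_taxa(tab2, "order")
  expect_true("unclassified" %in% colnames(agg2$counts))
})
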