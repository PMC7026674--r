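# Preprocessing: subject exclusion, rare-OTU filtering, rarefaction,
# relative abundance, taxonomic aggregation.

#' Build an exclusion rule table
#'
#' @param name Rule label used in the exclusion log.
#' @param field Metadata column the rule tests.
#' @param comparator One of `"gt"`, `"ge"`, `"lt"`, `"le"`, `"eq"`, `"ne"`,
#'   `"is_true"`, `"is_na"`.
#' @param value Comparison value (ignored for `is_true` / `is_na`).
#' @param applies_to `"HP"`, `"NHC"` or `"both"`: which arm of the cohort the
#'   rule is tested on.
#' @return One-row tibble; bind rows to form a rule list.
#' @export
exclusion_rule <- function(name, field, comparator, value = NA,
                           applies_to = c("both", "HP", "NHC")) {
  applies_to <- match.arg(applies_to)
  tibble::tibble(name = name, field = field, comparator = comparator,
                 value = list(value), applies_to = applies_to)
}

rule_matches <- function(meta, field, comparator, value) {
  if (!field %in% names(meta)) {
    abort(sprintf("exclusion rule references unknown metadata field `%s`.", field))
  }
  x <- meta[[field]]
  out <- switch(comparator,
    gt = x > value, ge = x >= value, lt = x < value, le = x <= value,
    eq = x == value, ne = x != value,
    is_true = isTRUE_vec(x), is_na = is.na(x),
    abort(sprintf("unknown comparator `%s`.", comparator))
  )
  out & !is.na(out)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Exclude subjects by a first-match rule list
#'
#' Each subject is excluded by the first rule it matches (rules are tested in
#' list order), so the exclusion log counts are disjoint and always sum to
#' the number of removed subjects.
#'
#' @param metadata Tibble with one row per subject; must contain
#'   `hospitalized` if any rule restricts its arm.
#' @param rules Tibble of [exclusion_rule()] rows (possibly empty).
#' @return List with `retained` (tibble) and `log` (tibble `rule`, `n_excluded`).
#' @export
exclude_subjects <- function(metadata, rules = NULL) {
  metadata <- tibble::as_tibble(metadata)
  if (is.null(rules) || nrow(rules) == 0) {
    return(list(retained = metadata,
                log = tibble::tibble(rule = character(), n_excluded = integer())))
  }
  excluded_by <- rep(NA_character_, nrow(metadata))
  for (r in seq_len(nrow(rules))) {
    hit <- rule_matches(metadata, rules$field[r], rules$comparator[r],
                        rules$value[[r]])
    if (rules$applies_to[r] != "both") {
      arm <- if (rules$applies_to[r] == "HP") metadata$hospitalized else !metadata$hospitalized
      hit <- hit & arm
    }
    hit <- hit & is.na(excluded_by)
    excluded_by[hit] <- rules$name[r]
  }
  log <- tibble::tibble(rule = rules$name) |>
    dplyr::mutate(n_excluded = vapply(.data$rule, function(nm)
      sum(excluded_by == nm, na.rm = TRUE), integer(1), USE.NAMES = FALSE))
  list(retained = metadata[is.na(excluded_by), ], log = log)
}

#' Remove globally rare OTUs
#'
#' Drops every OTU whose total count across all samples is strictly below
#' `threshold` as a fraction of the table's grand total (default 0.01%).
#' An OTU sitting exactly at the threshold is retained.
#'
#' @param table An [otu_table()].
#' @param threshold Dataset-wide relative-abundance cutoff (fraction).
#' @return Filtered [otu_table()]; sample rows are preserved.
#' @export
filter_rare_otus <- function(table, threshold = 1e-4) {
  stopifnot(inherits(table, "otu_table"))
  grand <- sum(table$counts)
  if (grand == 0) abort("cannot filter an all-zero table.")
  keep <- colSums(table$counts) / grand >= threshold
  table[, keep]
}

#' Rarefy samples to a common depth
#'
#' Each sample with at least `depth` reads is subsampled WITHOUT replacement
#' down to exactly `depth`; shallower samples are dropped and reported.
#'
#' @param table An [otu_table()].
#' @param depth Target depth (reads per sample).
#' @param seed Integer seed; fixed seed gives a deterministic subsample.
#' @return List with `table` (rarefied [otu_table()]) and `dropped`
#'   (character vector of removed sample ids).
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "otu_table"), depth >= 1)
  totals <- rowSums(table$counts)
  dropped <- rownames(table$counts)[totals < depth]
  kept <- table[totals >= depth, ]
  out <- with_seed(seed, {
    t(apply(kept$counts, 1, function(row) {
      if (sum(row) == depth) return(row)
      reads <- sample(rep.int(seq_along(row), row), depth)
      tabulate(reads, nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(kept$counts)
  list(table = otu_table(out, kept$taxonomy), dropped = dropped)
}

#' Convert counts to relative abundances
#'
#' @param table An [otu_table()] or a non-negative matrix with positive row sums.
#' @return Matrix of fractions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  rs <- rowSums(m)
  if (any(rs <= 0)) abort("relative_abundance: zero-sum sample row.")
  sweep(m, 1, rs, "/")
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Sums counts over OTUs sharing the same label at `rank`; OTUs unclassified
#' at that rank are pooled into `"unclassified"`.
#'
#' @param table An [otu_table()] with taxonomy.
#' @param rank Rank column name in the taxonomy (e.g. `"order"`).
#' @return An [otu_table()] with one column per rank label (taxonomy dropped).
#' @export
aggregate_taxa <- function(table, rank) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(table$taxonomy) || !rank %in% names(table$taxonomy)) {
    abort(sprintf("rank `%s` not present in taxonomy.", rank))
  }
  labels <- table$taxonomy[[rank]][match(colnames(table$counts), table$taxonomy$otu_id)]
  labels[is.na(labels) | labels == ""] <- "unclassified"
  groups <- unique(labels)
  agg <- vapply(groups, function(g)
    rowSums(table$counts[, labels == g, drop = FALSE]), numeric(nrow(table$counts)))
  agg <- matrix(agg, nrow = nrow(table$counts),
                dimnames = list(rownames(table$counts), groups))
  otu_table(agg, NULL)
}
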