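# Reading and writing the field's plain-text formats: mothur-style shared
# count tables, taxonomy with rank prefixes, metadata TSV, distance
# matrices, and the declarative cohort-config file.

RANK_PREFIXES <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g")

#' Write an OTU table as a mothur-style shared file
#'
#' Columns `label`, `Group`, `numOtus`, then one count column per OTU.
#'
#' @param table An [otu_table()].
#' @param path Output path.
#' @param label Value of the `label` column (OTU-definition tag).
#' @export
write_shared <- function(table, path, label = "0.03") {
  df <- tibble::tibble(label = label, Group = rownames(table$counts),
                       numOtus = ncol(table$counts))
  df <- dplyr::bind_cols(df, tibble::as_tibble(table$counts))
  readr::write_tsv(df, path)
}

#' Read a mothur-style shared file
#'
#' @param path Shared TSV path.
#' @param taxonomy Optional taxonomy tibble (or path to one) to attach.
#' @return An [otu_table()].
#' @export
read_shared <- function(path, taxonomy = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("label", "Group", "numOtus"))])
  rownames(counts) <- df$Group
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  otu_table(counts, taxonomy)
}

#' Write taxonomy with rank prefixes
#'
#' Lineages are serialized as `k__Bacteria;o__Clostridiales;g__Blautia;`
#' with empty ranks skipped.
#'
#' @param taxonomy Tibble with `otu_id` plus rank columns.
#' @param path Output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  ranks <- intersect(names(RANK_PREFIXES), names(taxonomy))
  lineage <- apply(taxonomy[ranks], 1, function(row) {
    ok <- !is.na(row) & row != ""
    paste0(RANK_PREFIXES[ranks][ok], "__", row[ok], ";", collapse = "")
  })
  readr::write_tsv(tibble::tibble(OTU = taxonomy$otu_id, Taxonomy = lineage), path)
}

#' Read a rank-prefixed taxonomy file
#' @param path Taxonomy TSV (`OTU`, `Taxonomy`).
#' @return Tibble `otu_id` plus one column per rank found.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  rank_names <- names(RANK_PREFIXES)
  rows <- lapply(df$Taxonomy, function(s) {
    toks <- strsplit(gsub(";$", "", s), ";", fixed = TRUE)[[1]]
    out <- setNames(rep(NA_character_, length(rank_names)), rank_names)
    for (tok in toks) {
      m <- regmatches(tok, regexec("^([a-z])__(.*)$", tok))[[1]]
      if (length(m) == 3) {
        rank <- names(RANK_PREFIXES)[RANK_PREFIXES == m[2]]
        if (length(rank) == 1) out[rank] <- m[3]
      }
    }
    out
  })
  dplyr::bind_cols(tibble::tibble(otu_id = df$OTU),
                   tibble::as_tibble(do.call(rbind, rows)))
}

#' Write / read subject metadata TSV
#'
#' Missing numeric fields are written as `NA`.
#' @param metadata Tibble of subject metadata.
#' @param path File path.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, na = "NA")
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a distance matrix
#'
#' `format = "square"` writes a TSV with sample ids in the first column;
#' `format = "phylip"` writes the lower-triangle phylip-style file (count of
#' samples on the first line).
#'
#' @param d Square distance matrix with dimnames.
#' @param path Output path.
#' @param format `"square"` or `"phylip"`.
#' @export
write_dist <- function(d, path, format = c("square", "phylip")) {
  format <- match.arg(format)
  d <- as_dist_matrix(d)
  if (format == "square") {
    df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(d)),
                           tibble::as_tibble(d))
    readr::write_tsv(df, path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(as.character(nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(c(rownames(d)[i],
                         if (i > 1) format(d[i, 1:(i - 1)], digits = 10)),
                       collapse = "\t"), con)
    }
  }
}

#' Read a square distance-matrix TSV written by [write_dist()]
#' @param path Input path.
#' @return Square matrix with dimnames.
#' @export
read_dist <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Read a cohort configuration from a YAML file
#'
#' Any key present in the file overrides the corresponding
#' [cohort_config()] default; nested tables (e.g. `age_mean_sd`) map to
#' named lists.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading config files requires the `yaml` package.")
  }
  raw <- yaml::read_yaml(path)
  args <- list()
  simple <- intersect(names(raw), c("overdispersion", "seed"))
  for (nm in simple) args[[nm]] <- raw[[nm]]
  for (nm in intersect(names(raw), c("n_per_group", "antibiotic_prob",
                                     "female_prob", "base_profile_bact",
                                     "base_profile_fungi", "crp_model",
                                     "leuko_model", "neutro_model",
                                     "depth_range_bact", "depth_range_fungi"))) {
    args[[nm]] <- unlist(raw[[nm]])
  }
  if ("age_mean_sd" %in% names(raw)) {
    args$age_mean_sd <- lapply(raw$age_mean_sd, unlist)
  }
  if ("cluster_probs" %in% names(raw)) {
    args$cluster_probs <- lapply(raw$cluster_probs, unlist)
  }
  do.call(cohort_config, args)
}
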