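#' Construct an OTU count table
#'
#' The central community container: a non-negative integer count matrix
#' (samples in rows, OTUs in columns) plus a taxonomy table mapping each OTU
#' to an ordered lineage.
#'
#' @param counts Integer matrix, samples x OTUs, with row and column names.
#' @param taxonomy Data frame with a column `otu_id` and one column per rank
#'   (e.g. `kingdom`, `phylum`, `class`, `order`, `family`, `genus`). May
#'   contain `NA` for unclassified ranks. Optional (`NULL` allowed).
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have sample ids as rownames and OTU ids as colnames.")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("duplicate sample or OTU ids in `counts`.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    if (!"otu_id" %in% names(taxonomy)) {
      abort("`taxonomy` must have an `otu_id` column.")
    }
    missing <- setdiff(colnames(counts), taxonomy$otu_id)
    if (length(missing) > 0) {
      abort(sprintf("taxonomy missing for %d OTUs (e.g. %s).",
                    length(missing), missing[1]))
    }
    taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), ]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$taxonomy)) {
    ranks <- setdiff(names(x$taxonomy), "otu_id")
    cat("  taxonomy ranks:", paste(ranks, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample ids of an OTU table
#' @param x An `otu_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' OTU ids of an OTU table
#' @param x An `otu_table`.
#' @return Character vector of OTU ids.
#' @export
otu_ids <- function(x) colnames(x$counts)

#' Subset an OTU table by sample and/or OTU ids
#' @param x An `otu_table`.
#' @param i,j Sample / OTU selector (ids or indices).
#' @param ... Ignored.
#' @export
`[.otu_table` <- function(x, i, j, ...) {
  counts <- x$counts[i, j, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[match(colnames(counts), tax$otu_id), ]
  otu_table(counts, tax)
}

#' Tidy a count table into long format
#'
#' @param x An `otu_table`.
#' @param ... Ignored.
#' @return Tibble with columns `sample_id`, `otu_id`, `count` and any
#'   taxonomy ranks.
#' @importFrom tibble as_tibble
#' @export
as_tibble.otu_table <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(rownames(x$counts), times = ncol(x$counts)),
    otu_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
  if (!is.null(x$taxonomy)) long <- dplyr::left_join(long, x$taxonomy, by = "otu_id")
  long
}
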