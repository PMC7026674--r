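# Diagnosis label hierarchy and hierarchy-consistent label vectors.

#' Build a label hierarchy from slash-delimited paths
#'
#' @param paths Character vector of root-to-leaf paths, e.g.
#'   `"Subject/HP/IBD/CD"`. All paths must share the same root token and a
#'   node may have only one parent (the hierarchy is a tree).
#' @return List of class `label_hierarchy`: `nodes` (first-seen order),
#'   `parent` (named, `NA` for the root), `depth` (named, root = 0).
#' @export
build_hierarchy <- function(paths) {
  parent <- character(0)
  nodes <- character(0)
  for (p in paths) {
    toks <- strsplit(p, "/", fixed = TRUE)[[1]]
    for (i in seq_along(toks)) {
      node <- toks[i]
      par <- if (i == 1) NA_character_ else toks[i - 1]
      if (!node %in% nodes) {
        nodes <- c(nodes, node)
        parent[node] <- par
      } else if (!identical(parent[[node]], par)) {
        abort(sprintf("node `%s` has conflicting parents (`%s` vs `%s`).",
                      node, parent[[node]], par))
      }
    }
  }
  if (sum(is.na(parent)) != 1) abort("hierarchy must have exactly one root.")
  depth <- setNames(integer(length(nodes)), nodes)
  for (node in nodes) {
    d <- 0L; cur <- node
    while (!is.na(parent[[cur]])) { cur <- parent[[cur]]; d <- d + 1L }
    depth[node] <- d
  }
  structure(list(nodes = nodes, parent = parent[nodes], depth = depth),
            class = "label_hierarchy")
}

#' Default diagnosis hierarchy
#'
#' Subject -> \{NHC, HP\}; HP -> \{IBD, Infection, Tumor, Other\};
#' IBD -> \{CD, UC\}.
#' @return A `label_hierarchy` with 9 nodes.
#' @export
diagnosis_hierarchy <- function() {
  build_hierarchy(c("Subject/NHC", "Subject/HP/IBD/CD", "Subject/HP/IBD/UC",
                    "Subject/HP/Infection", "Subject/HP/Tumor",
                    "Subject/HP/Other"))
}

hierarchy_root <- function(h) h$nodes[is.na(h$parent)]

#' Binary label vector for a leaf
#'
#' 1 on every node of the root-to-leaf path, 0 elsewhere, so a sample
#' labelled `CD` is positive at `Subject`, `HP`, `IBD` and `CD`.
#'
#' @param leaf A node name in the hierarchy.
#' @param h A [build_hierarchy()] result.
#' @return Named 0/1 vector over `h$nodes`.
#' @export
label_vector <- function(leaf, h) {
  if (!leaf %in% h$nodes) abort(sprintf("unknown hierarchy node `%s`.", leaf))
  v <- setNames(numeric(length(h$nodes)), h$nodes)
  cur <- leaf
  while (!is.na(cur)) { v[cur] <- 1; cur <- h$parent[[cur]] }
  v
}

#' Label matrix for a vector of leaves
#' @param leaves Character vector of leaf labels.
#' @param h A `label_hierarchy`.
#' @return Numeric matrix, samples x nodes.
#' @export
label_matrix <- function(leaves, h) {
  t(vapply(leaves, label_vector, numeric(length(h$nodes)), h = h))
}

#' Depth-exponential node weights
#'
#' w(node) = w0^depth(node), so the root has weight 1 and mistakes deeper in
#' the hierarchy count for less in the tree-growing variance.
#'
#' @param h A `label_hierarchy`.
#' @param w0 Base weight in (0, 1]; default 0.75.
#' @return Named positive vector over `h$nodes`.
#' @export
node_weights <- function(h, w0 = 0.75) {
  setNames(w0^h$depth, h$nodes)
}
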