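#' Create an empty taxonomy tree
#'
#' A taxonomy tree accumulates the lineages of successively queried taxa
#' (the "session memory" of an interactive taxon search): merging a second
#' lineage that shares ancestors with the first produces a bifurcation at the
#' deepest shared node.
#'
#' @return Object of class `taxonomy_tree` with empty `nodes`, `children` and
#'   `queried_ids`.
#' @export
taxonomy_tree <- function() {
  structure(
    list(nodes = empty_records(), children = list(), queried_ids = character()),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy tree: %d nodes, %d queried taxa>\n",
              nrow(x$nodes), length(x$queried_ids)))
  invisible(x)
}

#' Merge a lineage into a taxonomy tree
#'
#' Takes the union of the node sets and parent/child edges; the queried taxon
#' (last entry of the lineage) is recorded in `queried_ids`. Merging is
#' idempotent and order-independent. A lineage asserting a different parent
#' for a node already in the tree signals mixed backbones and is an error.
#'
#' @param tree A `taxonomy_tree`.
#' @param lin A `lineage` from [lineage()].
#' @return The updated `taxonomy_tree`.
#' @export
merge_lineage <- function(tree, lin) {
  stopifnot(inherits(tree, "taxonomy_tree"), inherits(lin, "lineage"))
  nodes <- tree$nodes
  children <- tree$children
  for (i in seq_len(nrow(lin))) {
    id <- lin$taxon_id[i]
    if (id %in% nodes$taxon_id) {
      if (nodes[nodes$taxon_id == id, "parent_id"] != lin$parent_id[i]) {
        stop("conflicting parent for node ", id,
             ": lineages drawn from mixed backbones")
      }
    } else {
      row <- as.data.frame(lin[i, c("taxon_id", "scientific_name", "rank",
                                    "parent_id")])
      nodes <- rbind(nodes, row)
      pid <- lin$parent_id[i]
      if (nzchar(pid)) {
        children[[pid]] <- sort(unique(c(children[[pid]], id)))
      }
    }
  }
  rownames(nodes) <- nodes$taxon_id
  tree$nodes <- nodes
  tree$children <- children
  tree$queried_ids <- sort(unique(c(tree$queried_ids,
                                    lin$taxon_id[nrow(lin)])))
  tree
}

#' Clear a taxonomy tree
#'
#' Forgets all accumulated lineages, returning an empty tree (the "clear
#' button" between queries).
#'
#' @param tree A `taxonomy_tree`.
#' @return An empty `taxonomy_tree`.
#' @export
clear_tree <- function(tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxonomy_tree()
}

tree_roots <- function(tree) {
  ids <- tree$nodes$taxon_id
  sort(ids[!nzchar(tree$nodes$parent_id)])
}

# children of id sorted alphabetically by scientific name (ties by id)
sorted_children <- function(tree, id) {
  kids <- tree$children[[id]]
  if (is.null(kids) || length(kids) == 0) return(character())
  nm <- tree$nodes[kids, "scientific_name"]
  kids[order(nm, kids)]
}

#' Export a taxonomy tree
#'
#' Serialises the tree deterministically (children ordered alphabetically by
#' scientific name) to one of three structural formats:
#' \describe{
#'   \item{dot}{Graphviz digraph with node labels `scientificName [rank]`.}
#'   \item{json}{Nodes, children and queried ids; round-trips through
#'     [tree_from_json()] to an identical tree.}
#'   \item{newick}{Scientific names as labels (spaces as underscores), no
#'     branch lengths. Requires a single root, i.e. all queried taxa share
#'     one kingdom, and a non-empty tree.}
#' }
#'
#' @param tree A `taxonomy_tree`.
#' @param format One of `"dot"`, `"json"`, `"newick"`.
#' @return A single character string.
#' @export
export_tree <- function(tree, format = c("dot", "json", "newick")) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  format <- match.arg(format)
  switch(format,
    dot = export_dot(tree),
    json = export_json(tree),
    newick = export_newick(tree)
  )
}

export_dot <- function(tree) {
  nodes <- tree$nodes[order(tree$nodes$taxon_id), , drop = FALSE]
  lines <- c("digraph taxonomy {")
  for (i in seq_len(nrow(nodes))) {
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s [%s]\"];",
                              nodes$taxon_id[i], nodes$scientific_name[i],
                              nodes$rank[i]))
  }
  for (id in sort(names(tree$children))) {
    for (kid in sorted_children(tree, id)) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", id, kid))
    }
  }
  lines <- c(lines, "}")
  paste(lines, collapse = "\n")
}

export_json <- function(tree) {
  nodes <- tree$nodes[order(tree$nodes$taxon_id), , drop = FALSE]
  rownames(nodes) <- NULL
  children <- lapply(sort(names(tree$children)), function(id) {
    sorted_children(tree, id)
  })
  names(children) <- sort(names(tree$children))
  obj <- list(
    nodes = nodes,
    children = children,
    queried_ids = sort(tree$queried_ids)
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = FALSE, pretty = TRUE,
                                digits = NA))
}

#' Rebuild a taxonomy tree from its JSON export
#'
#' @param json JSON string produced by `export_tree(tree, "json")`.
#' @return The reconstructed `taxonomy_tree`.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  tree <- taxonomy_tree()
  if (length(obj$nodes) == 0 || NROW(obj$nodes) == 0) return(tree)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  rownames(nodes) <- nodes$taxon_id
  tree$nodes <- nodes
  ch <- lapply(obj$children, as.character)
  tree$children <- ch[order(names(ch))]
  tree$queried_ids <- sort(as.character(obj$queried_ids))
  tree
}

export_newick <- function(tree) {
  roots <- tree_roots(tree)
  if (length(roots) == 0) stop("cannot export an empty tree as newick")
  if (length(roots) > 1) {
    stop("newick export requires a single kingdom root; tree has ",
         length(roots), " roots (use dot or json)")
  }
  label <- function(id) gsub(" ", "_", tree$nodes[id, "scientific_name"])
  rec <- function(id) {
    kids <- sorted_children(tree, id)
    if (length(kids) == 0) return(label(id))
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")", label(id))
  }
  paste0(rec(roots), ";")
}

#' Count bifurcation nodes
#'
#' Nodes with two or more children — the points where merged lineages diverge.
#'
#' @param tree A `taxonomy_tree`.
#' @return Integer count.
#' @export
count_bifurcations <- function(tree) {
  sum(vapply(tree$children, length, integer(1)) >= 2L)
}
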