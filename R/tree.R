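# Clone tree container: a rooted multifurcating tree over mutation clusters
# with a distinguished empty dummy root and an outlier set.

#' Construct a clone tree
#'
#' A clone tree is the latent state of the model: a rooted tree whose non-root
#' nodes each carry a non-empty cluster of mutations, topped by an empty dummy
#' root (label 0), plus a set of outlier mutations kept off the tree.
#'
#' @param parent integer vector of length K; `parent[v]` is the parent of node
#'   v, with 0 denoting the dummy root.
#' @param clusters list of length K of integer mutation indices per node.
#' @param outliers integer vector of outlier mutation indices.
#' @param n_mutations total number of mutations; defaults to the number
#'   covered by `clusters` and `outliers`.
#' @return object of class `clone_tree`.
#' @export
clone_tree <- function(parent, clusters, outliers = integer(),
                       n_mutations = NULL) {
  parent <- as.integer(parent)
  clusters <- lapply(clusters, as.integer)
  outliers <- as.integer(outliers)
  covered <- c(unlist(clusters), outliers)
  n_mutations <- n_mutations %||% length(covered)
  tree <- structure(
    list(parent = parent, clusters = clusters, outliers = outliers,
         n_mutations = as.integer(n_mutations)),
    class = "clone_tree"
  )
  validate_clone_tree(tree)
  tree
}

#' Validate clone tree invariants
#'
#' Checks acyclicity/single-rootedness of the parent map, disjointness of
#' clusters, coverage of all mutations by clusters plus outliers, and
#' non-emptiness of non-root clusters.
#'
#' @param tree a `clone_tree`.
#' @return the tree, invisibly; errors on violation.
#' @export
validate_clone_tree <- function(tree) {
  K <- length(tree$parent)
  if (length(tree$clusters) != K)
    stop_validation("parent and clusters disagree on node count")
  if (K > 0) {
    if (any(tree$parent < 0 | tree$parent > K))
      stop_validation("parent indices out of range")
    # every node must reach the dummy root
    for (v in seq_len(K)) {
      seen <- logical(K)
      u <- v
      while (u != 0L) {
        if (seen[u]) stop_validation("parent map has a cycle at node %d", v)
        seen[u] <- TRUE
        u <- tree$parent[u]
      }
    }
    if (any(vapply(tree$clusters, length, 1L) == 0L))
      stop_validation("non-root nodes must have non-empty clusters")
  }
  all_items <- c(unlist(tree$clusters), tree$outliers)
  if (anyDuplicated(all_items))
    stop_validation("clusters/outliers overlap")
  if (!setequal(all_items, seq_len(tree$n_mutations)))
    stop_validation("clusters plus outliers must cover all %d mutations",
                    tree$n_mutations)
  invisible(tree)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d nodes, %d mutations, %d outliers\n",
              length(x$parent), x$n_mutations, length(x$outliers)))
  invisible(x)
}

# list of children node ids per node; index 1 is the dummy root (id 0)
tree_children <- function(parent) {
  K <- length(parent)
  ch <- vector("list", K + 1L)
  for (v in seq_len(K)) {
    p <- parent[v] + 1L
    ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

# postorder over non-root nodes (children before parents)
tree_postorder <- function(parent) {
  K <- length(parent)
  if (K == 0L) return(integer())
  ch <- tree_children(parent)
  out <- integer(0)
  visit <- function(v) {
    for (c in ch[[v + 1L]]) visit(c)
    if (v != 0L) out[[length(out) + 1L]] <<- v
  }
  visit(0L)
  unlist(out)
}

# node ids in the subtree rooted at v (including v)
tree_subtree <- function(parent, v) {
  ch <- tree_children(parent)
  out <- integer(0)
  visit <- function(u) {
    out[[length(out) + 1L]] <<- u
    for (c in ch[[u + 1L]]) visit(c)
  }
  visit(v)
  unlist(out)
}

# canonical string key for a clone tree/state: recursive sorted representation,
# invariant to node relabelling; used by enumeration oracles and trace tallies.
canonical_tree_key <- function(parent, clusters, outliers = integer()) {
  ch <- tree_children(parent)
  rep_of <- function(v) {
    kids <- sort(vapply(ch[[v + 1L]], rep_of, character(1)))
    items <- if (v == 0L) integer() else sort(clusters[[v]])
    sprintf("{%s}(%s)", paste(items, collapse = ","),
            paste(kids, collapse = "|"))
  }
  sprintf("%s[o:%s]", rep_of(0L), paste(sort(outliers), collapse = ","))
}

#' Canonical key of a clone tree
#'
#' A string representation invariant to node relabelling, suitable for
#' tabulating posterior samples against enumeration oracles.
#'
#' @param tree a `clone_tree`.
#' @return character scalar.
#' @export
tree_key <- function(tree) {
  canonical_tree_key(tree$parent, tree$clusters, tree$outliers)
}
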