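# Dated-tree conditioning: I/O, node ages, recent-tip and short-branch
# collapsing, MRCA lookup, branch-to-clade assignment.

#' Read a dated tree from Newick
#'
#' @param x Path to a Newick file, or a Newick string containing `";"`.
#' @return An `ape` `phylo` object, rooted with branch lengths.
#' @export
read_dated_tree <- function(x) {
  tree <- if (grepl(";", x, fixed = TRUE)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (is.null(tree)) stop("could not parse Newick input")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  # a basal polytomy is read as a rooted tree with a root polytomy (the
  # Newick text cannot distinguish the two); deeper structure is kept as-is
  tree
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Output path; if `NULL`, the Newick string is returned.
#' @export
write_dated_tree <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Node ages in Myr before present
#'
#' Ages are measured from the present: the root carries the largest age and
#' ultrametric tips carry age 0. For non-ultrametric trees the deepest tip
#' defines the present.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Numeric vector of ages indexed by node number (tips first).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Collapse very recently diverged species pairs
#'
#' Every cherry (internal node whose children are all tips) younger than
#' `threshold` Myr is collapsed by retaining one of its tips uniformly at
#' random. The rule is applied repeatedly so clusters of more than two
#' recent tips reduce to a single representative. The comparison is strict
#' (a cherry at exactly `threshold` is kept).
#'
#' @param tree Ultrametric rooted `phylo`.
#' @param threshold Age threshold in Myr (default 1).
#' @return The collapsed tree, with the retained tips recorded in the
#'   `retained` attribute and dropped tips in `dropped`.
#' @export
collapse_recent_tips <- function(tree, threshold = 1) {
  dropped <- character(0)
  repeat {
    ages <- node_ages(tree)
    ntip <- length(tree$tip.label)
    parent <- tree$edge[, 1]
    child <- tree$edge[, 2]
    hit <- NULL
    for (nd in unique(parent)) {
      kids <- child[parent == nd]
      if (all(kids <= ntip) && length(kids) >= 2L && ages[nd] < threshold) {
        hit <- nd
        break
      }
    }
    if (is.null(hit)) break
    kids <- child[parent == hit]
    keep <- kids[sample.int(length(kids), 1L)]
    drop <- setdiff(kids, keep)
    dropped <- c(dropped, tree$tip.label[drop])
    tree <- ape::drop.tip(tree, drop)
  }
  attr(tree, "retained") <- tree$tip.label
  attr(tree, "dropped") <- dropped
  tree
}

#' Collapse short internal branches into polytomies
#'
#' Internal branches strictly shorter than `threshold` Myr are removed and
#' their children reattached to the grandparent, creating polytomies. Tip
#' branches are never modified.
#'
#' @param tree Rooted `phylo`.
#' @param threshold Length threshold in Myr (default 1).
#' @return The collapsed tree (same tip set).
#' @export
collapse_short_internal <- function(tree, threshold = 1) {
  ape::di2multi(tree, tol = threshold)
}

#' Most recent common ancestor of a tip set
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (or integer tip numbers).
#' @return Node number of the MRCA; for a single tip, the tip itself.
#' @export
mrca_node <- function(tree, tips) {
  if (length(tips) == 0L) stop("empty tip set")
  if (is.character(tips)) {
    idx <- match(tips, tree$tip.label)
    if (anyNA(idx)) stop("tips not in tree: ", paste(tips[is.na(idx)], collapse = ", "))
  } else {
    idx <- tips
  }
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# node numbers of all descendants of `node`, including `node` itself
descendants_of <- function(tree, node) {
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  out <- node
  frontier <- node
  while (length(frontier)) {
    nxt <- child[parent %in% frontier]
    out <- c(out, nxt)
    frontier <- nxt[nxt > length(tree$tip.label)]
  }
  out
}

#' Assign tree branches to clades
#'
#' A branch belongs to clade C when its parent node is a descendant of (or
#' equal to) the MRCA of C's tips. Branches matching no clade are labelled
#' `"stem"`. When overlapping clades both claim a branch, the clade with the
#' youngest MRCA wins (the most nested one).
#'
#' @param tree A rooted `phylo`.
#' @param clade_map A data.frame with columns `tip` and the clade column
#'   named by `level` (default `"phylum"`). Unmapped tips are allowed.
#' @param level Name of the clade column to use.
#' @return Character vector of clade labels, one per edge (rows of
#'   `tree$edge`).
#' @export
assign_branches <- function(tree, clade_map, level = "phylum") {
  stopifnot(all(c("tip", level) %in% names(clade_map)))
  cm <- clade_map[clade_map$tip %in% tree$tip.label, , drop = FALSE]
  clades <- unique(cm[[level]])
  ages <- node_ages(tree)
  labels <- rep("stem", nrow(tree$edge))
  anchors <- numeric(length(clades))
  names(anchors) <- clades
  # youngest-MRCA clades claim last so nested labels take precedence
  for (cl in clades) {
    anchors[cl] <- mrca_node(tree, cm$tip[cm[[level]] == cl])
  }
  ntip <- length(tree$tip.label)
  for (cl in clades[order(ages[anchors], decreasing = TRUE)]) {
    if (anchors[cl] <= ntip) {
      # single-tip clade: the MRCA is the tip; assign its own branch
      labels[tree$edge[, 2] == anchors[cl]] <- cl
    } else {
      desc <- descendants_of(tree, anchors[cl])
      labels[tree$edge[, 1] %in% desc] <- cl
    }
  }
  labels
}

#' Read a tip-to-clade mapping table
#'
#' @param file TSV with 2-3 columns: tip, phylum and optionally kingdom.
#' @return data.frame with columns `tip`, `phylum` and, when present,
#'   `kingdom`.
#' @export
read_clade_map <- function(file) {
  cm <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(ncol(cm) >= 2L)
  names(cm)[1:2] <- c("tip", "phylum")
  if (ncol(cm) >= 3L) names(cm)[3] <- "kingdom"
  cm
}
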