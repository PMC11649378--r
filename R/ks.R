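# Gene-structure divergence as distribution distance: pairwise two-sample
# Kolmogorov-Smirnov matrices, fixed-topology least-squares branch lengths,
# and KS-per-Myr divergence rates.

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum absolute difference between the two empirical CDFs, bounded
#' in `[0, 1]`: 0 for identical distributions, 1 for distributions with
#' disjoint supports.
#'
#' @param a,b Non-empty numeric samples.
#' @return The KS statistic `D`.
#' @export
ks_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Pairwise KS distance matrix between species
#'
#' @param distributions Named list of numeric vectors, one per species
#'   (e.g. the `intron_ratio` distributions of
#'   [extract_gene_structures()]). Species with empty or missing
#'   distributions are dropped with a warning.
#' @param feature Optional feature name stored as an attribute.
#' @return Symmetric matrix with zero diagonal and entries in `[0, 1]`.
#' @export
pairwise_ks_matrix <- function(distributions, feature = NULL) {
  ok <- vapply(distributions, function(v) !is.null(v) && length(v) > 0L,
               logical(1))
  if (any(!ok)) {
    warning("dropping species with missing distributions: ",
            paste(names(distributions)[!ok], collapse = ", "))
    distributions <- distributions[ok]
  }
  n <- length(distributions)
  if (n < 2L) stop("need at least 2 species")
  ids <- names(distributions)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- ks_distance(distributions[[i]], distributions[[j]])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  attr(D, "feature") <- feature
  D
}

#' Least-squares branch lengths on a fixed topology
#'
#' Finds branch lengths minimizing
#' `sum_{i<j} (d_ij - sum_{b in path(i,j)} l_b)^2` by ordinary least
#' squares over the pair-path incidence system, keeping the given topology
#' fixed. For identifiability in the unrooted sense, the two root-incident
#' branches (when the root is a bifurcation) are merged during the solve
#' and the fitted length is split between them in proportion to their
#' dated lengths. Negative solutions are clamped to zero after solving and
#' residuals are recomputed.
#'
#' @param D Symmetric distance matrix with tip-label dimnames; its tips
#'   must all occur in `tree` (the tree is pruned to them).
#' @param tree Rooted `phylo` providing the fixed topology and the dated
#'   lengths used to split the root edge.
#' @param nnls If `TRUE`, refine with coordinate-descent non-negative least
#'   squares instead of single-pass clamping.
#' @return Object of class `ks_tree`: list with `tree` (the topology with
#'   KS-unit branch lengths), `dated_tree` (pruned input), `rss`
#'   (post-clamping residual sum of squares), `n_clamped`.
#' @export
fit_branch_lengths <- function(D, tree, nnls = FALSE) {
  tips <- rownames(D)
  if (is.null(tips)) stop("distance matrix must carry tip-label dimnames")
  if (!all(tips %in% tree$tip.label)) {
    stop("distance-matrix tips missing from tree: ",
         paste(setdiff(tips, tree$tip.label), collapse = ", "))
  }
  tree <- ape::keep.tip(tree, tips)
  ntip <- length(tree$tip.label)
  B <- path_indicator(tree)[seq_len(ntip), , drop = FALSE]
  n_edge <- nrow(tree$edge)

  pairs <- utils::combn(ntip, 2)
  # pair-path incidence: edge b is on path(i,j) iff it is on exactly one
  # of the two root paths
  Afull <- abs(B[pairs[1, ], , drop = FALSE] - B[pairs[2, ], , drop = FALSE])
  d <- D[cbind(pairs[1, ], pairs[2, ])]

  # when the root bifurcates, its two incident edges always appear together
  # on cross-root paths (identical columns): only their sum is identifiable
  # in the unrooted sense, so one column is dropped and the fitted length
  # split afterwards
  root <- ntip + 1L
  root_edges <- which(tree$edge[, 1] == root)
  merge_pair <- if (length(root_edges) == 2L) root_edges else integer(0)
  if (length(merge_pair)) {
    cols <- setdiff(seq_len(n_edge), merge_pair[2L])
    A <- Afull[, cols, drop = FALSE]
    mcol <- match(merge_pair[1L], cols)
  } else {
    cols <- seq_len(n_edge)
    A <- Afull
    mcol <- NA_integer_
  }

  sol <- stats::lm.fit(A, d)$coefficients
  sol[is.na(sol)] <- 0
  if (nnls) {
    sol <- pmax(sol, 0)
    for (it in seq_len(200L)) {
      old <- sol
      for (b in seq_along(sol)) {
        r_b <- d - A[, -b, drop = FALSE] %*% sol[-b]
        denom <- sum(A[, b]^2)
        sol[b] <- if (denom > 0) max(0, sum(A[, b] * r_b) / denom) else 0
      }
      if (max(abs(sol - old)) < 1e-12) break
    }
  }

  lens <- numeric(n_edge)
  lens[cols] <- sol
  if (length(merge_pair)) {
    dl <- tree$edge.length[merge_pair]
    w <- if (sum(dl) > 0) dl / sum(dl) else c(0.5, 0.5)
    lens[merge_pair] <- sol[mcol] * w
  }
  n_clamped <- sum(lens < 0)
  lens <- pmax(lens, 0)

  ks_tree <- tree
  ks_tree$edge.length <- lens
  fitted_d <- drop(A %*% (if (length(merge_pair)) {
    v <- lens[cols]; v[mcol] <- lens[merge_pair[1L]] + lens[merge_pair[2L]]; v
  } else lens))
  structure(
    list(tree = ks_tree, dated_tree = tree,
         rss = sum((d - fitted_d)^2), n_clamped = n_clamped),
    class = "ks_tree"
  )
}

#' @export
print.ks_tree <- function(x, ...) {
  cat("Fixed-topology least-squares KS tree\n")
  cat(sprintf("  %d tips | total KS length %.4g | RSS %.4g | %d branch(es) clamped to 0\n",
              length(x$tree$tip.label), sum(x$tree$edge.length),
              x$rss, x$n_clamped))
  invisible(x)
}

#' Gene-structure divergence rates from a KS tree
#'
#' Divides KS branch lengths by the matching dated branch lengths: the
#' global rate is total KS tree length over total dated tree length, clade
#' rates use each clade's assigned branches, and per-branch rates are the
#' branchwise ratios (missing where the dated length is zero). Rates are in
#' KS units per Myr; `per_byr` columns multiply by 1000.
#'
#' @param ks_fit A `ks_tree` from [fit_branch_lengths()], or a `phylo`
#'   whose topology matches `dated_tree`.
#' @param dated_tree Dated `phylo` with the same topology.
#' @param clade_map Optional data.frame (`tip`, `phylum`) for clade rates.
#' @return List with `global` (per Myr), `global_per_byr`, `clades`
#'   (data.frame), `branches` (data.frame with per-branch rates).
#' @export
divergence_rates <- function(ks_fit, dated_tree, clade_map = NULL) {
  ks_tree <- if (inherits(ks_fit, "ks_tree")) ks_fit$tree else ks_fit
  if (!identical(dim(ks_tree$edge), dim(dated_tree$edge)) ||
      !setequal(ks_tree$tip.label, dated_tree$tip.label)) {
    stop("KS and dated trees have different topologies")
  }
  # align edges via child tip-set identity (labels may be ordered alike)
  if (!identical(ks_tree$tip.label, dated_tree$tip.label) ||
      !identical(ks_tree$edge, dated_tree$edge)) {
    stop("KS and dated trees must share identical node numbering; ",
         "fit the KS tree with fit_branch_lengths() on the dated tree")
  }
  lk <- ks_tree$edge.length
  ld <- dated_tree$edge.length
  global <- sum(lk) / sum(ld)
  branches <- data.frame(
    child = dated_tree$edge[, 2],
    dated_len = ld, ks_len = lk,
    rate = ifelse(ld > 0, lk / ld, NA_real_)
  )
  branches$rate_per_byr <- branches$rate * 1000
  clades <- NULL
  if (!is.null(clade_map)) {
    lab <- assign_branches(dated_tree, clade_map)
    cl_names <- setdiff(unique(lab), "stem")
    clades <- do.call(rbind, lapply(cl_names, function(cl) {
      sel <- lab == cl
      r <- sum(lk[sel]) / sum(ld[sel])
      data.frame(clade = cl, n_branches = sum(sel), rate = r,
                 rate_per_byr = r * 1000)
    }))
  }
  list(global = global, global_per_byr = global * 1000,
       clades = clades, branches = branches)
}
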