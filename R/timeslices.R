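# Time-sliced trait trajectories: linear interpolation of reconstructed
# states along branches, summarized per clade on a fixed Myr grid.

#' Linear model of a trait along one branch
#'
#' Assuming a constant rate of change along the branch, the state at age
#' `t` is `v(t) = m*t + b` with slope `m = (v0 - v1)/(t0 - t1)` and
#' intercept `b = v0 - m*t0`, where `t0 > t1` are the parent and child ages
#' (Myr before present) and `v0`, `v1` the states at those nodes.
#'
#' @param t0,t1 Parent and child ages (`t0 > t1`).
#' @param v0,v1 States at parent and child.
#' @return Named vector `c(m, b)`.
#' @export
branch_line <- function(t0, t1, v0, v1) {
  if (t0 <= t1) stop("t0 must exceed t1 (zero-length branches are excluded)")
  m <- (v0 - v1) / (t0 - t1)
  c(m = m, b = v0 - m * t0)
}

#' Interpolated states of all branches alive at one time point
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param states Named numeric vector of states at every node (tips and
#'   internals; e.g. `ancestral_states(fit)` from [rr_fit()]).
#' @param t Age in Myr before present.
#' @return data.frame with `edge` (row of `tree$edge`), `child` node and
#'   interpolated `value` for every branch with `t1 <= t <= t0`; empty
#'   when `t` lies outside the tree span.
#' @export
slice_values <- function(tree, states, t) {
  ages <- node_ages(tree)
  pa <- ages[tree$edge[, 1]]
  ca <- ages[tree$edge[, 2]]
  alive <- ca <= t & t <= pa & pa > ca
  idx <- which(alive)
  if (length(idx) == 0L) {
    return(data.frame(edge = integer(0), child = integer(0),
                      value = numeric(0)))
  }
  ntip <- length(tree$tip.label)
  node_key <- c(tree$tip.label, as.character((ntip + 1):(ntip + tree$Nnode)))
  v0 <- states[node_key[tree$edge[idx, 1]]]
  v1 <- states[node_key[tree$edge[idx, 2]]]
  m <- (v0 - v1) / (pa[idx] - ca[idx])
  b <- v0 - m * pa[idx]
  data.frame(edge = idx, child = tree$edge[idx, 2],
             value = unname(m * t + b))
}

#' Per-clade trait trajectories on a time grid
#'
#' Evaluates every branch's interpolated state on a grid of ages spaced
#' `dt` Myr apart (anchored at the present, t = 0) and summarizes, for each
#' clade, the branches assigned to it (see [assign_branches()]) that are
#' alive at each time point. Both the median and the mean across branches
#' are reported.
#'
#' @param tree Rooted `phylo`.
#' @param states Named states at every node (as in [slice_values()]).
#' @param clade_map data.frame with `tip` and the `level` column.
#' @param dt Grid spacing in Myr (default 5).
#' @param level Clade column name (default `"phylum"`).
#' @return data.frame with columns `clade`, `t`, `median`, `mean`,
#'   `n_branches`; rows where a clade has no living branch are omitted.
#' @export
clade_trajectory <- function(tree, states, clade_map, dt = 5,
                             level = "phylum") {
  labels <- assign_branches(tree, clade_map, level = level)
  root_age <- max(node_ages(tree))
  grid <- seq(0, root_age, by = dt)
  rows <- list()
  for (t in grid) {
    sv <- slice_values(tree, states, t)
    if (nrow(sv) == 0L) next
    lab <- labels[sv$edge]
    for (cl in unique(lab)) {
      if (cl == "stem") next
      v <- sv$value[lab == cl]
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, t = t, median = stats::median(v), mean = mean(v),
        n_branches = length(v)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(clade = character(0), t = numeric(0),
                      median = numeric(0), mean = numeric(0),
                      n_branches = integer(0))
  }
  out[order(out$clade, out$t), , drop = FALSE]
}
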