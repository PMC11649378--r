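# Perturbation-based 95% CIs for ancestral states: random tip dropping,
# within-clade tip swaps, node-age modification, penalty-based replicate
# rejection, empirical quantile intervals.

#' Configuration for the ancestral-CI perturbation protocol
#'
#' Defaults follow the protocol of dropping 20% of tips, swapping the
#' positions of 10% of the remaining tips within their phylum, and
#' modifying 10% of internal node ages; the loop runs until `n_valid`
#' replicates are collected. Replicates whose ridge penalty on the
#' normalized `lambda/(1+lambda)` scale falls below `lambda_min` can be
#' rejected; the original protocol used this to discard local-optimum fits
#' of its internal penalty optimizer. [rr_fit()] selects the penalty by a
#' deterministic global grid search, which has no local-optimum failure
#' mode and legitimately selects near-zero penalties on clean data, so the
#' default here is `lambda_min = 0` (no rejection); set 0.9 to reproduce
#' the original rule.
#'
#' @param drop_frac Fraction of tips dropped per replicate.
#' @param swap_frac Fraction of remaining tips whose positions are swapped.
#' @param age_frac Fraction of internal nodes whose ages are modified.
#' @param age_range Multiplicative age-perturbation range (uniform draw).
#' @param lambda_min Minimum normalized penalty for a replicate to count.
#' @param n_valid Number of valid replicates to collect.
#' @param ci Quantile bounds of the interval.
#' @return List of class `perturbation_config`.
#' @export
perturbation_config <- function(drop_frac = 0.20, swap_frac = 0.10,
                                age_frac = 0.10, age_range = c(0.5, 1.5),
                                lambda_min = 0, n_valid = 100,
                                ci = c(0.025, 0.975)) {
  stopifnot(drop_frac >= 0, drop_frac < 1, swap_frac >= 0, swap_frac < 1,
            age_frac >= 0, age_frac < 1, n_valid >= 1,
            length(ci) == 2L, ci[1] < ci[2])
  structure(list(drop_frac = drop_frac, swap_frac = swap_frac,
                 age_frac = age_frac, age_range = age_range,
                 lambda_min = lambda_min, n_valid = n_valid, ci = ci),
            class = "perturbation_config")
}

# swap tip positions: exchange the labels at the chosen tip slots, pairing
# only within the same phylum; traits stay attached to their label
swap_tip_positions <- function(tree, clade_map, swap_frac) {
  n <- length(tree$tip.label)
  k <- floor(swap_frac * n)
  if (k < 2L) return(tree)
  chosen <- sample.int(n, k)
  phy <- clade_map$phylum[match(tree$tip.label[chosen], clade_map$tip)]
  for (cl in unique(phy[!is.na(phy)])) {
    slots <- chosen[!is.na(phy) & phy == cl]
    if (length(slots) < 2L) next
    slots <- sample(slots)  # random pairing
    npair <- length(slots) %/% 2L
    for (j in seq_len(npair)) {
      a <- slots[2L * j - 1L]
      b <- slots[2L * j]
      tmp <- tree$tip.label[a]
      tree$tip.label[a] <- tree$tip.label[b]
      tree$tip.label[b] <- tmp
    }
  }
  tree
}

# multiply selected internal node ages by U(range), clamping each new age
# strictly between the current ages of its parent and children
perturb_node_ages <- function(tree, age_frac, age_range) {
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  k <- floor(age_frac * m)
  if (k < 1L) return(tree)
  ages <- node_ages(tree)
  parent_of <- integer(ntip + m)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  internal <- setdiff((ntip + 1L):(ntip + m), root)  # root age kept fixed
  if (length(internal) == 0L) return(tree)
  chosen <- sample(internal, min(k, length(internal)))
  for (nd in chosen) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    lo <- max(ages[kids])
    hi <- ages[parent_of[nd]]
    prop <- ages[nd] * stats::runif(1, age_range[1], age_range[2])
    eps <- 1e-6 * (hi - lo)
    ages[nd] <- min(max(prop, lo + eps), hi - eps)
  }
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  tree
}

#' Generate one perturbed replicate of a comparative dataset
#'
#' Applies, in order: uniform random dropping of `floor(drop_frac * n)`
#' tips; pairwise exchange of the positions of `floor(swap_frac * n')`
#' remaining tips (pairs constrained within the same phylum; traits travel
#' with the tip label); multiplicative modification of
#' `floor(age_frac * m)` internal node ages, clamped so every parent stays
#' older than its children.
#'
#' @param tree Rooted ultrametric `phylo`.
#' @param traits Named numeric vector of tip values.
#' @param clade_map data.frame with columns `tip`, `phylum`.
#' @param config A [perturbation_config()].
#' @return List with the perturbed `tree` and matching `traits`.
#' @export
perturb_replicate <- function(tree, traits, clade_map, config) {
  n <- length(tree$tip.label)
  ndrop <- floor(config$drop_frac * n)
  if (ndrop > 0L) {
    tree <- ape::drop.tip(tree, sample.int(n, ndrop))
  }
  tree <- swap_tip_positions(tree, clade_map, config$swap_frac)
  tree <- perturb_node_ages(tree, config$age_frac, config$age_range)
  list(tree = tree, traits = traits[tree$tip.label])
}

#' Perturbation-based confidence intervals for ancestral states
#'
#' Point estimates come from the ridge rate model on the full data. For
#' uncertainty, perturbed replicates are generated with
#' [perturb_replicate()] and refitted; replicates whose selected penalty on
#' the normalized scale is below `lambda_min` are discarded (local-optimum
#' guard), and the loop runs until `n_valid` replicates are collected (a
#' hard cap of `20 * n_valid` attempts throws an error). A focal node of
#' the original tree is matched, in each replicate, to the MRCA of its
#' surviving descendant tips; nodes with fewer than 2 surviving descendants
#' in a replicate are skipped there (coverage is reported). The interval is
#' the empirical `ci` quantile pair (type-7) of the matched estimates.
#'
#' @param tree Rooted ultrametric `phylo`.
#' @param traits Named numeric vector of tip values.
#' @param clade_map data.frame with columns `tip`, `phylum`.
#' @param config A [perturbation_config()].
#' @param lambda Penalty passed to [rr_fit()] for every replicate
#'   (default `"auto"`).
#' @return Object of class `ancestral_ci`: a data.frame with one row per
#'   internal node (`node`, `n_desc`, `point`, `lo`, `hi`,
#'   `n_replicates_covering`), plus attributes `fit` (the full-data
#'   `rrfit`), `n_attempts`, `config`.
#' @export
ancestral_ci <- function(tree, traits, clade_map,
                         config = perturbation_config(), lambda = "auto") {
  fit <- rr_fit(tree, traits, lambda = lambda, trait_name = "trait")
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  desc_tips <- lapply(nodes, function(nd) {
    d <- descendants_of(tree, nd)
    tree$tip.label[d[d <= ntip]]
  })
  names(desc_tips) <- as.character(nodes)

  draws <- matrix(NA_real_, length(nodes), config$n_valid,
                  dimnames = list(as.character(nodes), NULL))
  valid <- 0L
  attempts <- 0L
  while (valid < config$n_valid) {
    attempts <- attempts + 1L
    if (attempts > 20L * config$n_valid) {
      stop("could not collect ", config$n_valid, " valid replicates in ",
           20L * config$n_valid, " attempts (lambda_min too strict?)")
    }
    rep_data <- perturb_replicate(tree, traits, clade_map, config)
    rfit <- tryCatch(rr_fit(rep_data$tree, rep_data$traits, lambda = lambda),
                     error = function(e) NULL)
    if (is.null(rfit) || rfit$lambda_norm < config$lambda_min) next
    valid <- valid + 1L
    rtips <- rep_data$tree$tip.label
    for (j in seq_along(nodes)) {
      surv <- intersect(desc_tips[[j]], rtips)
      if (length(surv) < 2L) next
      mnode <- mrca_node(rep_data$tree, surv)
      draws[j, valid] <- rfit$ancestral_states[as.character(mnode)]
    }
  }

  qs <- t(apply(draws, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    stats::quantile(v, probs = config$ci, type = 7, names = FALSE)
  }))
  out <- data.frame(
    node = nodes,
    n_desc = lengths(desc_tips),
    point = unname(fit$ancestral_states[as.character(nodes)]),
    lo = qs[, 1],
    hi = qs[, 2],
    n_replicates_covering = rowSums(!is.na(draws)),
    row.names = NULL
  )
  attr(out, "fit") <- fit
  attr(out, "n_attempts") <- attempts
  attr(out, "config") <- config
  attr(out, "draws") <- draws
  class(out) <- c("ancestral_ci", "data.frame")
  out
}

#' Summarize ancestral CIs at clade MRCAs
#'
#' @param ci_result An [ancestral_ci()] result.
#' @param tree The tree the result was computed on.
#' @param clade_map data.frame with columns `tip` and `level`.
#' @param level Clade column name (default `"phylum"`).
#' @return data.frame with one row per clade: clade, n_species, point, lo,
#'   hi.
#' @export
clade_ci_table <- function(ci_result, tree, clade_map, level = "phylum") {
  clades <- unique(clade_map[[level]])
  rows <- lapply(clades, function(cl) {
    tips <- intersect(clade_map$tip[clade_map[[level]] == cl], tree$tip.label)
    if (length(tips) < 2L) return(NULL)
    nd <- mrca_node(tree, tips)
    r <- ci_result[ci_result$node == nd, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    data.frame(clade = cl, n_species = length(tips),
               point = r$point, lo = r$lo, hi = r$hi)
  })
  do.call(rbind, rows)
}
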