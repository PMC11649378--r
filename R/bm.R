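# Brownian-motion baseline: ML sigma^2 and root state, GLS ancestral
# reconstruction with the full node covariance matrix.

# covariance between every pair of nodes (tips + internals): shared
# root-to-MRCA path length on the tree
node_covariance <- function(tree) {
  B <- path_indicator(tree)
  C <- B %*% (tree$edge.length * t(B))
  ntip <- length(tree$tip.label)
  dimnames(C) <- rep(list(c(tree$tip.label,
                            as.character((ntip + 1):(ntip + tree$Nnode)))), 2)
  C
}

#' Fit a single-rate Brownian-motion model
#'
#' Maximum-likelihood fit of the homogeneous BM model: the root state is the
#' GLS phylogenetic mean, `sigma2` the ML rate
#' `(y - root)' C^-1 (y - root) / n` with `C` the tip covariance matrix, and
#' ancestral states are the GLS (conditional-expectation) reconstruction
#' using the full node covariance.
#'
#' @param tree Rooted `phylo` with branch lengths, at least 3 tips.
#' @param y Named numeric vector of tip trait values.
#' @return Object of class `bmfit` with `sigma2`, `root_state`,
#'   `ancestral_states` (internal nodes, named by node number), `logLik`,
#'   `AIC`, `tree`.
#' @export
bm_fit <- function(tree, y) {
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("need at least 3 tips")
  if (is.null(names(y))) stop("y must be named by tip label")
  y <- y[tree$tip.label]
  if (anyNA(y)) stop("missing trait values for some tips")

  C <- ape::vcv(tree)
  if (any(diag(C) <= 0)) stop("zero root-to-tip path length")
  Cinv <- solve(C)
  one <- rep(1, ntip)
  root <- as.numeric((one %*% Cinv %*% y) / (one %*% Cinv %*% one))
  r <- y - root
  sigma2 <- as.numeric(r %*% Cinv %*% r) / ntip
  ll <- as.numeric(-0.5 * (ntip * log(2 * pi * sigma2) +
                             determinant(C, logarithm = TRUE)$modulus +
                             ntip))

  Cfull <- node_covariance(tree)
  idx_int <- (ntip + 1):(ntip + tree$Nnode)
  Cay <- Cfull[idx_int, seq_len(ntip), drop = FALSE]
  anc <- root + drop(Cay %*% Cinv %*% r)
  names(anc) <- as.character(idx_int)

  structure(
    list(sigma2 = sigma2, root_state = root, ancestral_states = anc,
         logLik = ll, AIC = 2 * 2 - 2 * ll, tree = tree),
    class = "bmfit"
  )
}

#' @export
print.bmfit <- function(x, ...) {
  cat("Brownian-motion fit\n")
  cat(sprintf("  sigma2 %.6g | root %.6g | logLik %.4f | AIC %.2f\n",
              x$sigma2, x$root_state, x$logLik, x$AIC))
  invisible(x)
}

#' @export
coef.bmfit <- function(object, ...) {
  c(root_state = object$root_state, sigma2 = object$sigma2)
}

#' @export
logLik.bmfit <- function(object, ...) {
  structure(object$logLik, df = 2, nobs = length(object$tree$tip.label),
            class = "logLik")
}
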