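# Rate-heterogeneous trait evolution via phylogenetic ridge regression:
# tip values are regressed on root->tip branch-length path indicators, so
# every branch obtains its own (signed) evolutionary rate, and ancestral
# states follow additively along root->node paths.

# indicator matrix B[i, b] = 1 iff edge b lies on the root->i path;
# rows cover all nodes (tips 1..n, then internals; root row is all zero)
path_indicator <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  n_edge <- nrow(tree$edge)
  parent_of <- integer(n_node)
  edge_of <- integer(n_node)  # edge whose child is the node
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(n_edge)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  B <- matrix(0, n_node, n_edge)
  for (i in seq_len(n_node)) {
    nd <- i
    while (nd != root) {
      B[i, edge_of[nd]] <- 1
      nd <- parent_of[nd]
    }
  }
  B
}

#' Root-to-node path matrix
#'
#' Entry `X[i, b]` is the length of branch `b` when `b` lies on the path
#' from the root to node `i`, and 0 otherwise. Row sums therefore equal
#' root-to-node path lengths. Columns follow the rows of `tree$edge`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param nodes `"tips"` (default) for tip rows only, or `"all"` for every
#'   node (tips first, root row zero).
#' @return Numeric matrix, rows named by tip label (or node number).
#' @export
build_path_matrix <- function(tree, nodes = c("tips", "all")) {
  nodes <- match.arg(nodes)
  B <- path_indicator(tree)
  X <- sweep(B, 2, tree$edge.length, `*`)
  ntip <- length(tree$tip.label)
  rownames(X) <- c(tree$tip.label, as.character((ntip + 1):(ntip + tree$Nnode)))
  if (nodes == "tips") X <- X[seq_len(ntip), , drop = FALSE]
  colnames(X) <- as.character(tree$edge[, 2])  # edge named by child node
  X
}

#' Fit the phylogenetic ridge rate model
#'
#' Estimates one evolutionary rate per branch for a continuous trait. The
#' root state is first estimated as the generalized-least-squares
#' phylogenetic mean under Brownian-motion covariance and held fixed; the
#' per-branch rates `beta` then minimize
#' `sum_i (y_i - root - (X beta)_i)^2 + lambda * sum_b beta_b^2`,
#' where `X` is the root-to-tip path matrix. Because there are more
#' branches than tips the penalty is essential; `lambda = "auto"` selects
#' the penalty on a log-spaced grid by minimizing the leave-one-out
#' cross-validated tip prediction error (closed form via the ridge hat
#' matrix). The selected penalty is also reported on the normalized scale
#' `lambda / (1 + lambda)` used by the replicate-rejection rule of
#' [ancestral_ci()].
#'
#' Ancestral states follow additively: the state at any node is the root
#' state plus the sum of `beta_b * l_b` over the branches on its root path,
#' so tip states equal fitted values and
#' `state(child) - state(parent) = beta_b * l_b` for every branch.
#'
#' @param tree Rooted `phylo` with branch lengths, at least 3 tips.
#' @param y Named numeric vector of tip trait values (log10-transformed
#'   upstream where appropriate; the model itself is transform-agnostic).
#' @param lambda `"auto"` (LOOCV grid search) or a non-negative number;
#'   0 is floored at machine epsilon to keep the system well posed.
#' @param grid Candidate penalties used when `lambda = "auto"`.
#' @param trait_name Optional label stored in the fit.
#' @return Object of class `rrfit` with components `root_state`, `rates`
#'   (one per edge, named by child node), `lambda`, `lambda_norm`,
#'   `cv_error`, `ancestral_states` (all nodes, tips included),
#'   `fitted_tips`, `residuals`, `tree`, `trait_name`.
#' @export
rr_fit <- function(tree, y, lambda = "auto",
                   grid = 10^seq(-6, 3, length.out = 40),
                   trait_name = "trait") {
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("need at least 3 tips")
  if (is.null(names(y))) stop("y must be named by tip label")
  y <- y[tree$tip.label]
  if (anyNA(y)) stop("missing trait values for some tips")

  C <- ape::vcv(tree)
  Cinv <- solve(C)
  one <- rep(1, ntip)
  root <- as.numeric((one %*% Cinv %*% y) / (one %*% Cinv %*% one))

  X <- build_path_matrix(tree, "tips")
  yc <- y - root
  sv <- svd(X)
  d <- sv$d
  uy <- crossprod(sv$u, yc)  # U' yc

  ridge_beta <- function(lam) {
    drop(sv$v %*% (uy * d / (d^2 + lam)))
  }
  loocv <- function(lam) {
    h <- rowSums(sweep(sv$u^2, 2, d^2 / (d^2 + lam), `*`))
    res <- yc - sv$u %*% (uy * d^2 / (d^2 + lam))
    mean((res / pmax(1 - h, 1e-12))^2)
  }

  cv_error <- NA_real_
  if (identical(lambda, "auto")) {
    errs <- vapply(grid, loocv, numeric(1))
    lambda <- grid[which.min(errs)]
    cv_error <- min(errs)
  } else {
    lambda <- max(as.numeric(lambda), .Machine$double.eps)
    cv_error <- loocv(lambda)
  }
  beta <- ridge_beta(lambda)
  names(beta) <- as.character(tree$edge[, 2])

  Xall <- build_path_matrix(tree, "all")
  states <- root + drop(Xall %*% beta)
  names(states) <- rownames(Xall)
  fitted_tips <- states[seq_len(ntip)]

  structure(
    list(root_state = root, rates = beta, lambda = lambda,
         lambda_norm = lambda / (1 + lambda), cv_error = cv_error,
         ancestral_states = states, fitted_tips = fitted_tips,
         residuals = y - fitted_tips, tree = tree,
         trait_name = trait_name),
    class = "rrfit"
  )
}

#' @export
print.rrfit <- function(x, ...) {
  cat("Phylogenetic ridge rate model:", x$trait_name, "\n")
  cat(sprintf("  %d tips, %d branches\n",
              length(x$tree$tip.label), length(x$rates)))
  cat(sprintf("  root state   %.6g\n", x$root_state))
  cat(sprintf("  lambda       %.4g (normalized %.3f), LOOCV MSE %.4g\n",
              x$lambda, x$lambda_norm, x$cv_error))
  cat(sprintf("  |rate| range %.4g .. %.4g\n",
              min(abs(x$rates)), max(abs(x$rates))))
  invisible(x)
}

#' @export
summary.rrfit <- function(object, ...) {
  out <- list(
    trait_name = object$trait_name,
    root_state = object$root_state,
    lambda = object$lambda,
    lambda_norm = object$lambda_norm,
    cv_error = object$cv_error,
    rate_summary = summary(object$rates),
    rmse = sqrt(mean(object$residuals^2))
  )
  class(out) <- "summary.rrfit"
  out
}

#' @export
print.summary.rrfit <- function(x, ...) {
  cat("Phylogenetic ridge rate model:", x$trait_name, "\n")
  cat(sprintf("  root state %.6g | lambda %.4g (norm %.3f) | tip RMSE %.4g\n",
              x$root_state, x$lambda, x$lambda_norm, x$rmse))
  cat("  per-branch rates:\n")
  print(x$rate_summary)
  invisible(x)
}

#' @export
coef.rrfit <- function(object, ...) object$rates

#' @export
residuals.rrfit <- function(object, ...) object$residuals

#' @export
fitted.rrfit <- function(object, ...) object$fitted_tips

#' Predict states at tips or at all nodes
#'
#' @param object An `rrfit`.
#' @param nodes `"tips"` or `"all"`.
#' @param ... Unused.
#' @export
predict.rrfit <- function(object, nodes = c("tips", "all"), ...) {
  nodes <- match.arg(nodes)
  if (nodes == "tips") object$fitted_tips else object$ancestral_states
}

#' @export
plot.rrfit <- function(x, ...) {
  graphics::plot(x$tree$edge.length, abs(x$rates),
                 xlab = "branch length (Myr)",
                 ylab = "|rate| (trait units / Myr)",
                 main = paste("Per-branch rates:", x$trait_name), ...)
  invisible(x)
}

#' Ancestral states from a ridge rate fit
#'
#' @param fit An `rrfit`.
#' @param internal_only Drop tip rows (default `FALSE`).
#' @return Named numeric vector of node states (names are tip labels for
#'   tips, node numbers for internal nodes).
#' @export
ancestral_states <- function(fit, internal_only = FALSE) {
  s <- fit$ancestral_states
  if (internal_only) s <- s[-seq_along(fit$tree$tip.label)]
  s
}

#' Rescale a tree by inferred evolutionary rates
#'
#' Branch lengths become proportional to `|rate| * length`, renormalized so
#' the total tree length is conserved exactly. Downstream Brownian-motion
#' methods run on the rescaled tree then inherit the rate heterogeneity.
#'
#' @param tree The tree the fit was computed on.
#' @param fit An `rrfit` for that tree.
#' @return The tree with rescaled branch lengths.
#' @export
rescale_tree <- function(tree, fit) {
  stopifnot(nrow(tree$edge) == length(fit$rates))
  w <- abs(fit$rates) * tree$edge.length
  if (all(w == 0)) stop("all rates are zero; rescaling is degenerate")
  tree$edge.length <- w * sum(tree$edge.length) / sum(w)
  tree
}
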