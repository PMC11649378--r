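# PGLS with Brownian-motion covariance (on dated or rate-rescaled trees),
# AIC model comparison, simulation-based phylogenetic ANOVA, FDR.

#' Brownian-motion phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`;
#' the diagonal holds root-to-tip distances.
#'
#' @param tree Rooted `phylo` with non-negative branch lengths.
#' @return Symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree) {
  ape::vcv(tree)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `formula` by GLS with error covariance proportional to the
#' Brownian-motion phylogenetic covariance of `tree`:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`. Passing a rate-rescaled tree (see
#' [rescale_tree()]) turns the same machinery into a rate-heterogeneous
#' model, which is how the ridge and BM models are compared by AIC.
#' `sigma2` is the ML estimate `RSS_gls / n` (used for the log-likelihood
#' and AIC); coefficient standard errors use the unbiased `RSS_gls / (n-p)`.
#' `R2` is measured against the GLS intercept-only model on the same
#' covariance.
#'
#' @param formula Model formula; interaction terms are supported.
#' @param data data.frame with row names matching tip labels.
#' @param tree Rooted `phylo` covering all rows of `data`.
#' @param jitter Ridge jitter added to the covariance diagonal if it is
#'   computationally singular (default 1e-10 of the mean diagonal).
#' @return Object of class `pgls` with coefficients, SEs, t and p values,
#'   `sigma2` (ML), `logLik`, `AIC`, `r_squared`, `adj_r_squared`, `k`
#'   (parameter count incl. sigma2), `n`, residuals and fitted values.
#' @export
pgls_fit <- function(formula, data, tree, jitter = 1e-10) {
  tips <- tree$tip.label
  if (!all(tips %in% rownames(data))) stop("data rows missing for some tips")
  data <- data[tips, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)

  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stop("collinear predictors: ", paste(bad, collapse = ", "))
  }

  C <- phylo_covariance(tree)
  L <- tryCatch(chol(C), error = function(e) {
    chol(C + diag(jitter * mean(diag(C)), n))
  })
  # whiten: solve L' z = v  (C = L'L with upper-triangular chol)
  wh <- function(v) backsolve(L, v, transpose = TRUE)
  yt <- wh(y)
  Xt <- wh(X)
  colnames(Xt) <- colnames(X)

  fit <- stats::lm.fit(Xt, yt)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  sigma2_u <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2_u * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)

  logdetC <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  k <- p + 1  # coefficients + sigma2
  aic <- 2 * k - 2 * ll

  # intercept-only GLS baseline for R2
  ones <- wh(rep(1, n))
  mu0 <- sum(ones * yt) / sum(ones^2)
  rss0 <- sum((yt - ones * mu0)^2)
  r2 <- 1 - rss / rss0
  n_pred <- p - as.integer("(Intercept)" %in% colnames(X))
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - n_pred - 1)

  coefs <- cbind(Estimate = beta, `Std. Error` = se,
                 `t value` = tval, `Pr(>|t|)` = pval)
  rownames(coefs) <- colnames(X)

  fitted <- drop(X %*% beta)
  structure(
    list(coefficients = beta, coef_table = coefs, sigma2 = sigma2_ml,
         logLik = ll, AIC = aic, r_squared = r2, adj_r_squared = adj_r2,
         k = k, n = n, df_residual = n - p,
         residuals = y - fitted, fitted = fitted,
         formula = formula, tree = tree, response = unname(y),
         X = X),
    class = "pgls"
  )
}

#' @export
print.pgls <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d | R2 = %.4f (adj %.4f) | AIC = %.2f\n",
              x$n, x$r_squared, x$adj_r_squared, x$AIC))
  print(round(x$coef_table, 6))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  object
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  drop(X %*% object$coefficients)
}

#' @export
confint.pgls <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  se <- object$coef_table[, "Std. Error"]
  a <- (1 - level) / 2
  q <- stats::qt(1 - a, df = object$df_residual)
  out <- cbind(cf - q * se, cf + q * se)
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
plot.pgls <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals, xlab = "fitted", ylab = "residuals",
                 main = paste("PGLS:", deparse(x$formula)), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Compare two PGLS fits by AIC
#'
#' @param fit_a,fit_b `pgls` fits of the same response on the same tips
#'   (typically one on the dated tree and one on the rate-rescaled tree).
#' @return List with `delta_aic` (`AIC_a - AIC_b`) and `preferred`
#'   (`"a"` or `"b"`, lower AIC).
#' @export
compare_models <- function(fit_a, fit_b) {
  if (fit_a$n != fit_b$n) stop("fits have different numbers of observations")
  if (!isTRUE(all.equal(fit_a$response, fit_b$response))) {
    stop("fits have different response vectors")
  }
  d <- fit_a$AIC - fit_b$AIC
  list(delta_aic = d, preferred = if (d <= 0) "a" else "b",
       AIC_a = fit_a$AIC, AIC_b = fit_b$AIC)
}

#' Simulation-based phylogenetic ANOVA
#'
#' The observed one-way ANOVA F statistic for group differences in tip
#' values is compared with its null distribution obtained by simulating the
#' trait under Brownian motion on the working tree (rate-rescaled upstream
#' when rate heterogeneity is wanted), with `sigma2` estimated from the data
#' by ML. The p value uses the add-one correction
#' `(1 + #(F_sim >= F_obs)) / (1 + n_sims)`.
#'
#' @param y Named numeric vector of tip values.
#' @param groups Named character/factor vector of group labels for the same
#'   tips; at least 2 groups with at least 2 tips each.
#' @param tree Working tree (dated or rescaled).
#' @param n_sims Number of null simulations (default 1000; must be >= 1).
#' @return Object of class `phylo_anova` with `F_obs`, `p_sim`, `n_sims`,
#'   `groups` (group sizes), `sigma2`.
#' @export
phylo_anova <- function(y, groups, tree, n_sims = 1000) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  tips <- tree$tip.label
  if (is.null(names(y)) || is.null(names(groups))) {
    stop("y and groups must be named by tip label")
  }
  y <- y[tips]
  g <- factor(unname(groups[tips]))
  if (anyNA(y) || anyNA(g)) stop("missing values or groups after pruning")
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 tips each")
  }

  f_stat <- function(v) {
    m <- tapply(v, g, mean)
    ssb <- sum(sizes * (m - mean(v))^2)
    ssw <- sum((v - m[g])^2)
    (ssb / (length(sizes) - 1)) / (ssw / (length(v) - length(sizes)))
  }
  F_obs <- f_stat(y)

  bm <- bm_fit(tree, y)
  U <- chol(phylo_covariance(tree))
  Z <- matrix(stats::rnorm(length(y) * n_sims), length(y), n_sims)
  Y <- sqrt(bm$sigma2) * crossprod(U, Z)  # each column ~ N(0, sigma2 C)
  # F is location-invariant, so the root state need not be added
  gi <- as.integer(g)
  gm <- rowsum(Y, gi) / as.numeric(sizes)
  ssb <- colSums(as.numeric(sizes) * sweep(gm, 2, colMeans(Y))^2)
  ssw <- colSums((Y - gm[gi, , drop = FALSE])^2)
  F_sim <- (ssb / (length(sizes) - 1)) / (ssw / (length(y) - length(sizes)))

  p <- (1 + sum(F_sim >= F_obs)) / (1 + n_sims)
  structure(
    list(F_obs = F_obs, p_sim = p, n_sims = n_sims,
         groups = as.vector(sizes), group_labels = names(sizes),
         sigma2 = bm$sigma2),
    class = "phylo_anova"
  )
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat("Phylogenetic ANOVA (BM null simulations)\n")
  cat(sprintf("  F = %.4f, p = %.4g (%d simulations)\n",
              x$F_obs, x$p_sim, x$n_sims))
  cat("  groups:", paste(sprintf("%s (n=%d)", x$group_labels, x$groups),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p Vector of p values in `[0, 1]`.
#' @return Vector of q values (BH step-up).
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
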