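test_that("path matrix entries follow root->node paths", {
  two <- read_dated_tree("(A:1,B:1);")
  X2 <- build_path_matrix(two)
  expect_equal(unname(X2), diag(2)[, match(two$edge[, 2], 1:2)])

  tree <- read_dated_tree("((A:1,B:1):1,C:2);")
  X <- build_path_matrix(tree)
  # row A: its own branch (length 1) and the AB stem (length 1)
  expect_equal(unname(sort(X["A", X["A", ] > 0])), c(1, 1))
  expect_equal(unname(X["C", colnames(X) == "3"]), 2)
  expect_equal(sum(X["C", ] > 0), 1L)

  set.seed(5)
  rt <- ape::rtree(20)
  Xr <- build_path_matrix(rt)
  expect_equal(unname(rowSums(Xr)),
               unname(ape::node.depth.edgelength(rt)[1:20]))
})

test_that("constant traits give the constant root and null rates", {
  set.seed(6)
  tree <- simulate_tree(8, 50)
  y <- setNames(rep(2.5, 8), tree$tip.label)
  fit <- rr_fit(tree, y)
  expect_equal(fit$root_state, 2.5)
  expect_lt(max(abs(fit$rates)), 1e-8)
  expect_equal(unname(ancestral_states(fit)), rep(2.5, 8 + tree$Nnode))
})

test_that("the near-unpenalized ridge solves the normal equations and interpolates", {
  set.seed(7)
  tree <- simulate_tree(4, 10)
  beta_true <- rnorm(nrow(tree$edge), 0, 0.1)
  X <- build_path_matrix(tree)
  root_true <- 1.2
  y <- root_true + drop(X %*% beta_true)
  names(y) <- tree$tip.label
  fit <- rr_fit(tree, y, lambda = 1e-10)

  # interpolation of a consistent system
  expect_lt(max(abs(fit$fitted_tips - y)), 1e-8)

  # independent dense solve in the (well-conditioned) dual ridge form
  yc <- y - fit$root_state
  lam <- fit$lambda
  beta_oracle <- crossprod(X, solve(X %*% t(X) + diag(lam, nrow(X)), yc))
  expect_lt(max(abs(fit$rates - drop(beta_oracle))), 1e-8)
})

test_that("increasing the penalty monotonically shrinks the rates", {
  set.seed(8)
  tree <- simulate_tree(10, 100)
  y <- simulate_bm(tree, 0.02, root = 0)$tip_values
  norms <- vapply(c(1e-4, 1e-2, 1, 100), function(l) {
    sum(rr_fit(tree, y, lambda = l)$rates^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("ancestral states telescope along every branch", {
  set.seed(9)
  tree <- simulate_tree(12, 100)
  y <- simulate_bm(tree, 0.02, root = 1)$tip_values
  fit <- rr_fit(tree, y)
  st <- fit$ancestral_states
  ntip <- 12L
  key <- c(tree$tip.label, as.character((ntip + 1):(ntip + tree$Nnode)))
  for (e in seq_len(nrow(tree$edge))) {
    expect_equal(unname(st[key[tree$edge[e, 2]]] - st[key[tree$edge[e, 1]]]),
                 unname(fit$rates[e] * tree$edge.length[e]))
  }
  # tip states equal fitted values
  expect_equal(st[seq_len(ntip)], fit$fitted_tips)
})

test_that("rate rescaling conserves total length and follows |rate| weights", {
  # two-branch arithmetic: |rates| (1, 3), lengths (1, 1) -> (0.5, 1.5)
  two <- read_dated_tree("(A:1,B:1);")
  fake <- structure(list(rates = c(1, -3)), class = "rrfit")
  out <- rescale_tree(two, fake)
  expect_equal(sort(out$edge.length), c(0.5, 1.5))

  set.seed(10)
  tree <- simulate_tree(15, 60)
  y <- simulate_bm(tree, 0.05)$tip_values
  fit <- rr_fit(tree, y)
  rs <- rescale_tree(tree, fit)
  expect_equal(sum(rs$edge.length), sum(tree$edge.length),
               tolerance = 1e-12)

  # equal |rates| -> identity
  fit_eq <- structure(list(rates = rep(-2, nrow(tree$edge))), class = "rrfit")
  expect_equal(rescale_tree(tree, fit_eq)$edge.length, tree$edge.length)

  fit0 <- structure(list(rates = rep(0, nrow(tree$edge))), class = "rrfit")
  expect_error(rescale_tree(tree, fit0), "degenerate")
})

test_that("BM fit matches symmetry and an independent pruning oracle", {
  star <- read_dated_tree("(A:1,B:1,C:1);")
  y <- c(A = 0, B = 4, C = 2)
  fit <- bm_fit(star, y)
  expect_equal(fit$root_state, 2)

  set.seed(11)
  for (i in 1:3) {
    tree <- simulate_tree(5, 20)
    yy <- simulate_bm(tree, 0.1, root = 3)$tip_values
    ours <- bm_fit(tree, yy)
    oracle <- phytools::fastAnc(tree, yy)
    expect_lt(max(abs(ours$ancestral_states - as.numeric(oracle))), 1e-6)
    # ML sigma2 equals the GLS quadratic form computed independently
    C <- ape::vcv(tree)
    r <- yy[tree$tip.label] - ours$root_state
    expect_equal(ours$sigma2,
                 as.numeric(t(r) %*% solve(C) %*% r) / 5)
  }
})

test_that("BM sigma2 is recovered on simulated data", {
  set.seed(12)
  est <- replicate(30, {
    tree <- simulate_tree(80, 100)
    bm_fit(tree, simulate_bm(tree, 0.02)$tip_values)$sigma2
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.02), 3 * se)
})

test_that("clade rate shifts raise the inferred within-clade rates", {
  set.seed(13)
  # pick a mid-sized clade (about a third of the tips) to shift
  pick_clade <- function(tree, n) {
    nodes <- (n + 2L):(n + tree$Nnode)
    counts <- vapply(nodes, function(nd) {
      d <- gsevol:::descendants_of(tree, nd)
      sum(d <= n)
    }, integer(1))
    ok <- which(counts >= n %/% 4 & counts <= n %/% 2)
    if (!length(ok)) return(NULL)
    nodes[ok[1]]
  }
  wins <- logical(0)
  while (length(wins) < 50) {
    tree <- simulate_tree(24, 100)
    nd <- pick_clade(tree, 24)
    if (is.null(nd)) next
    in_fast <- seq_len(24) %in% gsevol:::descendants_of(tree, nd)
    cm <- data.frame(tip = tree$tip.label,
                     phylum = ifelse(in_fast, "fast", "slow"))
    sim <- simulate_bm(tree, 0.01, clade_multipliers = c(fast = 5),
                       clade_map = cm)
    fit <- rr_fit(tree, sim$tip_values)
    lab <- assign_branches(tree, cm)
    wins <- c(wins, mean(abs(fit$rates[lab == "fast"])) >
                mean(abs(fit$rates[lab == "slow"])))
  }
  expect_lt(binom.test(sum(wins), length(wins), 0.5,
                       alternative = "greater")$p.value, 0.05)
})
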