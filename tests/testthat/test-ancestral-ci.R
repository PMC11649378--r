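make_ci_setup <- function(n = 16, depth = 100, sigma2 = 0.02) {
  tree <- simulate_tree(n, depth)
  sim <- simulate_bm(tree, sigma2, root = 1)
  cm <- data.frame(tip = tree$tip.label,
                   phylum = rep(c("P1", "P2"), length.out = n))
  list(tree = tree, traits = sim$tip_values, cm = cm, sim = sim)
}

test_that("zero-fraction perturbation is the identity", {
  set.seed(30)
  s <- make_ci_setup()
  cfg <- perturbation_config(drop_frac = 0, swap_frac = 0, age_frac = 0)
  rep1 <- perturb_replicate(s$tree, s$traits, s$cm, cfg)
  expect_identical(rep1$tree$tip.label, s$tree$tip.label)
  expect_equal(rep1$tree$edge.length, s$tree$edge.length)
  expect_equal(rep1$traits, s$traits)
})

test_that("tip dropping removes the configured fraction", {
  set.seed(31)
  s <- make_ci_setup(n = 10)
  cfg <- perturbation_config(drop_frac = 0.2, swap_frac = 0, age_frac = 0)
  rep1 <- perturb_replicate(s$tree, s$traits, s$cm, cfg)
  expect_length(rep1$tree$tip.label, 8L)
  expect_equal(unname(rep1$traits),
               unname(s$traits[rep1$tree$tip.label]))
})

test_that("full within-phylum swapping produces a perfect matching", {
  set.seed(32)
  tree <- simulate_tree(12, 50)
  cm <- data.frame(tip = tree$tip.label, phylum = "P")
  traits <- simulate_bm(tree, 0.01)$tip_values
  cfg <- perturbation_config(drop_frac = 0, swap_frac = 0.99999,
                             age_frac = 0)
  # swap_frac ~ 1: floor(0.99999 * 12) = 11 tips chosen, 5 pairs exchanged
  rep1 <- perturb_replicate(tree, traits, cm, cfg)
  perm <- match(rep1$tree$tip.label, tree$tip.label)
  expect_true(all(perm[perm] == seq_along(perm)))  # an involution
  expect_equal(sum(perm != seq_along(perm)), 10L)  # 5 transpositions
})

test_that("swaps never pair tips across phyla", {
  set.seed(33)
  for (i in 1:10) {
    tree <- simulate_tree(14, 50)
    cm <- data.frame(tip = tree$tip.label,
                     phylum = sample(rep(c("P1", "P2"), 7)))
    traits <- simulate_bm(tree, 0.01)$tip_values
    cfg <- perturbation_config(drop_frac = 0, swap_frac = 0.9, age_frac = 0)
    rep1 <- perturb_replicate(tree, traits, cm, cfg)
    perm <- match(rep1$tree$tip.label, tree$tip.label)
    moved <- which(perm != seq_along(perm))
    for (i2 in moved) {
      p_from <- cm$phylum[match(tree$tip.label[perm[i2]], cm$tip)]
      p_to <- cm$phylum[match(tree$tip.label[i2], cm$tip)]
      expect_equal(p_from, p_to)
    }
  }
})

test_that("age perturbation keeps every parent older than its children", {
  set.seed(34)
  for (i in 1:20) {
    tree <- simulate_tree(20, 100)
    cfg <- perturbation_config(drop_frac = 0, swap_frac = 0, age_frac = 0.9)
    rep1 <- perturb_replicate(tree, setNames(rnorm(20), tree$tip.label),
                              data.frame(tip = tree$tip.label, phylum = "P"),
                              cfg)
    expect_true(all(rep1$tree$edge.length > 0))
    # untouched: tips stay at the present
    expect_lt(max(abs(node_ages(rep1$tree)[1:20])), 1e-8)
  }
})

test_that("the CI run is reproducible and respects quantile semantics", {
  set.seed(35)
  s <- make_ci_setup(n = 12)
  cfg <- perturbation_config(n_valid = 12)
  set.seed(99)
  r1 <- ancestral_ci(s$tree, s$traits, s$cm, cfg)
  set.seed(99)
  r2 <- ancestral_ci(s$tree, s$traits, s$cm, cfg)
  expect_equal(r1, r2)
  expect_true(all(r1$lo <= r1$hi, na.rm = TRUE))

  # quantiles equal an independent sort-based interpolation oracle
  draws <- attr(r1, "draws")
  sorted_quantile <- function(v, p) {
    v <- sort(v[!is.na(v)])
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  for (j in seq_len(nrow(draws))) {
    v <- draws[j, ]
    if (all(is.na(v))) next
    expect_equal(r1$lo[j], sorted_quantile(v, 0.025))
    expect_equal(r1$hi[j], sorted_quantile(v, 0.975))
  }
})

test_that("zero perturbation collapses the interval onto the point estimate", {
  set.seed(36)
  s <- make_ci_setup(n = 10)
  cfg <- perturbation_config(drop_frac = 0, swap_frac = 0, age_frac = 0,
                             n_valid = 5)
  r <- ancestral_ci(s$tree, s$traits, s$cm, cfg)
  expect_equal(r$lo, r$point, tolerance = 1e-8)
  expect_equal(r$hi, r$point, tolerance = 1e-8)
})

test_that("widening the quantile bounds never narrows an interval", {
  set.seed(37)
  s <- make_ci_setup(n = 12)
  set.seed(77)
  narrow <- ancestral_ci(s$tree, s$traits, s$cm,
                         perturbation_config(n_valid = 15))
  set.seed(77)
  wide <- ancestral_ci(s$tree, s$traits, s$cm,
                       perturbation_config(n_valid = 15,
                                           ci = c(0.005, 0.995)))
  ok <- !is.na(narrow$lo)
  expect_true(all(wide$lo[ok] <= narrow$lo[ok] + 1e-12))
  expect_true(all(wide$hi[ok] >= narrow$hi[ok] - 1e-12))
})

test_that("an unreachable validity threshold triggers the attempt cap", {
  set.seed(38)
  s <- make_ci_setup(n = 10)
  cfg <- perturbation_config(lambda_min = 0.999999, n_valid = 2)
  expect_error(ancestral_ci(s$tree, s$traits, s$cm, cfg), "valid replicates")
})

test_that("clade-level CI tables report one row per resolvable clade", {
  set.seed(39)
  s <- make_ci_setup(n = 12)
  cm <- s$cm
  # make phyla monophyletic-ish: split at the root
  root_kids <- s$tree$edge[s$tree$edge[, 1] == 13, 2]
  in_a <- seq_len(12) %in% gsevol:::descendants_of(s$tree, root_kids[1])
  cm$phylum <- ifelse(in_a, "P1", "P2")
  set.seed(40)
  r <- ancestral_ci(s$tree, s$traits, cm, perturbation_config(n_valid = 8))
  tab <- clade_ci_table(r, s$tree, cm)
  expect_true(all(tab$clade %in% c("P1", "P2")))
  expect_true(all(tab$n_species >= 2))
})
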