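test_that("Fitch reconstruction handles canonical cases", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")

  all1 <- setNames(c(1, 1, 1, 1), c("a", "b", "c", "d"))
  f1 <- fitch_ancestral(tr, all1)
  expect_equal(f1$parsimony_count, 0L)
  expect_true(all(vapply(f1$state_sets, identical, logical(1), 1L)))

  split <- setNames(c(1, 1, 0, 0), c("a", "b", "c", "d"))
  f2 <- fitch_ancestral(tr, split)
  expect_equal(f2$parsimony_count, 1L)
  expect_setequal(f2$state_sets[[5]], c(0L, 1L))   # root ambiguous
  expect_equal(f2$node_states[5], 0L)              # tie resolved to 0

  expect_error(fitch_ancestral(tr, split[1:3]), "every tip")
})

test_that("Fitch counts equal brute-force minima on small trees", {
  for (i in 1:20) {
    n <- 4 + (i %% 5)
    tr <- random_small_tree(n, seed = 600 + i)
    withr::with_seed(700 + i,
      st <- setNames(rbinom(n, 1, 0.5), tr$tip.label))
    got <- fitch_ancestral(tr, st)$parsimony_count
    expect_equal(got, brute_force_parsimony(tr, st))
    # never more than the number of minority-state tips
    expect_lte(got, min(sum(st == 0), sum(st == 1)) + (length(unique(st)) == 1))
  }
})

test_that("Fitch agrees with phangorn's parsimony scores", {
  skip_if_not_installed("phangorn")
  for (i in 1:8) {
    n <- 10 + 3 * i
    tr <- random_small_tree(n, seed = 800 + i)
    withr::with_seed(900 + i,
      st <- setNames(rbinom(n, 1, 0.4), tr$tip.label))
    if (length(unique(st)) < 2) next
    dat <- phangorn::phyDat(matrix(st, ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = c(0, 1))
    expect_equal(fitch_ancestral(tr, st)$parsimony_count,
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("phenotype reconstruction solves squared-change parsimony exactly", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  const <- setNames(rep(3.5, 4), tr$tip.label)
  expect_true(all(abs(phenotype_ancestral(tr, const) - 3.5) < 1e-12))

  t2 <- ape::read.tree(text = "(a:1,b:1);")
  x2 <- phenotype_ancestral(t2, setNames(c(0, 1), c("a", "b")))
  expect_equal(unname(x2[3]), 0.5)

  for (i in 1:6) {
    tr6 <- random_small_tree(6, seed = 950 + i)
    withr::with_seed(960 + i, tv <- setNames(rnorm(6), tr6$tip.label))
    got <- phenotype_ancestral(tr6, tv)
    oracle <- wls_ancestral_oracle(tr6, tv)
    expect_lt(max(abs(got[7:11] - oracle)), 1e-8)
  }

  tz <- ape::read.tree(text = "((a:1,b:0):1,(c:1,d:1):1);")
  expect_warning(phenotype_ancestral(tz, setNames(1:4, c("a", "b", "c", "d"))),
                 "jitter")
})

test_that("the branch-agreement score behaves as a location-invariant contrast", {
  tr <- random_small_tree(20, seed = 42)
  withr::with_seed(43, tv <- setNames(rnorm(20), tr$tip.label))
  ph <- phenotype_ancestral(tr, tv)
  N <- 20 + tr$Nnode

  # constant phenotype: score 0
  expect_equal(subsequent_score(tr, rbinom(N, 1, 0.5), rep(2, N)), 0)

  # all-one genotype: undefined
  expect_true(is.na(subsequent_score(tr, rep(1L, N), ph)))

  # location invariance
  g <- rbinom(N, 1, 0.5)
  if (length(unique(g[tr$edge[, 2]])) == 2) {
    expect_equal(subsequent_score(tr, g, ph),
                 subsequent_score(tr, g, ph + 100), tolerance = 1e-9)
  }

  # genotype matching the high-phenotype clade scores higher than noise
  two <- ape::read.tree(text = "(((a:1,b:1):2,(c:1,d:1):2):1,((e:1,f:1):2,(g:1,h:1):2):1);")
  tv2 <- setNames(c(0, 0, 0, 0, 10, 10, 10, 10), letters[1:8])
  ph2 <- phenotype_ancestral(two, tv2)
  gt <- setNames(c(0, 0, 0, 0, 1, 1, 1, 1), letters[1:8])
  ft <- fitch_ancestral(two, gt)
  aligned <- subsequent_score(two, ft$node_states, ph2)
  gt_rand <- setNames(c(1, 0, 1, 0, 0, 1, 0, 1), letters[1:8])
  fr <- fitch_ancestral(two, gt_rand)
  expect_gt(aligned, subsequent_score(two, fr$node_states, ph2))
  # of the order of the between-clade difference of 10 (root-adjacent
  # branches shrink the reconstruction towards the grand mean)
  expect_gt(aligned, 6)
})

test_that("null re-placement weights branches by length", {
  expect_error(simulate_null_genotypes(random_small_tree(5, 1), 0, 10),
               "at least 1")
  tr <- random_small_tree(12, seed = 77)
  ns <- simulate_null_genotypes(tr, n_events = 1, n_sims = 20000, seed = 3)
  # recover which edge each single event hit from the child state
  counts <- numeric(nrow(tr$edge))
  # a single event on edge e makes exactly the clade below e state 1;
  # identify e by matching the tip-state pattern
  below <- lapply(seq_len(nrow(tr$edge)), function(e) {
    n <- length(tr$tip.label)
    tips <- if (tr$edge[e, 2] <= n) tr$edge[e, 2]
            else unlist(ape::prop.part(tr)[tr$edge[e, 2] - n])
    sort(tips)
  })
  key <- vapply(below, paste, character(1), collapse = ",")
  n <- length(tr$tip.label)
  for (s in seq_len(ncol(ns))) {
    tips <- sort(which(ns[seq_len(n), s] == 1L))
    e <- match(paste(tips, collapse = ","), key)
    counts[e] <- counts[e] + 1
  }
  expect_equal(sum(counts), 20000)
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = tr$edge.length / sum(tr$edge.length)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("the Wilcoxon comparison matches a brute-force rank-sum oracle", {
  withr::with_seed(8, {
    x <- runif(6); y <- runif(6)
  })
  got <- compare_groups(c(x, y), rep(c(TRUE, FALSE), each = 6))
  # Mann-Whitney U as R reports it: pairs where x > y (plus half-ties)
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(got$W, U)

  expect_error(compare_groups(runif(5), rep(TRUE, 5)), "non-empty")

  # stochastically smaller group: decisive one-sided p
  hits <- vapply(1:10, function(i) {
    withr::with_seed(1000 + i, {
      a <- rbeta(30, 1, 5); b <- runif(170)
    })
    compare_groups(c(a, b), c(rep(TRUE, 30), rep(FALSE, 170)))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # exchangeable labels: p roughly uniform
  ps <- vapply(1:60, function(i) {
    withr::with_seed(2000 + i, v <- runif(40))
    compare_groups(v, rep(c(TRUE, FALSE), 20))$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("the per-site test runs end to end with sane outputs", {
  cfg <- sim_config(n_tips = 60, n_countries = 6, n_sites = 12,
                    mutation_rate = 0.4, insertion_noise = 0L,
                    recurrent_sites = data.frame(site = 1, multiplier = 10),
                    reference_length = 60, seed = 55)
  ds <- simulate_dataset(cfg)
  geno <- call_variants(ds$alignment)
  lat <- setNames(ds$climate$latitude, ds$climate$country)
  phen <- setNames(lat[unname(ds$countries[geno$ids])], geno$ids)
  tt <- run_tree_test(ds$tree, geno, phen, n_sims = 200, seed = 4)
  scored <- !is.na(tt$table$p_value)
  expect_gt(sum(scored), 0)
  expect_true(all(tt$table$p_value[scored] > 0 & tt$table$p_value[scored] <= 1))
  expect_true(all(tt$table$fitch_count[scored] >= 1))
  # deterministic under the same seed
  tt2 <- run_tree_test(ds$tree, geno, phen, n_sims = 200, seed = 4)
  expect_identical(tt$table, tt2$table)
})
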