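test_that("coalescent trees are binary, ultrametric, with the expected TMRCA", {
  expect_error(simulate_tree(1), "at least 2")

  t2 <- simulate_tree(2, seed = 5)
  expect_equal(t2$Nnode, 1L)
  expect_equal(length(t2$tip.label), 2L)

  tr <- simulate_tree(25, seed = 9)
  expect_equal(tr$Nnode, 24L)            # n_tips - 1 internal nodes
  depth <- ape::node.depth.edgelength(tr)
  tipd <- depth[seq_len(25)]
  expect_lt(max(tipd) - min(tipd), 1e-9) # ultrametric

  # E[TMRCA] = 2 (1 - 1/n); Monte-Carlo with n = 10
  heights <- vapply(1:300, function(i) {
    max(ape::node.depth.edgelength(simulate_tree(10, seed = 1000 + i)))
  }, numeric(1))
  expect_lt(abs(mean(heights) - 2 * (1 - 1 / 10)), 0.15)
})

test_that("mutation dropping is a Poisson process with recurrence multipliers", {
  cfg <- sim_config(n_tips = 50, n_sites = 20, mutation_rate = 0,
                    recurrent_sites = data.frame(site = integer(0),
                                                 multiplier = numeric(0)),
                    reference_length = 100, seed = 3)
  tr <- simulate_tree(50, seed = 3)
  out <- drop_mutations(tr, cfg)
  expect_true(all(out$genotypes == 0L))
  expect_equal(nrow(out$event_log), 0L)

  cfg$mutation_rate <- -1
  expect_error(drop_mutations(tr, cfg), "non-negative")
  expect_error(sim_config(n_tips = 50, mutation_rate = -1))

  # a 50x recurrent site on a 200-tip tree almost always has >= 2 events
  hits <- vapply(1:50, function(i) {
    cfg <- sim_config(n_tips = 200, n_sites = 5, mutation_rate = 0.2,
                      recurrent_sites = data.frame(site = 1, multiplier = 50),
                      reference_length = 50, seed = 2000 + i)
    tr <- simulate_tree(200, seed = 2000 + i)
    ev <- drop_mutations(tr, cfg)$event_log
    sum(ev$site == 1)
  }, numeric(1))
  expect_gte(mean(hits >= 2), 0.95)
})

test_that("segregating-site counts match the coalescent expectation at low rates", {
  mu <- 0.005; n_tips <- 40; n_sites <- 500
  segs <- vapply(1:40, function(i) {
    cfg <- sim_config(n_tips = n_tips, n_sites = n_sites, mutation_rate = mu,
                      recurrent_sites = data.frame(site = integer(0),
                                                   multiplier = numeric(0)),
                      reference_length = n_sites, seed = 4000 + i)
    tr <- simulate_tree(n_tips, seed = 4000 + i)
    g <- drop_mutations(tr, cfg)$genotypes
    f <- colMeans(g)
    sum(f > 0 & f < 1)
  }, numeric(1))
  # for small mu, E[S] ~ n_sites * mu * E[total length], E[L] = 2 H_{n-1}
  expected <- n_sites * mu * 2 * sum(1 / seq_len(n_tips - 1))
  expect_lt(abs(mean(segs) - expected) / expected, 0.25)
})

test_that("country assignment interpolates between clades and uniform", {
  tr <- simulate_tree(40, seed = 2)
  expect_error(assign_countries(tr, 41), "n_countries")

  one <- assign_countries(tr, 1, seed = 1)
  expect_equal(length(unique(one)), 1L)

  # mixing = 0, two countries: both monophyletic
  a <- assign_countries(tr, 2, mixing = 0, country_size_skew = 0, seed = 7)
  for (cc in unique(a)) {
    expect_true(ape::is.monophyletic(tr, names(a)[a == cc]))
  }

  # mixing = 1, skew = 0: uniform multinomial counts
  pvals <- vapply(1:60, function(i) {
    tr <- simulate_tree(500, seed = 5000 + i)
    a <- assign_countries(tr, 10, mixing = 1, country_size_skew = 0,
                          seed = 5000 + i)
    counts <- table(factor(a, levels = sprintf("C%03d", 1:10)))
    suppressWarnings(stats::chisq.test(counts)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.93)
})

test_that("climate tables reproduce the requested correlation structure", {
  expect_error(generate_climate(10, c("a", "b"),
                                matrix(c(1, 2, 2, 1), 2)), "positive semi")

  # identity correlation: all pairwise |r| small at n = 500
  cl <- generate_climate(500, climate_correlation = diag(14), seed = 21)
  X <- as.matrix(cl[, -1])
  R <- cor(X)
  expect_lt(max(abs(R[upper.tri(R)])), 0.15)

  # perfectly correlated pair: identical columns
  R1 <- matrix(c(1, 0, 0, 0, 1, 1, 0, 1, 1), 3)
  cl2 <- generate_climate(50, c("lat", "p1", "p2"), R1, seed = 4)
  expect_equal(cl2$p1, cl2$p2, tolerance = 1e-12)

  # default matrix recovered within 0.1 (fixed seed)
  cl3 <- generate_climate(1000, seed = 8)
  emp <- cor(as.matrix(cl3[, -1]))
  expect_lt(max(abs(emp - default_climate_correlation())), 0.1)

  # latitude correlates with temperature-like predictors
  expect_lt(cor(cl3$latitude, cl3$paleo_bio1), -0.5)
})

test_that("selection injection creates predictor-aligned clines", {
  withr::with_seed(31, {
    n_c <- 50; per <- 40
    countries <- setNames(rep(sprintf("C%03d", 1:n_c), each = per),
                          sprintf("ind%05d", 1:(n_c * per)))
    G <- matrix(rbinom(n_c * per * 3, 1, 0.3), ncol = 3,
                dimnames = list(names(countries), NULL))
  })
  climate <- generate_climate(n_c, seed = 31)

  # effect 0: exact identity
  same <- inject_selection(G, countries, climate,
                           data.frame(site = 2, predictor = "latitude",
                                      effect = 0), seed = 1)
  expect_identical(same, G)

  spearman <- function(g) {
    agg <- tapply(g, countries[rownames(G)], mean)
    cor(agg[climate$country], climate$latitude, method = "spearman")
  }
  up <- inject_selection(G, countries, climate,
                         data.frame(site = 1, predictor = "latitude",
                                    effect = 3), seed = 2)
  expect_gt(spearman(up[, 1]), 0.8)
  down <- inject_selection(G, countries, climate,
                           data.frame(site = 1, predictor = "latitude",
                                      effect = -3), seed = 2)
  expect_lt(spearman(down[, 1]), -0.8)

  expect_error(inject_selection(G, countries, climate,
                                data.frame(site = 1, predictor = "nope",
                                           effect = 1)), "unknown predictor")
})

test_that("alignment embedding round-trips through variant calling", {
  withr::with_seed(11, {
    G <- matrix(rbinom(30 * 12, 1, 0.4), 30, 12,
                dimnames = list(sprintf("i%02d", 1:30), NULL))
  })
  emb <- genotypes_to_alignment(G, reference_length = 80, insertion_noise = 0,
                                seed = 5)
  expect_equal(ncol(emb$alignment$seqs), 80L)
  called <- call_variants(emb$alignment)
  expect_equal(called$sites$pos, emb$site_map$pos)
  expect_equal(unname(called$G[rownames(G), ]), unname(G))

  embn <- genotypes_to_alignment(G, reference_length = 80, insertion_noise = 4,
                                 seed = 5)
  expect_equal(ncol(embn$alignment$seqs), 84L)

  expect_error(genotypes_to_alignment(G, 80, positions = c(3, 3, 5:13)),
               "duplicate")

  # curation of the noisy alignment restores the clean genotypes
  cur <- iterative_gap_curation(embn$alignment)
  called2 <- call_variants(cur$alignment)
  keep <- intersect(rownames(G), called2$ids)
  expect_gte(length(keep), nrow(G) - 4)
  expect_equal(unname(called2$G[keep, ]), unname(G[keep, ]))
})

test_that("the generator is byte-reproducible from (config, seed)", {
  cfg <- sim_config(n_tips = 80, n_countries = 5, n_sites = 15,
                    reference_length = 60, seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$alignment$seqs, b$alignment$seqs)
  expect_identical(a$climate, b$climate)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})
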