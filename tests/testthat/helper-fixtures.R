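# Shared fixtures, all built in code.

# small alignment with optional private insertions
toy_alignment <- function(n_seq = 10, width = 30, seed = 1) {
  withr::with_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    M <- matrix(rep(ref, each = n_seq + 1), nrow = n_seq + 1)
    rownames(M) <- c(sprintf("s%04d", seq_len(n_seq)), "ref")
  })
  alignment_matrix(M, ref_id = "ref")
}

# insert a private insertion column after `after` carried by `carrier`
add_private_insertion <- function(aln, carrier, after, base = "A", k = 1) {
  M <- aln$seqs
  ins <- matrix("-", nrow(M), k)
  ins[match(carrier, rownames(M)), ] <- base
  M2 <- cbind(M[, seq_len(after), drop = FALSE], ins,
              M[, -seq_len(after), drop = FALSE])
  rownames(M2) <- rownames(M)
  colnames(M2) <- NULL
  alignment_matrix(M2, ref_id = aln$ref_id)
}

# grouped logistic data with a known random-intercept SD
toy_glmm_data <- function(n_groups = 3, per_group = 12, sigma = 0.3,
                          beta = c(-0.2, 0.5), seed = 1) {
  withr::with_seed(seed, {
    grp <- rep(sprintf("g%02d", seq_len(n_groups)), each = per_group)
    x <- rnorm(n_groups * per_group)
    u <- rnorm(n_groups, sd = sigma)
    y <- rbinom(length(x), 1, plogis(beta[1] + beta[2] * x + u[as.integer(factor(grp))]))
  })
  glmm_spec(y, cbind(1, x = x), grp)
}

# a small simulated scan-ready data set
small_scan_data <- function(seed = 1, n_tips = 600, n_countries = 12,
                            n_sites = 40, selected = NULL) {
  cfg <- sim_config(n_tips = n_tips, n_countries = n_countries,
                    n_sites = n_sites,
                    recurrent_sites = data.frame(site = 1:2, multiplier = 20),
                    insertion_noise = 0L, seed = seed)
  if (!is.null(selected)) cfg$selected_sites <- selected
  ds <- simulate_dataset(cfg)
  geno <- maf_filter(call_variants(ds$alignment), 5e-5)
  fc <- filter_countries(geno, ds$countries, min_country_n = 10,
                         max_country_n = 100000, seed = 1)
  pcs <- genotype_pca(fc$genotypes, 4)
  list(ds = ds, genotypes = fc$genotypes, countries = fc$countries,
       climate = ds$climate, pcs = pcs)
}

# random small rooted binary tree with exponential branch lengths
random_small_tree <- function(n_tips, seed) {
  withr::with_seed(seed, ape::rcoal(n_tips))
}

# brute-force minimal number of state changes of a binary character
brute_force_parsimony <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  ts <- as.integer(tip_states[tree$tip.label])
  best <- Inf
  for (code in 0:(2^m - 1)) {
    anc <- as.integer(intToBits(code))[seq_len(m)]
    states <- c(ts, anc)
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# weighted-least-squares oracle for squared-change parsimony:
# minimise sum over edges of (x_parent - x_child)^2 / length
wls_ancestral_oracle <- function(tree, tip_values) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  w <- 1 / tree$edge.length
  A <- matrix(0, m, m); b <- rep(0, m)
  tv <- tip_values[tree$tip.label]
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1] - n
    ch <- tree$edge[e, 2]
    A[pa, pa] <- A[pa, pa] + w[e]
    if (ch <= n) {
      b[pa] <- b[pa] + w[e] * tv[ch]
    } else {
      chm <- ch - n
      A[chm, chm] <- A[chm, chm] + w[e]
      A[pa, chm] <- A[pa, chm] - w[e]
      A[chm, pa] <- A[chm, pa] - w[e]
    }
  }
  solve(A, b)
}
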