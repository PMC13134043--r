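# Simplified phylogenetic subsequent test: Fitch reconstruction of the
# genotype, squared-change parsimony reconstruction of the (continuous)
# phenotype, a branch-agreement score, and a homoplasy-matched null that
# re-places the observed number of mutation events on branches.

#' Fitch parsimony reconstruction of a binary character
#'
#' Bottom-up pass computes the Fitch state-sets and the minimum number of
#' state changes; the top-down pass resolves each node to the parent-
#' compatible state, with ambiguity at the root (and any remaining ties)
#' resolved towards state 0.
#'
#' @param tree a rooted binary `phylo` tree.
#' @param tip_states named 0/1 vector covering every tip.
#' @return list with `node_states` (resolved 0/1 per node, tips first, in
#'   `phylo` node numbering), `state_sets` (list of sets per node), and
#'   `parsimony_count`.
#' @export
fitch_ancestral <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(tip_states)))
    stop("every tip needs a state")
  ts <- tip_states[tree$tip.label]
  if (any(is.na(ts)) || !all(ts %in% c(0, 1))) stop("tip states must be 0/1")
  N <- n + tree$Nnode
  # sets encoded as bit masks: 1 = {0}, 2 = {1}, 3 = {0,1}
  set <- integer(N)
  set[seq_len(n)] <- ifelse(ts == 0, 1L, 2L)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  count <- 0L
  i <- 1L
  nE <- nrow(po)
  while (i <= nE) {
    parent <- po[i, 1]
    j <- i
    while (j < nE && po[j + 1L, 1] == parent) j <- j + 1L
    kids <- po[i:j, 2]
    s <- set[kids[1]]
    for (k in kids[-1]) {
      inter <- bitwAnd(s, set[k])
      if (inter != 0L) s <- inter
      else { s <- bitwOr(s, set[k]); count <- count + 1L }
    }
    set[parent] <- s
    i <- j + 1L
  }
  states <- integer(N)
  states[seq_len(n)] <- as.integer(ts)
  root <- n + 1L
  states[root] <- if (set[root] == 2L) 1L else 0L   # ambiguous -> 0
  pr <- po[nrow(po):1, , drop = FALSE]               # preorder
  for (e in seq_len(nrow(pr))) {
    child <- pr[e, 2]
    if (child <= n) next
    ps <- states[pr[e, 1]]
    pbit <- if (ps == 0) 1L else 2L
    states[child] <- if (bitwAnd(set[child], pbit) != 0L) ps
                     else if (set[child] == 2L) 1L else 0L
  }
  sets <- lapply(set, function(s) c(0L, 1L)[c(bitwAnd(s, 1L) != 0, bitwAnd(s, 2L) != 0)])
  list(node_states = states, state_sets = sets, parsimony_count = count)
}

#' Squared-change parsimony reconstruction of a continuous phenotype
#'
#' Internal-node values minimising the branch-length-weighted sum of squared
#' changes (equivalently the Brownian-motion maximum-likelihood states),
#' computed by the standard two-pass linear scheme: a postorder pass
#' accumulates conditional values and effective variances, a preorder pass
#' blends each node's conditional value with its parent's final value.
#' Zero-length branches are jittered to 1e-9 with a warning.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param tip_values named numeric vector covering every tip.
#' @return numeric vector of node values (tips first, `phylo` numbering).
#' @export
phenotype_ancestral <- function(tree, tip_values) {
  n <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(tip_values)))
    stop("every tip needs a value")
  if (any(tree$edge.length <= 0)) {
    warning("zero-length branches jittered to 1e-9")
    tree$edge.length <- pmax(tree$edge.length, 1e-9)
  }
  N <- n + tree$Nnode
  v <- numeric(N); d <- numeric(N)
  v[seq_len(n)] <- tip_values[tree$tip.label]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  # postorder: conditional value v and effective variance d per node
  i <- 1L
  nE <- nrow(po)
  while (i <= nE) {
    parent <- po[i, 1]
    j <- i
    while (j < nE && po[j + 1L, 1] == parent) j <- j + 1L
    rows <- i:j
    wsum <- 0; vsum <- 0
    for (r in rows) {
      child <- po[r, 2]
      w <- 1 / (elen[r] + d[child])
      wsum <- wsum + w
      vsum <- vsum + w * v[child]
    }
    v[parent] <- vsum / wsum
    d[parent] <- 1 / wsum
    i <- j + 1L
  }
  x <- v
  root <- n + 1L
  x[root] <- v[root]
  pr_idx <- nrow(po):1
  for (e in pr_idx) {
    child <- po[e, 2]
    if (child <= n) next
    w1 <- 1 / d[child]
    w2 <- 1 / elen[e]
    x[child] <- (w1 * v[child] + w2 * x[po[e, 1]]) / (w1 + w2)
  }
  x[seq_len(n)] <- tip_values[tree$tip.label]
  x
}

#' Branch-agreement score between a genotype and a phenotype
#'
#' Each branch carries the reconstructed genotype of its child end and the
#' mean of its endpoint phenotype reconstructions. The score is the absolute
#' difference between the branch-length-weighted mean phenotype over
#' genotype-1 branches and over genotype-0 branches: large values mean the
#' allele and the phenotype co-distribute across the tree. Undefined (NA)
#' when all branches carry one genotype.
#'
#' @param tree a `phylo` tree.
#' @param genotype_states 0/1 per node (tips first, `phylo` numbering).
#' @param phenotype_values numeric per node (same ordering).
#' @return scalar score, or `NA_real_` when undefined.
#' @export
subsequent_score <- function(tree, genotype_states, phenotype_values) {
  g <- genotype_states[tree$edge[, 2]]
  ph <- (phenotype_values[tree$edge[, 1]] + phenotype_values[tree$edge[, 2]]) / 2
  w <- tree$edge.length
  if (all(g == 1) || all(g == 0)) return(NA_real_)
  abs(sum(w[g == 1] * ph[g == 1]) / sum(w[g == 1]) -
      sum(w[g == 0] * ph[g == 0]) / sum(w[g == 0]))
}

#' Homoplasy-matched null genotypes
#'
#' Re-places the observed number of mutation events uniformly on branches
#' (branch-length weighted, with replacement) and propagates the resulting
#' 0/1 toggles from the root, yielding null genotype configurations with the
#' same event count as the observed site.
#'
#' @param tree a `phylo` tree.
#' @param n_events number of events per simulation (`>= 1`).
#' @param n_sims number of simulations.
#' @param seed integer seed.
#' @return integer matrix of node states, `(n_tips + n_internal) x n_sims`
#'   (tip rows first); tip rows are the null genotypes.
#' @export
simulate_null_genotypes <- function(tree, n_events, n_sims, seed = 1L) {
  if (n_events < 1) stop("n_events must be at least 1 (monomorphic sites never reach the test)")
  E <- nrow(tree$edge)
  n <- length(tree$tip.label)
  withr::with_seed(seed, {
    ev <- matrix(sample.int(E, n_events * n_sims, replace = TRUE,
                            prob = tree$edge.length),
                 nrow = n_events)
  })
  parity <- matrix(0L, E, n_sims)
  for (k in seq_len(n_events)) {
    idx <- cbind(ev[k, ], seq_len(n_sims))
    parity[idx] <- parity[idx] + 1L
  }
  parity <- parity %% 2L
  pre <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(0L, n + tree$Nnode, n_sims)
  map <- match(paste(pre$edge[, 1], pre$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in seq_len(E)) {
    states[pre$edge[e, 2], ] <- bitwXor(states[pre$edge[e, 1], ],
                                        parity[map[e], ])
  }
  states
}

# vectorised subsequent scores over columns of a node-state matrix
scores_from_states <- function(tree, state_matrix, phenotype_values) {
  child <- tree$edge[, 2]
  ph <- (phenotype_values[tree$edge[, 1]] + phenotype_values[child]) / 2
  w <- tree$edge.length
  Tm <- state_matrix[child, , drop = FALSE]
  W1 <- as.numeric(w %*% Tm)
  S1 <- as.numeric((w * ph) %*% Tm)
  Wtot <- sum(w); Stot <- sum(w * ph)
  out <- abs(S1 / W1 - (Stot - S1) / (Wtot - W1))
  out[W1 == 0 | W1 == Wtot] <- NA_real_
  out
}

#' Run the subsequent test across sites
#'
#' For every polymorphic site: Fitch reconstruction of the genotype, the
#' branch-agreement score against the squared-change-parsimony phenotype
#' reconstruction, and an empirical p-value against `n_sims` homoplasy-
#' matched null re-placements with the site's own parsimony event count
#' (`p = (1 + #{null >= observed}) / (1 + n_sims)`).
#'
#' @param tree a `phylo` tree whose tips are the analysed individuals.
#' @param genotypes a [genotype_matrix()] covering the tree's tips.
#' @param phenotype named numeric vector per individual (e.g. the latitude
#'   of each individual's country).
#' @param n_sims null simulations per site (default 1000).
#' @param seed integer seed.
#' @return object of class `tree_test_result`: `table` (site, fitch_count,
#'   score, p_value) and `null_scores` (n_sims x sites matrix).
#' @export
run_tree_test <- function(tree, genotypes, phenotype, n_sims = 1000L, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!setequal(tree$tip.label, genotypes$ids))
    tree <- ape::keep.tip(tree, intersect(tree$tip.label, genotypes$ids))
  if (!all(tree$tip.label %in% genotypes$ids))
    stop("tree tips missing from genotype matrix")
  phen_nodes <- phenotype_ancestral(tree, phenotype)
  S <- ncol(genotypes$G)
  out <- data.frame(site = seq_len(S), fitch_count = NA_integer_,
                    score = NA_real_, p_value = NA_real_)
  nulls <- matrix(NA_real_, n_sims, S)
  ord <- match(tree$tip.label, genotypes$ids)
  for (j in seq_len(S)) {
    g <- genotypes$G[ord, j]
    names(g) <- tree$tip.label
    if (anyNA(g) || length(unique(g)) < 2) next
    fit <- fitch_ancestral(tree, g)
    out$fitch_count[j] <- fit$parsimony_count
    obs <- subsequent_score(tree, fit$node_states, phen_nodes)
    out$score[j] <- obs
    if (is.na(obs)) next
    ns <- simulate_null_genotypes(tree, fit$parsimony_count, n_sims,
                                  seed = subseed(seed, j))
    sc <- scores_from_states(tree, ns, phen_nodes)
    nulls[, j] <- sc
    out$p_value[j] <- (1 + sum(sc >= obs, na.rm = TRUE)) / (1 + n_sims)
  }
  structure(list(table = out, null_scores = nulls, n_sims = n_sims),
            class = "tree_test_result")
}

#' @export
print.tree_test_result <- function(x, ...) {
  cat("Subsequent test:", sum(!is.na(x$table$p_value)), "sites scored,",
      x$n_sims, "null draws each\n")
  invisible(x)
}

#' Compare subsequent-test p-values between linked and unlinked SNPs
#'
#' One-sided Wilcoxon rank-sum test of whether the p-values of SNPs linked
#' to scan candidates (`r^2 >` the linkage threshold) are stochastically
#' smaller than those of unlinked SNPs.
#'
#' @param tree_pvalues numeric vector of per-site empirical p-values.
#' @param linked_flags logical vector, same length.
#' @return list with `W` (rank-sum statistic) and `p_value`.
#' @export
compare_groups <- function(tree_pvalues, linked_flags) {
  ok <- !is.na(tree_pvalues) & !is.na(linked_flags)
  x <- tree_pvalues[ok & linked_flags]
  y <- tree_pvalues[ok & !linked_flags]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  wt <- wilcox.test(x, y, alternative = "less", exact = FALSE, correct = TRUE)
  list(W = unname(wt$statistic), p_value = wt$p.value)
}
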