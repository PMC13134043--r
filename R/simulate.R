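# Synthetic-data generator: coalescent genealogy, recurrent (homoplasic)
# mutation, clade-biased country assignment, correlated climate predictors,
# and injectable climate-driven allele-frequency clines.

#' Names of the simulated climate predictors
#'
#' Latitude and modern annual precipitation are the joint scan predictors;
#' the 12 "paleo" predictors are synthetic stand-ins for reconstructed
#' paleo-bioclimatic variables (annual/quarterly temperature and
#' precipitation summaries, leaf-area index) plus endemic plant species and
#' disease-outbreak counts.
#'
#' @return list with components `latprecip` (2 names) and `paleo` (12 names).
#' @export
climate_predictor_names <- function() {
  list(
    latprecip = c("latitude", "annual_precipitation"),
    paleo = c("paleo_bio1", "paleo_bio4", "paleo_bio8", "paleo_bio9",
              "paleo_bio10", "paleo_bio11", "paleo_bio12", "paleo_bio17",
              "paleo_bio19", "paleo_lai", "endemic_species", "outbreaks")
  )
}

# Two-factor loading matrix behind the default predictor correlation:
# f1 = latitudinal/thermal gradient, f2 = moisture gradient.
climate_loadings <- function() {
  nm <- unlist(climate_predictor_names(), use.names = FALSE)
  L <- rbind(
    latitude             = c(1.00,  0.00),
    annual_precipitation = c(0.00,  0.75),
    paleo_bio1           = c(-0.85, 0.00),
    paleo_bio4           = c(0.75, -0.20),
    paleo_bio8           = c(-0.70, 0.20),
    paleo_bio9           = c(-0.70, -0.10),
    paleo_bio10          = c(-0.80, 0.00),
    paleo_bio11          = c(-0.85, 0.00),
    paleo_bio12          = c(0.00,  0.85),
    paleo_bio17          = c(-0.10, 0.70),
    paleo_bio19          = c(0.10,  0.65),
    paleo_lai            = c(-0.50, 0.50),
    endemic_species      = c(-0.40, 0.30),
    outbreaks            = c(-0.35, 0.15)
  )
  stopifnot(identical(rownames(L), nm))
  L
}

#' Default correlation matrix over the simulated climate predictors
#'
#' Built from a two-latent-factor model (a latitudinal/thermal factor that
#' latitude loads on with weight 1, and a moisture factor), so temperature-
#' like predictors correlate strongly with latitude and precipitation-like
#' predictors correlate with each other. Positive semi-definite by
#' construction.
#'
#' @return 14 x 14 correlation matrix with unit diagonal.
#' @export
default_climate_correlation <- function() {
  L <- climate_loadings()
  R <- L %*% t(L)
  diag(R) <- 1
  R
}

#' Simulation configuration
#'
#' Collects every generator parameter. Defaults define the package's standard
#' study conditions: 2,000 individuals in 40 countries, 200 sites on a
#' 2,000-base reference, per-site mutation rate 0.2 per coalescent time unit,
#' ten recurrent sites at 20x rate, half-mixed clade/country structure,
#' moderately skewed country sizes, and the default climate correlation.
#'
#' @param n_tips number of individuals (tree tips).
#' @param n_countries number of countries.
#' @param n_sites number of simulated sites.
#' @param mutation_rate per-site mutation rate per unit branch length.
#' @param recurrent_sites data.frame with columns `site`, `multiplier`:
#'   sites whose mutation rate is multiplied (homoplasy generators).
#' @param selected_sites data.frame with columns `site`, `predictor`,
#'   `effect`: climate-coupled sites (log-odds effect per predictor SD).
#' @param mixing in `[0,1]`; 0 = countries are monophyletic clades,
#'   1 = uniform-multinomial assignment.
#' @param country_size_skew `>= 0`; Dirichlet concentration `1/skew` for
#'   country weights (0 = equal weights).
#' @param climate_correlation target predictor correlation matrix.
#' @param reference_length reference sequence length (bases).
#' @param insertion_noise number of sequences given a private insertion
#'   column (exercises curation).
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 2000L, n_countries = 40L, n_sites = 200L,
                       mutation_rate = 0.2,
                       recurrent_sites = data.frame(site = 1:10, multiplier = 20),
                       selected_sites = data.frame(site = integer(0),
                                                   predictor = character(0),
                                                   effect = numeric(0)),
                       mixing = 0.5, country_size_skew = 0.5,
                       climate_correlation = default_climate_correlation(),
                       reference_length = 2000L, insertion_noise = 5L,
                       seed = 1L) {
  stopifnot(n_tips >= 2, n_countries >= 1, n_sites >= 1, mutation_rate >= 0,
            mixing >= 0, mixing <= 1, country_size_skew >= 0,
            reference_length >= n_sites)
  if (nrow(selected_sites) &&
      (any(selected_sites$site < 1) || any(selected_sites$site > n_sites)))
    stop("selected_sites must index simulated sites")
  validate_correlation(climate_correlation)
  structure(as.list(environment()), class = "sim_config")
}

validate_correlation <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix must be positive semi-definite")
  invisible(R)
}

# deterministic sub-seed derivation, kept below 2^31
subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483629)
}

#' Simulate a Kingman-coalescent genealogy
#'
#' Rooted binary ultrametric tree: while `k` lineages remain, the next
#' coalescence time is exponential with rate `choose(k, 2)` (constant
#' population size), so the expected root height is `2 (1 - 1/n)`.
#'
#' @param n_tips number of tips (`>= 2`).
#' @param seed integer seed.
#' @return an [ape::rcoal()] `phylo` tree with tips `ind0001, ...`.
#' @export
simulate_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  withr::with_seed(seed,
    ape::rcoal(n_tips, tip.label = sprintf("ind%05d", seq_len(n_tips))))
}

#' Drop mutations on a tree as a Poisson process per branch
#'
#' Each site receives mutation events as a Poisson process along branches at
#' rate `mutation_rate` times the site's recurrence multiplier; every event
#' toggles the 0/1 allelic state inherited down the tree, so sites hit on
#' several branches are homoplasic (the same allele arises independently in
#' separate clades).
#'
#' @param tree a `phylo` tree.
#' @param config a [sim_config()] (uses `n_sites`, `mutation_rate`,
#'   `recurrent_sites`, `seed`).
#' @return list with `genotypes` (tips x sites 0/1 matrix, rows named by tip)
#'   and `event_log` (data.frame `site`, `edge` with one row per event;
#'   `edge` indexes rows of `tree$edge`).
#' @export
drop_mutations <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"))
  if (config$mutation_rate < 0) stop("mutation_rate must be non-negative")
  tree <- ape::reorder.phylo(tree, "cladewise")
  S <- config$n_sites
  rate <- rep(config$mutation_rate, S)
  rs <- config$recurrent_sites
  if (!is.null(rs) && nrow(rs)) {
    if (any(rs$multiplier < 0)) stop("recurrence multipliers must be non-negative")
    rate[rs$site] <- rate[rs$site] * rs$multiplier
  }
  E <- nrow(tree$edge)
  n <- length(tree$tip.label)
  withr::with_seed(subseed(config$seed, 2L), {
    lambda <- outer(tree$edge.length, rate)        # E x S
    events <- matrix(rpois(E * S, lambda), E, S)
  })
  state <- matrix(0L, n + tree$Nnode, S)
  parity <- events %% 2L
  for (e in seq_len(E)) {
    state[tree$edge[e, 2], ] <- bitwXor(state[tree$edge[e, 1], ], parity[e, ])
  }
  geno <- state[seq_len(n), , drop = FALSE]
  rownames(geno) <- tree$tip.label
  idx <- which(events > 0, arr.ind = TRUE)
  event_log <- data.frame(
    site = rep(idx[, 2], events[idx]),
    edge = rep(idx[, 1], events[idx])
  )
  event_log <- event_log[order(event_log$site, event_log$edge), , drop = FALSE]
  rownames(event_log) <- NULL
  list(genotypes = geno, event_log = event_log)
}

#' Assign tips to countries with tunable clade-country concordance
#'
#' With `mixing = 0` the tree is cut at the height where exactly
#' `n_countries` lineages exist, making each country a monophyletic clade;
#' with `mixing = 1` every tip is drawn independently from a multinomial over
#' countries. Intermediate values reassign each tip with probability
#' `mixing`. `country_size_skew > 0` draws unequal country weights from a
#' Dirichlet with concentration `1/skew`.
#'
#' @param tree a `phylo` tree (ultrametric for the clade cut).
#' @param n_countries number of countries (`1 <= n_countries <= n_tips`).
#' @param mixing,country_size_skew see [sim_config()].
#' @param seed integer seed.
#' @return named character vector of country labels, one per tip.
#' @export
assign_countries <- function(tree, n_countries, mixing = 0.5,
                             country_size_skew = 0.5, seed = 1L) {
  n <- length(tree$tip.label)
  if (n_countries < 1 || n_countries > n) stop("n_countries must be in [1, n_tips]")
  labels <- sprintf("C%03d", seq_len(n_countries))
  withr::with_seed(subseed(seed, 3L), {
    w <- if (country_size_skew > 0) {
      g <- rgamma(n_countries, shape = 1 / country_size_skew)
      g / sum(g)
    } else rep(1 / n_countries, n_countries)

    if (n_countries == 1L) {
      assignment <- rep(labels, n)
    } else {
      # cut the tree where exactly n_countries lineages exist
      depth <- ape::node.depth.edgelength(tree)
      height <- max(depth[seq_len(n)]) - depth
      internal <- sort(height[(n + 1):(n + tree$Nnode)], decreasing = TRUE)
      cut <- if (n_countries <= length(internal))
        mean(internal[c(n_countries - 1L, n_countries)])
      else internal[length(internal)] / 2
      cross <- which(height[tree$edge[, 1]] > cut & height[tree$edge[, 2]] <= cut)
      children <- split(tree$edge[, 2], tree$edge[, 1])
      assignment <- character(n)
      for (k in seq_along(cross)) {
        tips <- tips_below(tree, tree$edge[cross[k], 2], children)
        assignment[tips] <- labels[k]
      }
    }
    resample <- runif(n) < mixing
    if (any(resample)) {
      assignment[resample] <- sample(labels, sum(resample), replace = TRUE, prob = w)
    }
  })
  names(assignment) <- tree$tip.label
  assignment
}

# tip indices descending from a node (the node itself if a tip);
# `children` is split(tree$edge[,2], tree$edge[,1]) precomputed by the caller
tips_below <- function(tree, node, children = split(tree$edge[, 2], tree$edge[, 1])) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, children[[as.character(v)]])
  }
  out
}

#' Generate a per-country climate table with a target correlation
#'
#' Draws standard-normal predictors with the requested correlation matrix.
#' Latitude (the first predictor) is set equal to the leading latent factor,
#' so it is exactly monotone in it; the remaining predictors are drawn
#' conditionally, preserving the target correlation even when it is singular
#' (perfectly correlated predictors come out identical).
#'
#' @param n_countries number of countries (rows).
#' @param predictor_names character vector of column names; defaults to the
#'   14 standard predictors.
#' @param climate_correlation target correlation matrix (symmetric PSD, unit
#'   diagonal), ordered as `predictor_names`.
#' @param seed integer seed.
#' @return data.frame with `country` plus one column per predictor.
#' @export
generate_climate <- function(n_countries,
                             predictor_names = unlist(climate_predictor_names(),
                                                      use.names = FALSE),
                             climate_correlation = default_climate_correlation(),
                             seed = 1L) {
  R <- as.matrix(climate_correlation)
  validate_correlation(R)
  p <- length(predictor_names)
  if (nrow(R) != p) stop("correlation matrix must match predictor_names")
  withr::with_seed(subseed(seed, 4L), {
    z1 <- rnorm(n_countries)
    X <- matrix(0, n_countries, p)
    X[, 1] <- z1
    if (p > 1) {
      b <- R[-1, 1, drop = FALSE]                    # regression on factor 1
      Sc <- R[-1, -1, drop = FALSE] - b %*% t(b)     # conditional covariance
      es <- eigen((Sc + t(Sc)) / 2, symmetric = TRUE)
      lam <- pmax(es$values, 0)
      Lr <- es$vectors %*% diag(sqrt(lam), length(lam))
      Z <- matrix(rnorm(n_countries * (p - 1)), n_countries)
      X[, -1] <- z1 %*% t(b) + Z %*% t(Lr)
    }
  })
  colnames(X) <- predictor_names
  data.frame(country = sprintf("C%03d", seq_len(n_countries)), X,
             check.names = FALSE)
}

#' Inject climate-coupled selection at designated sites
#'
#' For each selected site, every individual's alternative-allele state is
#' re-drawn as Bernoulli with probability
#' `plogis(qlogis(p0) + effect * z)`, where `p0` is the site's observed
#' alternative-allele frequency (clamped away from 0/1) and `z` the
#' standardized predictor value of the individual's country. Independent
#' per-individual redraws deliberately break the site's linkage with the
#' genealogy, mimicking recurrent climate-favoured alleles. Sites with
#' `effect = 0` and non-selected sites are returned unchanged.
#'
#' @param genotypes tips x sites 0/1 matrix (rows named by individual).
#' @param countries named country vector as from [assign_countries()].
#' @param climate climate table as from [generate_climate()].
#' @param selected_sites data.frame `site`, `predictor`, `effect`.
#' @param seed integer seed.
#' @param baseline_clamp numeric length-2: clamp range for `p0`.
#' @return modified genotype matrix.
#' @export
inject_selection <- function(genotypes, countries, climate, selected_sites,
                             seed = 1L, baseline_clamp = c(0.05, 0.95)) {
  if (!nrow(selected_sites)) return(genotypes)
  preds <- setdiff(colnames(climate), "country")
  sel <- selected_sites
  if (is.numeric(sel$predictor)) sel$predictor <- preds[sel$predictor]
  if (any(is.na(sel$predictor)) || !all(sel$predictor %in% preds))
    stop("unknown predictor in selected_sites")
  if (any(sel$site < 1 | sel$site > ncol(genotypes)))
    stop("selected site outside genotype matrix")
  if (any(!is.finite(sel$effect))) stop("effect sizes must be finite")
  ctry <- countries[rownames(genotypes)]
  withr::with_seed(subseed(seed, 5L), {
    for (k in seq_len(nrow(sel))) {
      if (sel$effect[k] == 0) next
      zc <- as.numeric(scale(climate[[sel$predictor[k]]]))
      names(zc) <- climate$country
      z <- zc[ctry]
      g <- genotypes[, sel$site[k]]
      p0 <- min(max(mean(g, na.rm = TRUE), baseline_clamp[1]), baseline_clamp[2])
      p <- plogis(qlogis(p0) + sel$effect[k] * z)
      genotypes[, sel$site[k]] <- rbinom(length(p), 1L, p)
    }
  })
  genotypes
}

#' Embed simulated genotypes into a gapped reference alignment
#'
#' Sites are placed at distinct 1-based reference positions; the alternative
#' allele is a fixed transition of the reference base. With
#' `insertion_noise = k`, `k` sequences each receive one private insertion
#' column (gap in the reference and all other sequences), widening the
#' alignment by `k` columns — the pattern the iterative gap curation removes.
#'
#' @param genotypes tips x sites 0/1 matrix (NA allowed, becomes `N`).
#' @param reference_length reference length (`>= n_sites`).
#' @param insertion_noise number of sequences given a private insertion.
#' @param seed integer seed.
#' @param positions optional distinct 1-based site positions.
#' @param ref_id reference row identifier.
#' @return list with `alignment` (an [alignment_matrix()]) and `site_map`
#'   (data.frame `site`, `pos`, `ref`, `alt`).
#' @export
genotypes_to_alignment <- function(genotypes, reference_length,
                                   insertion_noise = 0L, seed = 1L,
                                   positions = NULL, ref_id = "reference") {
  S <- ncol(genotypes)
  if (reference_length < S) stop("reference_length must be >= number of sites")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  withr::with_seed(subseed(seed, 6L), {
    refseq <- sample(c("A", "C", "G", "T"), reference_length, replace = TRUE)
    if (is.null(positions)) positions <- sort(sample.int(reference_length, S))
    if (anyDuplicated(positions)) stop("duplicate site positions")
    ref_al <- refseq[positions]
    alt_al <- unname(transition[ref_al])
    ids <- rownames(genotypes)
    M <- matrix(rep(refseq, each = length(ids)), nrow = length(ids))
    for (j in seq_len(S)) {
      g <- genotypes[, j]
      M[which(g == 1L), positions[j]] <- alt_al[j]
      M[which(is.na(g)), positions[j]] <- "N"
    }
    M <- rbind(M, refseq)
    rownames(M) <- c(ids, ref_id)
    if (insertion_noise > 0) {
      carriers <- sample(seq_along(ids), insertion_noise)
      at <- sort(sample.int(reference_length - 1L, insertion_noise))
      out <- vector("list", insertion_noise + 1L)
      prev <- 0L
      for (k in seq_len(insertion_noise)) {
        out[[k]] <- M[, (prev + 1L):at[k], drop = FALSE]
        ins <- rep("-", nrow(M))
        ins[carriers[k]] <- sample(c("A", "C", "G", "T"), 1)
        out[[k]] <- cbind(out[[k]], ins)
        prev <- at[k]
      }
      out[[insertion_noise + 1L]] <- M[, (prev + 1L):reference_length, drop = FALSE]
      M <- do.call(cbind, out)
      colnames(M) <- NULL
    }
  })
  list(alignment = alignment_matrix(M, ref_id = ref_id),
       site_map = data.frame(site = seq_len(S), pos = positions,
                             ref = ref_al, alt = alt_al))
}

#' Pick candidate sites for selection injection
#'
#' Chooses `n` sites with minor-allele frequency at least `min_maf`
#' (common variants, as climate-coupled candidates are expected to be),
#' avoiding designated recurrent sites unless too few remain.
#'
#' @param genotypes 0/1 matrix.
#' @param n number of sites.
#' @param min_maf minimum minor-allele frequency.
#' @param avoid site indices to avoid.
#' @param seed integer seed.
#' @return integer site indices.
#' @export
choose_selected_sites <- function(genotypes, n, min_maf = 0.1,
                                  avoid = integer(0), seed = 1L) {
  f <- colMeans(genotypes, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  pool <- setdiff(which(maf >= min_maf), avoid)
  if (length(pool) < n) pool <- which(maf >= min_maf)
  if (length(pool) < n) stop("not enough common sites to select from")
  withr::with_seed(subseed(seed, 7L), sort(sample(pool, n)))
}

#' Simulate a complete study data set
#'
#' Runs the generator end to end: coalescent tree, mutation dropping,
#' country assignment, climate table, selection injection, and embedding into
#' a gapped alignment. All stages are seeded from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `alignment`, `site_map`, `genotypes`
#'   (post-selection truth matrix), `event_log`, `countries`, `climate`,
#'   `truth` (per-site selection table), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_tree(config$n_tips, seed = subseed(config$seed, 1L))
  mut <- drop_mutations(tree, config)
  countries <- assign_countries(tree, config$n_countries, config$mixing,
                                config$country_size_skew, seed = config$seed)
  climate <- generate_climate(config$n_countries,
                              climate_correlation = config$climate_correlation,
                              seed = config$seed)
  geno <- inject_selection(mut$genotypes, countries, climate,
                           config$selected_sites, seed = config$seed)
  emb <- genotypes_to_alignment(geno, config$reference_length,
                                insertion_noise = config$insertion_noise,
                                seed = config$seed)
  truth <- data.frame(site = seq_len(config$n_sites),
                      pos = emb$site_map$pos,
                      selected = FALSE, predictor = NA_character_,
                      effect = 0)
  if (nrow(config$selected_sites)) {
    sel <- config$selected_sites
    preds <- setdiff(colnames(climate), "country")
    if (is.numeric(sel$predictor)) sel$predictor <- preds[sel$predictor]
    truth$selected[sel$site] <- sel$effect != 0
    truth$predictor[sel$site] <- sel$predictor
    truth$effect[sel$site] <- sel$effect
  }
  list(tree = tree, alignment = emb$alignment, site_map = emb$site_map,
       genotypes = geno, event_log = mut$event_log, countries = countries,
       climate = climate, truth = truth, config = config)
}
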