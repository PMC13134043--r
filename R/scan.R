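# Per-SNP likelihood-ratio scans: joint latitude + annual-precipitation
# alternative models, single-predictor paleo-bioclimatic alternatives,
# Bonferroni control, dispersion/convergence filtering, candidate
# clustering and competitive predictor assignment.

#' Scan configuration
#'
#' @param alpha family-wise significance level (default 0.01).
#' @param r2_cluster squared-correlation threshold for clustering candidate
#'   genotypes (default 0.2, edges where `r^2 >` threshold).
#' @param r2_linked squared-correlation threshold for calling a SNP "linked"
#'   to a candidate (default 0.5).
#' @param dispersion_min minimum Pearson dispersion ratio of the null model
#'   (default 0.8; lower ratios are filtered).
#' @param n_pcs number of ancestry principal components in the null model
#'   (default 4).
#' @param predictors_latprecip the two joint scan predictors.
#' @param predictors_paleo the 12 single-predictor alternatives, in the
#'   declared tie-breaking order.
#' @param glmm_method passed to [fit_glmm()].
#' @return list of class `scan_config`.
#' @export
scan_config <- function(alpha = 0.01, r2_cluster = 0.2, r2_linked = 0.5,
                        dispersion_min = 0.8, n_pcs = 4L,
                        predictors_latprecip = climate_predictor_names()$latprecip,
                        predictors_paleo = climate_predictor_names()$paleo,
                        glmm_method = "profile") {
  stopifnot(alpha > 0, alpha < 1, r2_cluster > 0, r2_cluster < 1,
            r2_linked > 0, r2_linked < 1, dispersion_min >= 0)
  structure(as.list(environment()), class = "scan_config")
}

# country-standardized predictor columns broadcast to individuals
predictor_columns <- function(climate, countries, vars) {
  missing_vars <- setdiff(vars, colnames(climate))
  if (length(missing_vars))
    stop("predictors not in climate table: ", paste(missing_vars, collapse = ", "))
  idx <- match(unname(countries), climate$country)
  if (anyNA(idx)) stop("countries missing from climate table")
  Z <- vapply(vars, function(v) as.numeric(scale(climate[[v]]))[idx],
              numeric(length(countries)))
  Z <- matrix(Z, ncol = length(vars), dimnames = list(NULL, vars))
  Z
}

# shared per-SNP null-model pass: fits intercept + PCs + random country
# intercept, applies the convergence and dispersion filters
null_model_pass <- function(G, pcs, countries, config) {
  S <- ncol(G)
  Xpc <- pcs$scores[, seq_len(config$n_pcs), drop = FALSE]
  fits <- vector("list", S)
  reason <- rep("none", S)
  dispersion <- rep(NA_real_, S)
  for (j in seq_len(S)) {
    ok <- !is.na(G[, j])
    spec0 <- glmm_spec(G[ok, j], cbind(`(Intercept)` = 1, Xpc[ok, , drop = FALSE]),
                       countries[ok])
    f0 <- fit_glmm(spec0, method = config$glmm_method)
    if (!f0$converged) {
      reason[j] <- "nonconvergence"
    } else {
      dispersion[j] <- f0$dispersion
      if (f0$dispersion < config$dispersion_min) reason[j] <- "dispersion"
    }
    fits[[j]] <- list(fit = f0, spec = spec0, ok = ok)
  }
  list(fits = fits, reason = reason, dispersion = dispersion)
}

#' Latitude + annual-precipitation association scan
#'
#' For every SNP, fits the null model (intercept, ancestry PCs 1..`n_pcs`,
#' random country intercept) and the alternative adding country-standardized
#' latitude and annual precipitation as joint fixed effects, and compares
#' them with a 2-df likelihood-ratio test. SNPs whose null model fails to
#' converge or has Pearson dispersion below `dispersion_min` are filtered
#' before multiple-testing correction; the Bonferroni threshold is
#' `alpha / n_tested` over the surviving SNPs. Candidates (p below the
#' threshold) are clustered at `r^2 > r2_cluster` and each cluster's most
#' significant member flagged as representative.
#'
#' @param genotypes a [genotype_matrix()].
#' @param pcs per-individual `pc_scores` from [genotype_pca()].
#' @param countries named country vector.
#' @param climate per-country climate table.
#' @param config a [scan_config()].
#' @param null_pass optional precomputed null-model pass (internal reuse).
#' @return object of class `scan_result`: per-site `table` (site, pos,
#'   statistic, p_value, filtered_reason, candidate, cluster,
#'   representative), `n_tested`, `bonferroni_threshold`, `alpha`, `df`,
#'   and the retained null fits.
#' @export
run_latprecip_scan <- function(genotypes, pcs, countries, climate,
                               config = scan_config(), null_pass = NULL) {
  G <- genotypes$G
  S <- ncol(G)
  if (S == 0) stop("no SNPs to scan")
  Z <- predictor_columns(climate, countries[genotypes$ids],
                         config$predictors_latprecip)
  if (is.null(null_pass))
    null_pass <- null_model_pass(G, pcs, countries[genotypes$ids], config)

  stat <- p <- rep(NA_real_, S)
  reason <- null_pass$reason
  for (j in seq_len(S)) {
    if (reason[j] != "none") next
    np <- null_pass$fits[[j]]
    ok <- np$ok
    Xalt <- cbind(np$spec$X, Z[ok, , drop = FALSE])
    fa <- fit_glmm(glmm_spec(G[ok, j], Xalt, countries[genotypes$ids][ok]),
                   method = config$glmm_method,
                   beta_init = c(np$fit$beta, 0, 0))
    if (!fa$converged) { reason[j] <- "nonconvergence"; next }
    lrt <- likelihood_ratio_test(np$fit, fa, df = length(config$predictors_latprecip))
    stat[j] <- lrt$statistic
    p[j] <- lrt$p_value
  }
  tested <- reason == "none"
  n_tested <- sum(tested)
  if (n_tested == 0) stop("no SNPs survive the scan filters")
  thr <- config$alpha / n_tested
  candidate <- tested & !is.na(p) & p < thr

  tab <- data.frame(site = seq_len(S), pos = genotypes$sites$pos,
                    statistic = stat, p_value = p, filtered_reason = reason,
                    dispersion = null_pass$dispersion,
                    candidate = candidate, cluster = NA_integer_,
                    representative = FALSE)
  if (any(candidate)) {
    cl <- cluster_candidates(genotypes, which(candidate), p[candidate],
                             r2_threshold = config$r2_cluster)
    tab$cluster[cl$site] <- cl$cluster
    tab$representative[cl$site] <- cl$representative
  }
  structure(list(table = tab, n_tested = n_tested, bonferroni_threshold = thr,
                 alpha = config$alpha, df = length(config$predictors_latprecip),
                 config = config, null_pass = null_pass),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("GEA scan:", x$n_tested, "SNPs tested, threshold",
      format(signif(x$bonferroni_threshold, 3)), "-",
      sum(x$table$candidate), "candidates\n")
  invisible(x)
}

#' Sequential principal-component drop tests
#'
#' Starting from the fitted latitude + precipitation alternative model for
#' one SNP, removes each ancestry PC in turn (highest first) and reports the
#' 1-df likelihood-ratio test of the removal against the full alternative.
#' Also reports whether at least one PC is individually significant at
#' `alpha` (raw p-values; any multiplicity correction is left to the
#' caller's configuration).
#'
#' @param genotypes a [genotype_matrix()].
#' @param site site index to test.
#' @param pcs,countries,climate,config as in [run_latprecip_scan()].
#' @return list with `table` (pc, statistic, p_value) and
#'   `any_pc_significant`.
#' @export
drop_pc_tests <- function(genotypes, site, pcs, countries, climate,
                          config = scan_config()) {
  ctry <- countries[genotypes$ids]
  y <- genotypes$G[, site]
  ok <- !is.na(y)
  Xpc <- pcs$scores[, seq_len(config$n_pcs), drop = FALSE]
  Z <- predictor_columns(climate, ctry, config$predictors_latprecip)
  Xfull <- cbind(`(Intercept)` = 1, Xpc, Z)[ok, , drop = FALSE]
  full <- fit_glmm(glmm_spec(y[ok], Xfull, ctry[ok]), method = config$glmm_method)
  if (!full$converged) stop("alternative model did not converge for this site")
  out <- data.frame(pc = paste0("PC", rev(seq_len(config$n_pcs))),
                    statistic = NA_real_, p_value = NA_real_)
  for (i in seq_len(config$n_pcs)) {
    k <- config$n_pcs - i + 1L
    Xred <- Xfull[, setdiff(colnames(Xfull), paste0("PC", k)), drop = FALSE]
    red <- fit_glmm(glmm_spec(y[ok], Xred, ctry[ok]),
                    method = config$glmm_method, beta_init = NULL)
    lrt <- likelihood_ratio_test(red, full, df = 1)
    out$statistic[i] <- lrt$statistic
    out$p_value[i] <- lrt$p_value
  }
  list(table = out, any_pc_significant = any(out$p_value < config$alpha))
}

#' Cluster candidate SNPs by genotype correlation
#'
#' Pairwise squared Pearson correlation between candidate genotype vectors
#' (pairwise-complete over non-missing entries) defines a graph with edges
#' where `r^2 >` the threshold; clusters are its connected components and
#' each cluster's representative is the member with the smallest p-value
#' (ties broken towards the smaller site index). Candidates with zero
#' genotype variance are excluded with a warning.
#'
#' @param genotypes a [genotype_matrix()] or plain matrix.
#' @param candidate_sites integer site indices.
#' @param p_values p-values aligned with `candidate_sites`.
#' @param r2_threshold clustering threshold.
#' @return data.frame `site`, `cluster`, `representative`, `p_value`.
#' @export
cluster_candidates <- function(genotypes, candidate_sites, p_values,
                               r2_threshold = 0.2) {
  if (!length(candidate_sites)) stop("no candidate sites to cluster")
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$G else genotypes
  M <- G[, candidate_sites, drop = FALSE]
  v <- apply(M, 2, function(x) var(x, na.rm = TRUE))
  if (any(v == 0 | is.na(v))) {
    warning("excluding zero-variance candidates from clustering")
    keep <- which(v > 0 & !is.na(v))
    candidate_sites <- candidate_sites[keep]
    p_values <- p_values[keep]
    M <- M[, keep, drop = FALSE]
  }
  k <- length(candidate_sites)
  if (k == 0) return(data.frame(site = integer(0), cluster = integer(0),
                                representative = logical(0), p_value = numeric(0)))
  r2 <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  adj <- (r2 > r2_threshold)
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  rep_flag <- logical(k)
  for (cl in unique(comp)) {
    members <- which(comp == cl)
    best <- members[order(p_values[members], candidate_sites[members])][1]
    rep_flag[best] <- TRUE
  }
  data.frame(site = candidate_sites, cluster = as.integer(comp),
             representative = rep_flag, p_value = p_values)
}

#' Single-predictor paleo-bioclimatic association scan
#'
#' For the SNP set that survived the null-model filters, fits one
#' alternative model per paleo predictor (the predictor replacing latitude
#' and precipitation as the single added fixed effect) and compares each to
#' the same null with a 1-df likelihood-ratio test. The Bonferroni threshold
#' is `alpha / (n_tested * n_predictors)`. A SNP is a candidate if at least
#' one predictor passes; its assigned predictor is the most significant one
#' (ties broken by the declared predictor order). Candidates are clustered
#' as in [run_latprecip_scan()] using each SNP's smallest p-value.
#'
#' @inheritParams run_latprecip_scan
#' @param latprecip optional `scan_result` whose null fits and filter status
#'   are reused, guaranteeing the same SNP set.
#' @return object of class `paleo_scan_result`: `table` (site, pos,
#'   filtered_reason, min_p, candidate, assigned_predictor, cluster,
#'   representative), per-predictor p-value matrix `p_matrix`,
#'   `n_tested`, `bonferroni_threshold`.
#' @export
run_paleobio_scan <- function(genotypes, pcs, countries, climate,
                              config = scan_config(), latprecip = NULL) {
  preds <- config$predictors_paleo
  if (!length(preds)) stop("no paleo predictors supplied")
  G <- genotypes$G
  S <- ncol(G)
  ctry <- countries[genotypes$ids]
  Z <- predictor_columns(climate, ctry, preds)
  null_pass <- if (!is.null(latprecip)) latprecip$null_pass
               else null_model_pass(G, pcs, ctry, config)
  reason <- null_pass$reason
  P <- matrix(NA_real_, S, length(preds), dimnames = list(NULL, preds))
  Tst <- P
  for (j in seq_len(S)) {
    if (reason[j] != "none") next
    np <- null_pass$fits[[j]]
    ok <- np$ok
    for (v in seq_along(preds)) {
      Xalt <- cbind(np$spec$X, Z[ok, v, drop = FALSE])
      fa <- fit_glmm(glmm_spec(G[ok, j], Xalt, ctry[ok]),
                     method = config$glmm_method,
                     beta_init = c(np$fit$beta, 0))
      if (!fa$converged) next
      lrt <- likelihood_ratio_test(np$fit, fa, df = 1)
      Tst[j, v] <- lrt$statistic
      P[j, v] <- lrt$p_value
    }
  }
  tested <- reason == "none"
  n_tested <- sum(tested)
  if (n_tested == 0) stop("no SNPs survive the scan filters")
  thr <- config$alpha / (n_tested * length(preds))
  min_p <- suppressWarnings(apply(P, 1, min, na.rm = TRUE))
  min_p[!is.finite(min_p)] <- NA_real_
  candidate <- tested & !is.na(min_p) & min_p < thr
  assigned <- rep(NA_character_, S)
  for (j in which(candidate)) {
    # ties broken by declared predictor order (preds ordering)
    assigned[j] <- preds[which(P[j, ] == min_p[j])[1]]
  }
  tab <- data.frame(site = seq_len(S), pos = genotypes$sites$pos,
                    filtered_reason = reason, min_p = min_p,
                    candidate = candidate, assigned_predictor = assigned,
                    cluster = NA_integer_, representative = FALSE)
  if (any(candidate)) {
    cl <- cluster_candidates(genotypes, which(candidate), min_p[candidate],
                             r2_threshold = config$r2_cluster)
    tab$cluster[cl$site] <- cl$cluster
    tab$representative[cl$site] <- cl$representative
  }
  structure(list(table = tab, p_matrix = P, stat_matrix = Tst,
                 n_tested = n_tested, bonferroni_threshold = thr,
                 alpha = config$alpha, predictors = preds, config = config),
            class = "paleo_scan_result")
}

#' @export
print.paleo_scan_result <- function(x, ...) {
  cat("Paleo-bioclimatic scan:", x$n_tested, "SNPs x", length(x$predictors),
      "predictors, threshold", format(signif(x$bonferroni_threshold, 3)), "-",
      sum(x$table$candidate), "candidates\n")
  invisible(x)
}

#' Overlap between the joint and paleo-predictor scans
#'
#' Counts paleo candidates that are also latitude/precipitation candidates
#' (shared), those in strong linkage (`r^2 > r2_linked`) with at least one
#' latitude/precipitation candidate without being one (linked), and the
#' rest (unshared).
#'
#' @param latprecip a `scan_result`.
#' @param paleo a `paleo_scan_result` on the same individuals.
#' @param genotypes the [genotype_matrix()] both scans used.
#' @param r2_linked linkage threshold.
#' @return list with index vectors `shared`, `linked`, `unshared` and the
#'   corresponding counts.
#' @export
compare_scans <- function(latprecip, paleo, genotypes, r2_linked = 0.5) {
  lp <- latprecip$table$site[latprecip$table$candidate]
  pb <- paleo$table$site[paleo$table$candidate]
  shared <- intersect(pb, lp)
  rest <- setdiff(pb, shared)
  linked <- integer(0)
  if (length(rest) && length(lp)) {
    G <- genotypes$G
    r2 <- suppressWarnings(
      cor(G[, rest, drop = FALSE], G[, lp, drop = FALSE],
          use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    linked <- rest[apply(r2, 1, max) > r2_linked]
  }
  unshared <- setdiff(rest, linked)
  list(shared = shared, linked = linked, unshared = unshared,
       n_shared = length(shared), n_linked = length(linked),
       n_unshared = length(unshared))
}
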