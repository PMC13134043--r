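# Principal-component summaries of shared ancestry (genotype PCA) and of
# climate space (environmental PCA).

new_pc_scores <- function(ids, scores, var_explained) {
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- ids
  structure(list(ids = ids, scores = scores, var_explained = var_explained),
            class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat("PC scores:", nrow(x$scores), "units x", ncol(x$scores), "components;",
      "variance fractions:", paste(signif(x$var_explained, 3), collapse = " "), "\n")
  invisible(x)
}

#' Principal components of a genotype matrix
#'
#' Column-centred (optionally unit-variance-scaled) PCA of the 0/1 genotype
#' matrix by singular value decomposition; missing genotypes are imputed to
#' the column mean before centring. The sign of each component is fixed by
#' making its largest-magnitude loading positive, so output is deterministic.
#'
#' @param genotypes a [genotype_matrix()] or plain 0/1 matrix with row names.
#' @param n_components number of components (default 4).
#' @param scale. logical; unit-variance scaling of sites (default `FALSE`,
#'   plain covariance PCA).
#' @return a `pc_scores` object: per-individual `scores`
#'   (individuals x components) and `var_explained` fractions.
#' @export
genotype_pca <- function(genotypes, n_components = 4L, scale. = FALSE) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$G else as.matrix(genotypes)
  ids <- rownames(G)
  if (ncol(G) < n_components) stop("fewer sites than requested components")
  if (nrow(G) < n_components + 1) stop("need at least n_components + 1 individuals")
  G <- apply(G, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  })
  G <- scale(G, center = TRUE, scale = FALSE)
  if (scale.) {
    s <- apply(G, 2, sd)
    G[, s > 0] <- sweep(G[, s > 0, drop = FALSE], 2, s[s > 0], "/")
  }
  sv <- svd(G, nu = n_components, nv = n_components)
  d2 <- sv$d^2
  ve <- if (sum(d2) > 0) d2[seq_len(n_components)] / sum(d2) else rep(0, n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) scores[, k] <- -scores[, k]
  }
  new_pc_scores(ids, scores, ve)
}

#' Principal components of the climate table
#'
#' PCA of the standardized per-country predictor columns; constant columns
#' are dropped with a warning. Scores are per country and can be broadcast
#' to individuals through their country assignment.
#'
#' @param climate data.frame with `country` plus predictor columns.
#' @param n_components number of components (default 1).
#' @param countries optional named country vector; when given, scores are
#'   broadcast to individuals (ids = individual IDs).
#' @return a `pc_scores` object.
#' @export
environmental_pca <- function(climate, n_components = 1L, countries = NULL) {
  X <- as.matrix(climate[, setdiff(colnames(climate), "country"), drop = FALSE])
  const <- apply(X, 2, sd) == 0
  if (any(const)) {
    warning("dropping constant predictor columns: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 2) stop("need at least two non-constant predictors")
  X <- scale(X)
  sv <- svd(X, nu = n_components, nv = n_components)
  d2 <- sv$d^2
  ve <- d2[seq_len(n_components)] / sum(d2)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) scores[, k] <- -scores[, k]
  }
  pcs <- new_pc_scores(climate$country, scores, ve)
  if (!is.null(countries)) {
    idx <- match(unname(countries), climate$country)
    if (anyNA(idx)) stop("countries not present in climate table")
    pcs <- new_pc_scores(names(countries),
                         pcs$scores[idx, , drop = FALSE], ve)
  }
  pcs
}
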