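# Alignment curation and sample filtering: iterative removal of private-
# insertion carriers, binary variant extraction (gaps as non-variants),
# minor-allele-frequency filtering, and per-country sample-size rules.

#' Curation configuration
#'
#' @param gap_threshold fraction of sequences that must carry a gap in a
#'   reference-gap column for it to count as a spurious insertion
#'   (default 0.9997, i.e. 99.97%).
#' @param maf_min minimum minor allele frequency, `>=` convention at the
#'   boundary (default 5e-5, the literal 0.005%).
#' @param min_country_n countries with fewer individuals are dropped
#'   (default 20, `>=` retained).
#' @param max_country_n countries with more individuals are subsampled to
#'   exactly this many (default 1000).
#' @param subsample_seed seed for the country subsampling.
#' @return list of class `curation_config`.
#' @export
curation_config <- function(gap_threshold = 0.9997, maf_min = 5e-5,
                            min_country_n = 20L, max_country_n = 1000L,
                            subsample_seed = 1L) {
  stopifnot(gap_threshold > 0, gap_threshold <= 1,
            maf_min >= 0, maf_min < 0.5, min_country_n <= max_country_n)
  structure(as.list(environment()), class = "curation_config")
}

#' Iteratively remove carriers of near-universal-gap insertions
#'
#' Repeats until stable: (a) find insertion columns — columns where the
#' reference carries a gap and the fraction of sequences carrying a gap
#' exceeds `gap_threshold`; (b) remove every non-reference sequence with a
#' non-gap character in any such column (the putative sequencing/alignment
#' errors); (c) delete columns left all-gap. Because removing an insertion's
#' private carrier leaves every other sequence's coordinates unchanged,
#' gap-column deletion here plays the role of the re-alignment step of a
#' full pipeline. The reference row is never removed. The procedure
#' terminates (each iteration removes at least one sequence or stops) and is
#' idempotent.
#'
#' @param alignment an [alignment_matrix()].
#' @param gap_threshold see [curation_config()].
#' @return list with `alignment` (stable), `removed` (IDs removed),
#'   `n_iterations` (loop passes including the final check).
#' @export
iterative_gap_curation <- function(alignment, gap_threshold = 0.9997) {
  stopifnot(inherits(alignment, "alignment_matrix"))
  M <- alignment$seqs
  if (nrow(M) == 0 || ncol(M) == 0) stop("empty alignment")
  ref_id <- alignment$ref_id
  removed <- character(0)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    gap_frac <- colMeans(M == "-")
    ins_cols <- which(M[ref_id, ] == "-" & gap_frac > gap_threshold)
    if (!length(ins_cols)) break
    carrier <- rownames(M)[rowSums(M[, ins_cols, drop = FALSE] != "-") > 0]
    carrier <- setdiff(carrier, ref_id)
    removed <- c(removed, carrier)
    M <- M[!(rownames(M) %in% carrier), , drop = FALSE]
    all_gap <- colSums(M != "-") == 0
    M <- M[, !all_gap, drop = FALSE]
  }
  list(alignment = alignment_matrix(M, ref_id = ref_id),
       removed = removed, n_iterations = n_iter)
}

#' Extract binary substitution variants from a curated alignment
#'
#' For every column where the reference carries a base (`A/C/G/T`) and at
#' least one other sequence carries a different base, one site is emitted:
#' genotype 0 for the reference base, 1 for any non-reference base
#' (multi-allelic columns collapse to a binary reference/alternative coding,
#' matching the scan's binary response; all observed alternative bases are
#' still recorded for the VCF). Gaps and `N` are treated as missing and
#' contribute no variation, so columns varying only in gaps/`N` emit
#' nothing. Positions are 1-based reference coordinates.
#'
#' @param alignment an [alignment_matrix()].
#' @return a [genotype_matrix()] over the non-reference sequences (possibly
#'   with zero sites).
#' @export
call_variants <- function(alignment) {
  stopifnot(inherits(alignment, "alignment_matrix"))
  M <- alignment$seqs
  ref <- M[alignment$ref_id, ]
  ind <- M[setdiff(rownames(M), alignment$ref_id), , drop = FALSE]
  refpos <- cumsum(ref != "-")
  sites <- list(); G <- list()
  for (j in seq_len(ncol(M))) {
    if (!(ref[j] %in% c("A", "C", "G", "T"))) next
    col <- ind[, j]
    is_base <- col %in% c("A", "C", "G", "T")
    alt <- setdiff(unique(col[is_base]), ref[j])
    if (!length(alt)) next
    g <- rep(NA_integer_, length(col))
    g[is_base] <- as.integer(col[is_base] != ref[j])
    sites[[length(sites) + 1L]] <- data.frame(
      pos = refpos[j], ref = ref[j], alt = paste(sort(alt), collapse = ","))
    G[[length(G) + 1L]] <- g
  }
  if (!length(sites)) {
    return(genotype_matrix(
      matrix(integer(0), nrow = nrow(ind), ncol = 0,
             dimnames = list(rownames(ind), NULL)),
      data.frame(pos = integer(0), ref = character(0), alt = character(0))))
  }
  genotype_matrix(matrix(unlist(G), nrow = nrow(ind),
                         dimnames = list(rownames(ind), NULL)),
                  do.call(rbind, sites))
}

#' Filter sites by minor allele frequency
#'
#' Sites are retained iff `min(freq(0), freq(1))` over non-missing entries is
#' at least `maf_min` (boundary retained).
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency.
#' @return filtered [genotype_matrix()]; a warning is issued if no site
#'   survives.
#' @export
maf_filter <- function(genotypes, maf_min = 5e-5) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (ncol(genotypes$G) == 0) stop("genotype matrix has no sites")
  f <- colMeans(genotypes$G, na.rm = TRUE)
  keep <- pmin(f, 1 - f) >= maf_min
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("MAF filter removed every site")
  genotype_matrix(genotypes$G[, keep, drop = FALSE],
                  genotypes$sites[keep, , drop = FALSE])
}

#' Apply per-country sample-size rules
#'
#' Drops every individual from countries with fewer than `min_country_n`
#' members; countries with more than `max_country_n` members are reduced to
#' a uniform random subsample of exactly `max_country_n` (seeded). Row order
#' is otherwise preserved and genotype values never change.
#'
#' @param genotypes a [genotype_matrix()].
#' @param countries named country vector covering all individuals.
#' @param min_country_n,max_country_n,seed see [curation_config()].
#' @return list with filtered `genotypes` and `countries`.
#' @export
filter_countries <- function(genotypes, countries, min_country_n = 20L,
                             max_country_n = 1000L, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- genotypes$ids
  if (!all(ids %in% names(countries))) stop("every individual needs a country")
  ctry <- countries[ids]
  tab <- table(ctry)
  keep_countries <- names(tab)[tab >= min_country_n]
  if (!length(keep_countries)) stop("no countries survive the size filter")
  keep <- ids[ctry %in% keep_countries]
  withr::with_seed(seed, {
    for (cn in names(tab)[tab > max_country_n]) {
      members <- ids[ctry == cn]
      drop <- sample(members, length(members) - max_country_n)
      keep <- setdiff(keep, drop)
    }
  })
  sel <- ids %in% keep
  list(genotypes = genotype_matrix(genotypes$G[sel, , drop = FALSE],
                                   genotypes$sites),
       countries = ctry[sel])
}

#' Exclude individuals from listed countries
#'
#' Supports robustness re-runs of the scan without designated regions.
#'
#' @param genotypes a [genotype_matrix()].
#' @param countries named country vector.
#' @param excluded_countries character vector (may be empty).
#' @return list with filtered `genotypes` and `countries`.
#' @export
exclude_regions <- function(genotypes, countries, excluded_countries = character(0)) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ctry <- countries[genotypes$ids]
  sel <- !(ctry %in% excluded_countries)
  list(genotypes = genotype_matrix(genotypes$G[sel, , drop = FALSE],
                                   genotypes$sites),
       countries = ctry[sel])
}
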