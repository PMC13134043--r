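# Containers and file formats: gapped alignments (multi-FASTA), binary
# genotype matrices (haploid VCF v4.2), country/climate tables (CSV),
# trees (Newick via ape).

ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct an alignment matrix
#'
#' @param seqs character matrix over `{A,C,G,T,N,-}`, rows named by sequence
#'   ID; one row must be the designated reference.
#' @param ref_id reference sequence ID.
#' @return object of class `alignment_matrix` (fields `seqs`, `ids`,
#'   `ref_id`).
#' @export
alignment_matrix <- function(seqs, ref_id) {
  seqs <- as.matrix(seqs)
  if (is.null(rownames(seqs))) stop("sequence rows must be named")
  if (anyDuplicated(rownames(seqs))) stop("duplicate sequence IDs")
  if (!ref_id %in% rownames(seqs)) stop("reference ID not present in alignment")
  bad <- setdiff(unique(as.vector(seqs)), ALPHABET)
  if (length(bad)) stop("invalid alignment characters: ", paste(bad, collapse = " "))
  structure(list(seqs = seqs, ids = rownames(seqs), ref_id = ref_id),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat("Alignment:", nrow(x$seqs), "sequences x", ncol(x$seqs),
      "columns (reference:", x$ref_id, ")\n")
  invisible(x)
}

#' @export
dim.alignment_matrix <- function(x) dim(x$seqs)

#' Read a gapped multi-FASTA alignment
#'
#' All sequences must have equal (aligned) length; lowercase bases are
#' normalised to uppercase; duplicate IDs are an error.
#'
#' @param path FASTA file.
#' @param ref_id ID of the reference sequence row.
#' @return an [alignment_matrix()].
#' @export
read_fasta <- function(path, ref_id) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence IDs in FASTA")
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1) stop("ragged alignment: unequal sequence lengths")
  M <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(M) <- ids
  alignment_matrix(M, ref_id = ref_id)
}

#' Write an alignment to multi-FASTA
#'
#' @param alignment an [alignment_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  seqs <- apply(alignment$seqs, 1, paste0, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- alignment$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a genotype matrix
#'
#' @param G integer matrix, individuals x sites, entries 0 (reference), 1
#'   (alternative) or NA (missing); rows named by individual ID.
#' @param sites data.frame with columns `pos` (1-based reference position,
#'   strictly increasing), `ref` (reference allele), `alt` (comma-separated
#'   observed alternative alleles).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, sites) {
  G <- as.matrix(G)
  if (is.null(rownames(G))) stop("genotype rows must be named")
  stopifnot(is.data.frame(sites), all(c("pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == ncol(G))
  if (nrow(sites) > 1 && any(diff(sites$pos) <= 0))
    stop("site positions must be strictly increasing")
  vals <- unique(as.vector(G))
  if (!all(vals %in% c(0L, 1L, NA))) stop("genotypes must be 0, 1 or NA")
  structure(list(G = G, sites = sites, ids = rownames(G)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotypes:", nrow(x$G), "individuals x", ncol(x$G), "sites\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

#' Write genotypes as haploid VCF v4.2
#'
#' One sample column per individual with haploid `GT` (`0`, `1` or `.`);
#' `CHROM` is the reference ID, `POS` the 1-based reference coordinate, and
#' `ALT` lists all observed alternative bases even though the genotype coding
#' is binary.
#'
#' @param genotypes a [genotype_matrix()].
#' @param reference_id reference sequence ID (CHROM).
#' @param path output file.
#' @param meta optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, reference_id, path, meta = NULL) {
  st <- genotypes$sites
  if (nrow(st) > 1 && any(diff(st$pos) <= 0))
    stop("internal error: sites must be position-sorted")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=mtclimscan ",
                  as.character(utils::packageVersion("mtclimscan"))),
           if (!is.null(meta)) paste0("##", names(meta), "=", meta),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", genotypes$ids), collapse = "\t"))
  gt <- genotypes$G
  gc <- matrix(as.character(gt), nrow(gt), ncol(gt))
  gc[is.na(gt)] <- "."
  body <- vapply(seq_len(nrow(st)), function(j) {
    paste(c(reference_id, st$pos[j], ".", st$ref[j], st$alt[j], ".", ".", ".",
            "GT", gc[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a haploid VCF written by [write_vcf()]
#'
#' @param path VCF file.
#' @return list with `genotypes` (a [genotype_matrix()]) and `reference_id`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t")[[1]]
  if (header[1] != "#CHROM") stop("invalid VCF: missing #CHROM header")
  ids <- header[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  if (!length(rows)) stop("VCF contains no sites")
  chrom <- unique(vapply(rows, `[[`, character(1), 1))
  if (length(chrom) != 1) stop("multiple CHROM values unsupported")
  sites <- data.frame(
    pos = as.integer(vapply(rows, `[[`, character(1), 2)),
    ref = vapply(rows, `[[`, character(1), 4),
    alt = vapply(rows, `[[`, character(1), 5)
  )
  G <- vapply(rows, function(r) suppressWarnings(as.integer(r[-(1:9)])),
              integer(length(ids)))
  G <- matrix(G, nrow = length(ids), ncol = nrow(sites),
              dimnames = list(ids, NULL))
  list(genotypes = genotype_matrix(G, sites), reference_id = chrom)
}

#' Write / read the per-individual country table
#'
#' @param countries named character vector (names = individual IDs).
#' @param path CSV path.
#' @return `path` / named character vector.
#' @export
write_country_table <- function(countries, path) {
  write.csv(data.frame(individual_id = names(countries),
                       country = unname(countries)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_country_table
#' @export
read_country_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  setNames(d$country, d$individual_id)
}

#' Write / read the per-country climate table
#'
#' @param climate data.frame with a `country` column plus predictor columns.
#' @param path CSV path.
#' @return `path` / data.frame.
#' @export
write_climate_table <- function(climate, path) {
  write.csv(climate, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_table
#' @export
read_climate_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
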