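# End-to-end driver: simulate (or ingest) -> curate -> pca -> latprecip scan
# -> paleo scan -> tree test -> manifest. Every stage writes plain-text
# outputs under `outdir`; identical config + seed reproduce identical files.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] (ignored when `input` supplies real files).
#' @param curation a [curation_config()].
#' @param scan a [scan_config()].
#' @param n_tree_sims null draws per site in the tree-test stage.
#' @param excluded_countries countries removed before the scan (robustness
#'   re-runs).
#' @param stages stages to run, in order.
#' @param input optional list of file paths for real-data mode: `alignment`
#'   (multi-FASTA), `reference_id`, `countries` (CSV), `climate` (CSV),
#'   `tree` (Newick, optional).
#' @param seed master seed for stages not covered by `sim`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), curation = curation_config(),
                            scan = scan_config(), n_tree_sims = 200L,
                            excluded_countries = character(0),
                            stages = c("simulate", "curate", "pca", "scan",
                                       "paleoscan", "treetest"),
                            input = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [pipeline_config()] and its
#' sub-configurations; matrix-valued fields (the climate correlation) keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  curation <- do.call(curation_config, y$curation %||% list())
  scan <- do.call(scan_config, y$scan %||% list())
  pipeline_config(sim = sim, curation = curation, scan = scan,
                  n_tree_sims = y$n_tree_sims %||% 200L,
                  excluded_countries = y$excluded_countries %||% character(0),
                  stages = y$stages %||% c("simulate", "curate", "pca", "scan",
                                           "paleoscan", "treetest"),
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the configured stages, writing each stage's outputs (FASTA,
#' Newick, VCF, CSV tables) and a JSON run manifest under `outdir`. A stage
#' failure halts the run after writing a manifest that records the completed
#' stages.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return the manifest, invisibly; stage results are attached as the
#'   `results` attribute.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mtclimscan")),
    seed = config$seed,
    stages_requested = config$stages,
    stages_completed = character(0),
    counts = list(), thresholds = list(), seeds = list(),
    input_checksums = list()
  )
  res <- list()
  finish <- function(ok) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(structure(manifest, results = res))
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    r <- tryCatch(fun(), error = function(e) {
      manifest$stages_completed <<- manifest$stages_completed
      finish(FALSE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages_completed <<- c(manifest$stages_completed, name)
    r
  }

  run_stage("simulate", function() {
    ds <- simulate_dataset(config$sim)
    write_fasta(ds$alignment, file.path(outdir, "alignment.fasta"))
    ape::write.tree(ds$tree, file.path(outdir, "tree.nwk"))
    write_country_table(ds$countries, file.path(outdir, "countries.csv"))
    write_climate_table(ds$climate, file.path(outdir, "climate.csv"))
    write.csv(ds$truth, file.path(outdir, "truth.csv"), row.names = FALSE)
    manifest$seeds$simulate <<- config$sim$seed
    manifest$counts$sequences_simulated <<- config$sim$n_tips
    res$dataset <<- ds
    ds
  })

  if ("curate" %in% config$stages || "scan" %in% config$stages) {
    if (!is.null(config$input)) {
      aln <- read_fasta(config$input$alignment, config$input$reference_id)
      countries <- read_country_table(config$input$countries)
      climate <- read_climate_table(config$input$climate)
      tree <- if (!is.null(config$input$tree)) ape::read.tree(config$input$tree)
      for (f in c("alignment", "countries", "climate"))
        manifest$input_checksums[[f]] <- unname(tools::md5sum(config$input[[f]]))
    } else {
      aln <- res$dataset$alignment
      countries <- res$dataset$countries
      climate <- res$dataset$climate
      tree <- res$dataset$tree
    }
  }

  run_stage("curate", function() {
    cc <- config$curation
    cur <- iterative_gap_curation(aln, cc$gap_threshold)
    geno <- call_variants(cur$alignment)
    geno <- maf_filter(geno, cc$maf_min)
    fc <- filter_countries(geno, countries, cc$min_country_n, cc$max_country_n,
                           seed = cc$subsample_seed)
    if (length(config$excluded_countries)) {
      fc <- exclude_regions(fc$genotypes, fc$countries,
                            config$excluded_countries)
    }
    write_vcf(fc$genotypes, aln$ref_id, file.path(outdir, "variants.vcf"),
              meta = c(gap_threshold = cc$gap_threshold, maf_min = cc$maf_min))
    write.csv(data.frame(removed_id = cur$removed),
              file.path(outdir, "removed_sequences.csv"), row.names = FALSE)
    write.csv(data.frame(stage = c("input", "gap_curation", "country_filter"),
                         n_sequences = c(nrow(aln$seqs) - 1L,
                                         nrow(cur$alignment$seqs) - 1L,
                                         nrow(fc$genotypes$G))),
              file.path(outdir, "filter_audit.csv"), row.names = FALSE)
    manifest$counts$sequences_removed_gap <<- length(cur$removed)
    manifest$counts$sites_called <<- ncol(geno$G)
    manifest$counts$individuals_retained <<- nrow(fc$genotypes$G)
    manifest$seeds$subsample <<- cc$subsample_seed
    res$genotypes <<- fc$genotypes
    res$countries <<- fc$countries
    res$climate <<- climate
    res$tree <<- tree
    fc
  })

  run_stage("pca", function() {
    pcs <- genotype_pca(res$genotypes, n_components = config$scan$n_pcs)
    write.csv(data.frame(individual_id = pcs$ids, pcs$scores),
              file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    res$pcs <<- pcs
    pcs
  })

  run_stage("scan", function() {
    sc <- run_latprecip_scan(res$genotypes, res$pcs, res$countries,
                             res$climate, config$scan)
    write.csv(sc$table, file.path(outdir, "scan_latprecip.csv"),
              row.names = FALSE)
    manifest$counts$snps_tested <<- sc$n_tested
    manifest$counts$latprecip_candidates <<- sum(sc$table$candidate)
    manifest$thresholds$latprecip_bonferroni <<- sc$bonferroni_threshold
    res$latprecip <<- sc
    sc
  })

  run_stage("paleoscan", function() {
    pb <- run_paleobio_scan(res$genotypes, res$pcs, res$countries,
                            res$climate, config$scan, latprecip = res$latprecip)
    write.csv(pb$table, file.path(outdir, "scan_paleo.csv"), row.names = FALSE)
    manifest$counts$paleo_candidates <<- sum(pb$table$candidate)
    manifest$thresholds$paleo_bonferroni <<- pb$bonferroni_threshold
    res$paleo <<- pb
    pb
  })

  run_stage("treetest", function() {
    ids <- res$genotypes$ids
    tr <- ape::keep.tip(res$tree, ids)
    lat <- setNames(res$climate$latitude, res$climate$country)
    phen <- setNames(lat[unname(res$countries[ids])], ids)
    tt <- run_tree_test(tr, res$genotypes, phen,
                        n_sims = config$n_tree_sims,
                        seed = subseed(config$seed, 99L))
    linked <- linked_to_candidates(res$genotypes, res$latprecip,
                                   config$scan$r2_linked)
    tab <- cbind(tt$table, linked = linked)
    write.csv(tab, file.path(outdir, "tree_test.csv"), row.names = FALSE)
    cg <- if (any(linked, na.rm = TRUE) && any(!linked, na.rm = TRUE))
      compare_groups(tt$table$p_value, linked) else list(W = NA, p_value = NA)
    manifest$counts$treetest_sites <<- sum(!is.na(tt$table$p_value))
    manifest$thresholds$wilcoxon_p <<- cg$p_value
    manifest$seeds$treetest <<- subseed(config$seed, 99L)
    res$treetest <<- tt
    res$wilcoxon <<- cg
    tt
  })

  finish(TRUE)
}

#' Flag SNPs linked to scan candidates
#'
#' `TRUE` for sites that are candidates themselves or whose genotype
#' correlation with any candidate exceeds the linkage threshold.
#'
#' @param genotypes a [genotype_matrix()].
#' @param latprecip a `scan_result`.
#' @param r2_linked linkage threshold.
#' @return logical vector over sites.
#' @export
linked_to_candidates <- function(genotypes, latprecip, r2_linked = 0.5) {
  cand <- latprecip$table$site[latprecip$table$candidate]
  linked <- logical(ncol(genotypes$G))
  if (!length(cand)) return(linked)
  linked[cand] <- TRUE
  r2 <- suppressWarnings(
    cor(genotypes$G, genotypes$G[, cand, drop = FALSE],
        use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  linked | apply(r2, 1, max) > r2_linked
}
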