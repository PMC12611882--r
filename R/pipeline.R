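# Orchestration: run the stage chain simulate -> normalize -> resilience ->
# scan -> associate -> mediate -> motif on one configuration and seed, with
# per-stage counts and a reproducible manifest.

#' Pipeline configuration
#'
#' @param stages Character vector of stages to run, in order, from
#'   `simulate`, `normalize`, `resilience`, `scan`, `associate`, `mediate`,
#'   `motif`. Later stages require their upstream outputs.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param seed Master seed for the whole run.
#' @param fdr FDR threshold used by scan and associate.
#' @param min_strains Minimum observed strains per protein for the scan.
#' @param cis_window_mb cis classification window in megabases.
#' @param r2_threshold Haplotype-block membership threshold.
#' @param n_boot Mediation bootstrap replicates.
#' @param motif_bed Optional path to a binding-site BED for the motif stage.
#' @param tf_pattern Regex selecting TF abundance tracks (default `"^TF"`).
#' @param out_dir Optional directory to write report files into.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "normalize", "resilience",
                                       "scan", "associate", "mediate",
                                       "motif"),
                            sim = sim_config(),
                            seed = 1L,
                            fdr = 0.05,
                            min_strains = 10,
                            cis_window_mb = 5,
                            r2_threshold = 1.0,
                            n_boot = 1000,
                            motif_bed = NULL,
                            tf_pattern = "^TF",
                            out_dir = NULL) {
  known <- c("simulate", "normalize", "resilience", "scan", "associate",
             "mediate", "motif")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  stopifnot(fdr > 0, fdr < 1, min_strains >= 1, cis_window_mb > 0,
            r2_threshold >= 0, r2_threshold <= 1, n_boot >= 1)
  if (!is.null(motif_bed) && !file.exists(motif_bed)) {
    abort(sprintf("motif BED not found: %s", motif_bed))
  }
  cfg <- list(stages = stages, sim = sim, seed = as.integer(seed), fdr = fdr,
              min_strains = min_strains, cis_window_mb = cis_window_mb,
              r2_threshold = r2_threshold, n_boot = n_boot,
              motif_bed = motif_bed, tf_pattern = tf_pattern,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, wiring each stage's outputs into
#' the next, and returns a report bundle: per-stage results, per-stage
#' counts (strains used, tests run, records surviving each filter), and a
#' run manifest (package version, seed, configuration hash). Identical
#' configuration and seed give identical reports. A stage whose upstream
#' output is missing fails immediately, naming the stage.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  need <- function(stage, what, value) {
    if (is.null(value)) {
      abort(sprintf("stage '%s' requires the output of stage '%s'.", stage, what))
    }
    value
  }
  report <- list()
  counts <- list()
  sim_cfg <- cfg$sim
  sim_cfg$seed <- cfg$seed
  cohort <- NULL; strain_ab <- NULL; res <- NULL
  records <- NULL; block <- NULL; assoc <- NULL; module <- NULL

  for (stage in cfg$stages) {
    if (stage == "simulate") {
      genotypes <- simulate_genotypes(sim_cfg)
      cohort <- simulate_cohort(sim_cfg, genotypes)
      cohort$genotypes <- genotypes
      report$truth <- cohort$truth
      counts$simulate <- list(
        strains = sim_cfg$n_strains, markers = nrow(genotypes),
        animals = nrow(cohort$phenotypes), features = nrow(cohort$abundance)
      )
    } else if (stage == "normalize") {
      cohort <- need(stage, "simulate", cohort)
      pep <- simulate_peptides(cohort$abundance, cohort$samples, sim_cfg)
      norm <- pep$abundance |>
        normalize_log2_median() |>
        remove_batch_effect(pep$samples)
      prot <- rollup_proteins(norm, pep$peptide_map)
      keep <- pep$samples$group != "reference"
      prot <- prot[, c("feature", pep$samples$sample[keep])]
      qc <- pca_qc(norm, pep$samples)
      strain_ab <- strain_abundance(prot, cohort$samples)
      report$normalize_qc <- qc
      counts$normalize <- list(
        peptides = nrow(pep$abundance), proteins = nrow(prot),
        batches = dplyr::n_distinct(pep$samples$batch),
        batch_separation = qc$batch_separation
      )
    } else if (stage == "resilience") {
      cohort <- need(stage, "simulate", cohort)
      res <- resilience_scores(cohort$phenotypes)
      report$resilience <- res
      counts$resilience <- list(
        strains = nrow(res$strains), animals = nrow(res$animals),
        r_squared = res$fit$r.squared, h2 = res$heritability$h2,
        h2_rix = res$heritability$h2_rix
      )
    } else if (stage == "scan") {
      cohort <- need(stage, "simulate", cohort)
      if (is.null(strain_ab)) {
        strain_ab <- strain_abundance(cohort$abundance, cohort$samples)
      }
      filtered <- filter_min_strains(strain_ab, cfg$min_strains)
      records <- qtl_scan(filtered, cohort$genotypes, fdr = cfg$fdr)
      records <- classify_cis_trans(records, cohort$genes,
                                    window = cfg$cis_window_mb * 1e6)
      peaks <- pqtl_peaks(records)
      report$pqtl <- records
      report$pqtl_peaks <- peaks
      counts$scan <- list(
        proteins_tested = dplyr::n_distinct(records$protein),
        tests = nrow(records),
        significant_records = sum(records$significant),
        significant_proteins = nrow(peaks),
        cis = sum(peaks$class == "cis", na.rm = TRUE),
        trans = sum(peaks$class == "trans", na.rm = TRUE)
      )
    } else if (stage == "associate") {
      res <- need(stage, "resilience", res)
      records <- need(stage, "scan", records)
      sig_proteins <- unique(records$protein[records$significant])
      universe <- strain_ab[strain_ab$feature %in% sig_proteins, ]
      assoc <- trait_association(universe, res$strains, fdr = cfg$fdr)
      # the resilience locus: the modal peak marker among trait-associated
      # proteins, expanded to its complete-LD haplotype block
      sig_peaks <- report$pqtl_peaks[report$pqtl_peaks$protein %in%
                                       assoc$protein[assoc$significant], ]
      if (nrow(sig_peaks) == 0) {
        abort("stage 'associate' found no trait-associated pQTL proteins.")
      }
      modal <- names(sort(table(sig_peaks$marker), decreasing = TRUE))[1]
      block <- haplotype_block(cohort$genotypes, modal,
                               r2_threshold = cfg$r2_threshold)
      de <- stratified_de(strain_ab, cohort$genotypes, block$peak,
                          fdr = cfg$fdr)
      report$haplotype_block <- block
      report$trait_association <- assoc
      report$stratified_de <- de
      counts$associate <- list(
        universe = nrow(assoc),
        significant = sum(assoc$significant),
        positive = sum(assoc$significant & assoc$direction == "+"),
        negative = sum(assoc$significant & assoc$direction == "-"),
        block_markers = nrow(block$members),
        de_up = sum(de$significant & de$direction == "+"),
        de_down = sum(de$significant & de$direction == "-")
      )
    } else if (stage == "mediate") {
      assoc <- need(stage, "associate", assoc)
      block <- need(stage, "associate", block)
      sig <- assoc$protein[assoc$significant]
      peaks <- report$pqtl_peaks
      in_block <- peaks$protein[peaks$chr == block$interval$chr &
                                  peaks$bp >= block$interval$start &
                                  peaks$bp <= block$interval$end]
      module <- intersect(sig, in_block)
      if (length(module) < 2) {
        abort("stage 'mediate' found fewer than 2 module proteins in the block.")
      }
      pca <- module_pca(strain_ab, module)
      codes <- genotype_codes(cohort$genotypes)
      d <- dplyr::inner_join(
        dplyr::select(pca$scores, "strain", "PC1"),
        res$strains, by = "strain"
      )
      d$x <- as.numeric(codes[block$peak, d$strain])
      med <- mediate(d, "x", "PC1", "resilience", n_boot = cfg$n_boot,
                     seed = substream_seed(cfg$seed, "mediation"))
      report$module <- module
      report$module_pca <- pca
      report$mediation <- med
      counts$mediate <- list(
        module_size = length(module),
        pc1_fraction = pca$variance_fractions[1],
        indirect = med$indirect, p_indirect = med$p_indirect
      )
    } else if (stage == "motif") {
      block <- need(stage, "associate", block)
      if (is.null(cfg$motif_bed)) {
        abort("stage 'motif' requires `motif_bed` in the configuration.")
      }
      sites <- read_motif_sites(cfg$motif_bed)
      snps <- dplyr::semi_join(marker_info(cohort$genotypes),
                               block$members, by = "marker")
      hits <- snps_in_sites(snps, sites)
      tf_ab <- strain_ab[grepl(cfg$tf_pattern, strain_ab$feature), ]
      res <- need(stage, "resilience", res)
      tfcor <- tf_trait_correlation(tf_ab, res$strains)
      top_tf <- tfcor$tf[1]
      strat <- genotype_stratified_fit(res$strains, tf_ab, cohort$genotypes,
                                       block$peak, top_tf)
      report$motif_sites <- sites
      report$motif_hits <- hits
      report$tf_correlation <- tfcor
      report$tf_stratified <- strat
      counts$motif <- list(
        sites = nrow(sites), snps_tested = nrow(snps),
        hits = nrow(hits), tfs_tested = nrow(tfcor),
        tfs_significant = sum(tfcor$p < 0.05), top_tf = top_tf
      )
    }
  }

  manifest <- list(
    package = "resqtl",
    version = as.character(utils::packageVersion("resqtl")),
    seed = cfg$seed,
    stages = cfg$stages,
    config_hash = content_hash(jsonlite::toJSON(
      cfg[setdiff(names(cfg), "out_dir")], auto_unbox = TRUE, digits = NA,
      force = TRUE
    ))
  )
  out <- structure(list(manifest = manifest, counts = counts, results = report),
                   class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_pipeline_report(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  seed %d, config %s; stages: %s\n", x$manifest$seed,
              x$manifest$config_hash, paste(x$manifest$stages, collapse = " -> ")))
  for (nm in names(x$counts)) {
    c1 <- x$counts[[nm]]
    cat(sprintf("  %-10s %s\n", nm,
                paste(sprintf("%s=%s", names(c1),
                              vapply(c1, function(v) format(v, digits = 4), "")),
                      collapse = " ")))
  }
  invisible(x)
}

# Write the JSON + TSV report bundle (no timestamps, so reruns are
# byte-identical).
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(manifest = report$manifest, counts = report$counts),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  tabs <- list(pqtl = report$results$pqtl,
               trait_association = report$results$trait_association,
               stratified_de = report$results$stratified_de,
               tf_correlation = report$results$tf_correlation,
               motif_hits = report$results$motif_hits)
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]])) {
      readr::write_tsv(tabs[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  if (!is.null(report$results$resilience)) {
    readr::write_tsv(report$results$resilience$strains,
                     file.path(out_dir, "strain_resilience.tsv"),
                     progress = FALSE)
  }
  invisible(out_dir)
}
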