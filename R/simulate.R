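# Synthetic recombinant-inbred-backcross cohort generator.
#
# The generator plants a known causal structure -- a chr1 haplotype block of
# perfectly linked markers driving a correlated protein module that in turn
# drives the deviation of AD strain means from their non-transgenic (Ntg)
# baseline -- and records everything it planted, so every downstream stage
# can be checked for parameter recovery.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic cohort
#' generator. Defaults describe the study conditions the package is
#' validated under: 49 strains with 2--17 female replicates per strain,
#' a 10-marker perfectly linked block on chromosome 1 driving an
#' 8-protein module with pairwise correlation 0.463, a strain-mean
#' baseline regression calibrated to R^2 = 0.38, and a full-mediation
#' path structure (no direct SNP effect on the trait).
#'
#' Two calibration conventions matter and are documented in the methods
#' vignette:
#' * `h2_strain` is the value the ANOVA sum-of-squares heritability
#'   estimator is expected to *recover*, not the raw between-strain
#'   variance fraction; the generator inverts the estimator's expectation.
#' * `baseline_r2` is the expected *observed* R^2 of the strain-mean
#'   regression, i.e. after attenuation by within-strain noise on both
#'   axes and finite-panel optimism; the generator inverts both.
#'
#' @param n_strains Number of recombinant inbred strains (default 49).
#' @param replicates_range Integer pair, inclusive range of per-strain
#'   replicate counts in each transgene group (default `c(2, 17)`).
#' @param n_markers_per_chrom Markers per chromosome (block included on
#'   chromosome 1).
#' @param n_chromosomes Number of chromosomes.
#' @param recomb_prob Per-adjacent-marker switch probability of the
#'   two-state Markov genotype process.
#' @param block_markers Number of perfectly linked markers planted in the
#'   chromosome 1 block (default 10).
#' @param h2_strain Target per-animal heritability of the resilience trait
#'   as recovered by the ANOVA SS estimator, in (0, 1).
#' @param baseline_r2 Target observed R^2 of the AD-on-Ntg strain-mean
#'   regression.
#' @param module_size Number of proteins in the PCA module (default 8; one
#'   member gets a negative loading).
#' @param module_rho Magnitude of the pairwise correlation among module
#'   proteins; the population PC1 variance fraction is
#'   `(1 + (module_size - 1) * module_rho) / module_size` (0.463 gives the
#'   ~53% seen for an 8-protein module; the default 0.55 keeps the planted
#'   per-protein SNP effects, bounded above by `sqrt(module_rho)`, reliably
#'   detectable at genome-wide FDR in a 49-strain panel).
#' @param n_null_proteins Number of unassociated proteins.
#' @param n_cis_null How many null proteins receive a planted cis driver at
#'   a random marker.
#' @param snp_module_effect,module_trait_effect,snp_direct_effect
#'   Standardized path coefficients a (SNP -> module latent),
#'   b (module -> trait deviation) and c' (direct SNP -> trait deviation).
#' @param trans_loading,trans_driver_effect Loading on the module latent and
#'   planted own-driver effect of the ninth trait-associated protein, whose
#'   pQTL sits on a different chromosome.
#' @param cis_null_effect Standardized effect of planted cis drivers on null
#'   proteins.
#' @param batch_count Number of proteomics batches; `NULL` derives
#'   `ceiling(n_samples / 14)` (14 cortex samples plus 2 references per
#'   batch).
#' @param batch_shift Additive per-batch shift in log2 units applied by
#'   [simulate_peptides()] (batch b is shifted by `(b - 1) * batch_shift`).
#' @param n_tfs Number of transcription-factor abundance tracks; the first
#'   is planted with marginal trait correlation `tf_trait_cor`, the second
#'   correlates with the trait only in BB-genotype strains with R^2
#'   `tf_bb_r2`.
#' @param tf_trait_cor,tf_bb_r2 See `n_tfs`.
#' @param ntg_mean,ad_mean,strain_sd,ntg_within_sd Location/scale of percent
#'   freezing: Ntg and AD grand means, between-strain SD, and Ntg
#'   within-strain SD (AD within-strain SD is derived from `h2_strain`).
#' @param protein_sd,protein_noise_sd Between-strain SD and per-animal
#'   technical SD of log2 protein abundance.
#' @param seed Master integer seed; all substreams derive from it via
#'   [substream_seed()].
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 12, n_chromosomes = 3, seed = 7)
#' cfg$block_markers
sim_config <- function(n_strains = 49,
                       replicates_range = c(2L, 17L),
                       n_markers_per_chrom = 12,
                       n_chromosomes = 19,
                       recomb_prob = 0.1,
                       block_markers = 10,
                       h2_strain = 0.5,
                       baseline_r2 = 0.38,
                       module_size = 8,
                       module_rho = 0.55,
                       n_null_proteins = 120,
                       n_cis_null = 40,
                       snp_module_effect = 0.97,
                       module_trait_effect = 0.97,
                       snp_direct_effect = 0,
                       trans_loading = 0.68,
                       trans_driver_effect = 0.73,
                       cis_null_effect = 0.9,
                       batch_count = NULL,
                       batch_shift = 0.5,
                       n_tfs = 26,
                       tf_trait_cor = 0.55,
                       tf_bb_r2 = 0.53,
                       ntg_mean = 55,
                       ad_mean = 40,
                       strain_sd = 10,
                       ntg_within_sd = 8,
                       protein_sd = 0.5,
                       protein_noise_sd = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fr01 <- c("recomb_prob", "h2_strain", "baseline_r2", "module_rho",
            "tf_trait_cor", "tf_bb_r2")
  for (f in fr01) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a probability/fraction in [0, 1].", f))
    }
  }
  counts <- c("n_strains", "n_markers_per_chrom", "n_chromosomes",
              "block_markers", "module_size", "n_tfs")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      abort(sprintf("`%s` must be a positive integer count.", f))
    }
  }
  if (cfg$n_null_proteins < 0 || cfg$n_cis_null < 0 ||
      cfg$n_cis_null > cfg$n_null_proteins) {
    abort("`n_cis_null` must lie in [0, n_null_proteins].")
  }
  rr <- cfg$replicates_range
  if (length(rr) != 2 || any(rr < 1) || rr[1] > rr[2]) {
    abort("`replicates_range` must be an increasing positive integer pair.")
  }
  if (cfg$h2_strain <= 0 || cfg$h2_strain >= 1) {
    abort("`h2_strain` must lie strictly inside (0, 1).")
  }
  if (cfg$block_markers > cfg$n_markers_per_chrom) {
    abort("`block_markers` cannot exceed `n_markers_per_chrom`.")
  }
  for (f in c("snp_module_effect", "module_trait_effect")) {
    if (abs(cfg[[f]]) > 1) abort(sprintf("`%s` must lie in [-1, 1].", f))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d strains, replicates %d-%d, %d chromosomes x %d markers\n",
              x$n_strains, x$replicates_range[1], x$replicates_range[2],
              x$n_chromosomes, x$n_markers_per_chrom))
  cat(sprintf("  block: %d linked markers on chr1; module: %d proteins (rho=%.3f)\n",
              x$block_markers, x$module_size, x$module_rho))
  cat(sprintf("  paths a=%.2f b=%.2f c'=%.2f; h2=%.2f baseline R2=%.2f; seed %d\n",
              x$snp_module_effect, x$module_trait_effect, x$snp_direct_effect,
              x$h2_strain, x$baseline_r2, as.integer(x$seed)))
  invisible(x)
}

# ---- calibration arithmetic ----------------------------------------------

# Between/within variance ratio u = sigma_s^2 / sigma_e^2 such that the
# one-way ANOVA SS-ratio estimator has (ratio-of-expectations) expectation h2
# for s strains with n_bar replicates each:
#   E[SSb] = (s-1)(sigma_e^2 + n sigma_s^2),  E[SSw] = s(n-1) sigma_e^2.
h2_variance_ratio <- function(h2, n_strains, n_bar) {
  u <- (h2 * n_strains * (n_bar - 1) / ((1 - h2) * (n_strains - 1)) - 1) / n_bar
  if (u <= 0) {
    abort(paste0("infeasible `h2_strain`: below the null expectation of the ",
                 "SS-ratio estimator for this panel size."))
  }
  u
}

# Latent strain-mean R^2 such that the observed strain-mean regression R^2
# has expectation `target` after (i) attenuation by within-strain noise on
# both axes and (ii) finite-panel OLS optimism ~ (1 - rho^2)/(s - 1).
calibrate_baseline <- function(cfg) {
  s <- cfg$n_strains
  rr <- seq(cfg$replicates_range[1], cfg$replicates_range[2])
  e_inv_n <- mean(1 / rr)
  n_bar <- mean(rr)
  u <- h2_variance_ratio(cfg$h2_strain, s, n_bar)
  f <- u / (1 + u)              # planted between-strain fraction of resilience
  k_x <- cfg$strain_sd^2 / (cfg$strain_sd^2 + cfg$ntg_within_sd^2 * e_inv_n)
  rho_eff2 <- (cfg$baseline_r2 - 1 / (s - 1)) / (1 - 1 / (s - 1))
  if (rho_eff2 <= 0) abort("`baseline_r2` too small to calibrate for this panel.")
  g <- (1 - f) / f * e_inv_n
  rho_lat2 <- rho_eff2 * (1 + g) / (k_x + rho_eff2 * g)
  if (rho_lat2 >= 1) {
    abort("infeasible calibration: baseline_r2 plus deviation variance exceed 1.")
  }
  beta_base <- sqrt(rho_lat2)   # slope on the (equal-SD) Ntg strain means
  sd_dev <- cfg$strain_sd * sqrt(1 - rho_lat2)
  # Ntg-mean measurement noise leaks into the between-strain part of the
  # residuals through the fitted slope; include it so measured h2 is unbiased.
  leak <- (beta_base * k_x)^2 * cfg$ntg_within_sd^2 * e_inv_n
  sigma_w <- sqrt((sd_dev^2 + leak) * (1 - f) / f)
  list(f = f, rho_lat2 = rho_lat2, beta_base = beta_base,
       sd_dev = sd_dev, sigma_w = sigma_w, e_inv_n = e_inv_n, n_bar = n_bar)
}

# ---- genotypes ------------------------------------------------------------

BLOCK_START <- 173200610
BLOCK_END <- 175596722

#' Simulate recombinant-inbred-backcross genotypes
#'
#' Strains are independent; within each chromosome the 0/1 code follows a
#' two-state Markov chain with switch probability `recomb_prob` between
#' adjacent markers (0 = homozygous BB, 1 = heterozygous BD -- a backcross
#' panel carries either a paternal B or D allele over a maternal B6
#' background). Chromosome 1 additionally carries a planted block of
#' `block_markers` markers with *identical* strain distribution patterns
#' inside a fixed GRCm39-style interval; every other marker is guaranteed
#' polymorphic and guaranteed not to be in complete LD (|r| = 1) with the
#' block, so downstream haplotype-block extraction at r^2 = 1 recovers
#' exactly the planted members.
#'
#' @param cfg A [sim_config()].
#' @return A genotype tibble (`marker`, `chr`, `bp`, one 0/1 column per
#'   strain) with a `block` attribute (see [genotype_block()]).
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_strains = 8, n_chromosomes = 2, seed = 1))
#' genotype_block(g)$markers
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_strains < 4) abort("need at least 4 strains for downstream regressions.")
  set.seed(substream_seed(cfg$seed, "genotypes"))
  s <- cfg$n_strains
  strains <- sprintf("S%02d", seq_len(s))

  draw_polymorphic <- function() {
    repeat {
      v <- stats::rbinom(s, 1, 0.5)
      if (min(sum(v), s - sum(v)) >= min(2, floor(s / 4))) return(v)
    }
  }
  block_pattern <- draw_polymorphic()

  distinct_from_block <- function(v) {
    !(all(v == block_pattern) || all(v == 1 - block_pattern))
  }
  fix_column <- function(v) {
    while (length(unique(v)) < 2 || !distinct_from_block(v)) {
      v <- stats::rbinom(s, 1, 0.5)
    }
    v
  }

  markov_chrom <- function(n_mark) {
    m <- matrix(0L, nrow = s, ncol = n_mark)
    m[, 1] <- stats::rbinom(s, 1, 0.5)
    if (n_mark > 1) {
      for (j in 2:n_mark) {
        switch_ <- stats::rbinom(s, 1, cfg$recomb_prob)
        m[, j] <- ifelse(switch_ == 1, 1L - m[, j - 1], m[, j - 1])
      }
    }
    m
  }

  chrom_tables <- vector("list", cfg$n_chromosomes)
  block_ids <- character(0)
  for (chr in seq_len(cfg$n_chromosomes)) {
    if (chr == 1) {
      n_flank <- cfg$n_markers_per_chrom - cfg$block_markers
      flank_bp <- integer(0)
      while (length(flank_bp) < n_flank) {
        cand <- round(runif(n_flank * 2, 3e6, 1.9e8))
        cand <- cand[cand < BLOCK_START | cand > BLOCK_END]
        flank_bp <- unique(c(flank_bp, cand))[seq_len(min(n_flank, length(unique(c(flank_bp, cand)))))]
      }
      flank_bp <- sort(flank_bp)
      block_bp <- sort(round(runif(cfg$block_markers, BLOCK_START, BLOCK_END)))
      codes_flank <- markov_chrom(max(n_flank, 1))[, seq_len(n_flank), drop = FALSE]
      codes_flank <- apply(codes_flank, 2, fix_column)
      if (n_flank > 0 && is.null(dim(codes_flank))) {
        codes_flank <- matrix(codes_flank, nrow = s)
      }
      codes_block <- matrix(rep(block_pattern, cfg$block_markers), nrow = s)
      bp <- c(flank_bp, block_bp)
      codes <- cbind(codes_flank, codes_block)
      ord <- order(bp)
      bp <- bp[ord]
      codes <- codes[, ord, drop = FALSE]
      ids <- sprintf("chr%d_m%03d", chr, seq_along(bp))
      block_ids <- ids[bp >= BLOCK_START & bp <= BLOCK_END]
    } else {
      bp <- sort(unique(round(runif(cfg$n_markers_per_chrom, 3e6, 1.9e8))))
      while (length(bp) < cfg$n_markers_per_chrom) {
        bp <- sort(unique(c(bp, round(runif(1, 3e6, 1.9e8)))))
      }
      codes <- markov_chrom(cfg$n_markers_per_chrom)
      codes <- apply(codes, 2, fix_column)
      ids <- sprintf("chr%d_m%03d", chr, seq_along(bp))
    }
    tab <- tibble::tibble(marker = ids, chr = chr, bp = bp)
    codes_t <- t(codes)             # markers x strains
    colnames(codes_t) <- strains
    chrom_tables[[chr]] <- dplyr::bind_cols(tab, tibble::as_tibble(codes_t))
  }
  out <- dplyr::bind_rows(chrom_tables)
  attr(out, "block") <- list(
    markers = block_ids, chr = 1L,
    start = BLOCK_START, end = BLOCK_END,
    pattern = setNames(block_pattern, strains)
  )
  out
}

#' Planted haplotype block of a simulated genotype table
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @return List with `markers`, `chr`, `start`, `end`, `pattern`.
#' @export
genotype_block <- function(genotypes) {
  b <- attr(genotypes, "block")
  if (is.null(b)) abort("no planted block recorded on this genotype table.")
  b
}

# ---- cohort ---------------------------------------------------------------

#' Simulate a phenotyped, proteome-profiled cohort with recorded truth
#'
#' Builds per-animal contextual-fear phenotypes for transgenic (AD) and
#' non-transgenic (Ntg) littermates on every strain, a log2 protein
#' abundance matrix over the AD animals, per-protein gene positions, and a
#' truth table recording every planted effect.
#'
#' The causal structure: the planted block genotype `x` (standardized over
#' strains) drives a module latent `L = a x + noise`; the deviation of AD
#' strain means from the Ntg baseline is `D = c' x + b L + noise`; module
#' proteins load on `L` with +/- sqrt(module_rho); a ninth trait-associated
#' protein loads negatively on `L` but carries a stronger planted driver on
#' a different chromosome. Calibration of the baseline regression and of the
#' within-strain noise follows [sim_config()].
#'
#' @param cfg A [sim_config()].
#' @param genotypes Genotypes from [simulate_genotypes()] (must carry the
#'   planted block).
#' @return A list of class `resqtl_cohort` with elements `phenotypes`
#'   (tibble: animal, strain, group, sex, age, cfm, cfa), `abundance` (wide
#'   log2 tibble over AD animals), `samples` (sample metadata), `genes`
#'   (gene positions), and `truth` (class `resqtl_truth`).
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 10, n_chromosomes = 2, n_null_proteins = 5,
#'                   n_cis_null = 1, n_tfs = 2, seed = 3)
#' cohort <- simulate_cohort(cfg, simulate_genotypes(cfg))
#' cohort$truth$paths
simulate_cohort <- function(cfg, genotypes) {
  validate_sim_config(cfg)
  block <- genotype_block(genotypes)
  strains <- setdiff(names(genotypes), genotype_meta_cols)
  s <- length(strains)
  if (s != cfg$n_strains) abort("genotype table does not match `n_strains`.")
  cal <- calibrate_baseline(cfg)
  a <- cfg$snp_module_effect
  b <- cfg$module_trait_effect
  cc <- cfg$snp_direct_effect
  lam0 <- sqrt(cfg$module_rho)
  a_med0 <- a * lam0 / sqrt(lam0^2 + (1 - cfg$module_rho) / cfg$module_size)
  if (cc^2 + b^2 + 2 * cc * b * a_med0 > 1) {
    abort("infeasible paths: direct + mediated variance exceed 1.")
  }

  set.seed(substream_seed(cfg$seed, "phenotypes"))
  codes <- genotype_codes(genotypes)
  x <- as.numeric(codes[block$markers[1], strains])
  x_c <- as.numeric(scale(x))
  z_ntg <- rnorm(s)
  L <- a * x_c + sqrt(max(0, 1 - a^2)) * rnorm(s)

  # Module proteins realize the latent with protein-specific noise; the
  # trait deviation is driven by the module's *realized* signal (the signed
  # mean of the standardized module proteins, ~ what PC1 recovers), so that
  # the mediator the analysis sees really carries the planted effect and
  # full mediation is recoverable rather than leaking into the direct path
  # through mediator measurement error.
  m <- cfg$module_size
  lam <- sqrt(cfg$module_rho)
  module_sign <- c(rep(1, m - 1), -1)
  mod_vals <- t(vapply(seq_len(m), function(j) {
    module_sign[j] * lam * L + sqrt(1 - cfg$module_rho) * rnorm(s)
  }, numeric(s)))
  m_signal <- colMeans(module_sign * mod_vals)   # lam * L + averaged noise
  m_z <- as.numeric(scale(m_signal))
  # effective X -> mediator path on the realized-signal scale
  a_med <- a * lam / sqrt(lam^2 + (1 - cfg$module_rho) / m)

  drive <- cc * x_c + b * m_z
  v_drive <- var(drive)
  if (v_drive > 1) abort("infeasible paths: direct + mediated variance exceed 1.")
  D <- drive + sqrt(1 - v_drive) * rnorm(s)
  m_ntg <- cfg$ntg_mean + cfg$strain_sd * z_ntg
  m_ad <- cfg$ad_mean + cal$beta_base * (m_ntg - cfg$ntg_mean) + cal$sd_dev * D

  rr <- seq(cfg$replicates_range[1], cfg$replicates_range[2])
  n_ad <- rr[sample.int(length(rr), s, replace = TRUE)]
  n_ntg <- rr[sample.int(length(rr), s, replace = TRUE)]
  clamp <- function(v) pmin(100, pmax(0, v))
  pheno <- purrr::map_dfr(seq_len(s), function(i) {
    cfm_ad <- clamp(m_ad[i] + cal$sigma_w * rnorm(n_ad[i]))
    cfm_ntg <- clamp(m_ntg[i] + cfg$ntg_within_sd * rnorm(n_ntg[i]))
    cfm <- c(cfm_ad, cfm_ntg)
    tibble::tibble(
      strain = strains[i],
      group = rep(c("AD", "Ntg"), c(n_ad[i], n_ntg[i])),
      cfm = cfm,
      cfa = clamp(25 + 0.35 * cfm + 8 * rnorm(length(cfm)))
    )
  })
  pheno <- dplyr::mutate(pheno,
    animal = sprintf("A%04d", dplyr::row_number()),
    sex = "F", age = 6, .before = 1
  )
  pheno <- pheno[c("animal", "strain", "group", "sex", "age", "cfm", "cfa")]

  # realized strain-level deviation (what the resilience stage can recover)
  ad_means <- tapply(pheno$cfm[pheno$group == "AD"],
                     pheno$strain[pheno$group == "AD"], mean)[strains]
  ntg_means <- tapply(pheno$cfm[pheno$group == "Ntg"],
                      pheno$strain[pheno$group == "Ntg"], mean)[strains]
  dev_real <- as.numeric(ad_means) -
    (cfg$ad_mean + cal$beta_base * (as.numeric(ntg_means) - cfg$ntg_mean))
  t_z <- as.numeric(scale(dev_real))

  # ---- remaining proteins (strain level, standardized) -------------------
  set.seed(substream_seed(cfg$seed, "proteins"))
  module_ids <- sprintf("P%03d", seq_len(m))
  trans_id <- sprintf("P%03d", m + 1)
  null_ids <- sprintf("P%03d", m + 1 + seq_len(cfg$n_null_proteins))
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))

  non_block <- marker_info(genotypes)
  non_block <- non_block[!(non_block$marker %in% block$markers), ]
  other_chr <- non_block[non_block$chr != block$chr, ]
  if (nrow(other_chr) == 0) abort("need markers on a second chromosome for the trans driver.")
  trans_marker <- other_chr$marker[sample(nrow(other_chr), 1)]
  x9_c <- as.numeric(scale(as.numeric(codes[trans_marker, strains])))
  l9 <- cfg$trans_loading
  b9 <- cfg$trans_driver_effect
  v9 <- l9^2 + b9^2
  if (v9 > 1) abort("infeasible trans-member loadings.")
  # loads (negatively) on the realized module signal, like the module
  # members, but its own strongest driver sits on another chromosome
  trans_vals <- -l9 * m_z + b9 * x9_c + sqrt(1 - v9) * rnorm(s)

  cis_markers <- character(0)
  null_vals <- matrix(rnorm(cfg$n_null_proteins * s), ncol = s)
  if (cfg$n_cis_null > 0) {
    if (cfg$n_cis_null > nrow(non_block)) {
      abort("`n_cis_null` exceeds the number of non-block markers.")
    }
    cis_markers <- non_block$marker[sample(nrow(non_block), cfg$n_cis_null)]
    ce <- cfg$cis_null_effect
    for (k in seq_len(cfg$n_cis_null)) {
      xm <- as.numeric(scale(as.numeric(codes[cis_markers[k], strains])))
      null_vals[k, ] <- ce * xm + sqrt(1 - ce^2) * rnorm(s)
    }
  }

  tf_vals <- matrix(rnorm(cfg$n_tfs * s), ncol = s)
  if (cfg$n_tfs >= 1) {
    tf_vals[1, ] <- cfg$tf_trait_cor * t_z +
      sqrt(1 - cfg$tf_trait_cor^2) * rnorm(s)
  }
  if (cfg$n_tfs >= 2) {
    rho_bb <- sqrt(cfg$tf_bb_r2)
    bb <- x == 0
    v <- rnorm(s)
    tzg <- t_z
    tzg[bb] <- as.numeric(scale(t_z[bb]))
    v[bb] <- rho_bb * tzg[bb] + sqrt(1 - cfg$tf_bb_r2) * v[bb]
    tf_vals[2, ] <- v
  }

  feat_ids <- c(module_ids, trans_id, null_ids, tf_ids)
  std <- rbind(mod_vals, matrix(trans_vals, nrow = 1), null_vals, tf_vals)
  rownames(std) <- feat_ids
  base <- runif(length(feat_ids), 14, 24)
  strain_log2 <- base + cfg$protein_sd * std
  colnames(strain_log2) <- strains

  # per-animal values over AD animals
  ad_animals <- pheno[pheno$group == "AD", c("animal", "strain")]
  vals <- strain_log2[, ad_animals$strain, drop = FALSE] +
    cfg$protein_noise_sd * matrix(rnorm(length(feat_ids) * nrow(ad_animals)),
                                  nrow = length(feat_ids))
  colnames(vals) <- ad_animals$animal
  abundance <- matrix_abundance(vals)
  samples <- tibble::tibble(
    sample = ad_animals$animal, strain = ad_animals$strain,
    group = "AD", batch = NA_character_
  )

  # ---- gene positions -----------------------------------------------------
  gene_len <- 2e4
  rand_gene <- function(n) {
    chr <- sample(cfg$n_chromosomes, n, replace = TRUE)
    start <- round(runif(n, 3e6, 1.85e8))
    tibble::tibble(chr = chr, start = start, end = start + gene_len)
  }
  near <- function(chr, center, jitter = 1e6) {
    start <- round(center + runif(length(center), -jitter, jitter))
    tibble::tibble(chr = chr, start = start, end = start + gene_len)
  }
  mi <- marker_info(genotypes)
  cis_bp <- mi$bp[match(cis_markers, mi$marker)]
  cis_chr <- mi$chr[match(cis_markers, mi$marker)]
  genes <- dplyr::bind_rows(
    dplyr::mutate(near(rep(block$chr, m),
                       round(runif(m, block$start, block$end))),
                  protein = module_ids, .before = 1),
    dplyr::mutate(near(block$chr, round((block$start + block$end) / 2)),
                  protein = trans_id, .before = 1),
    if (cfg$n_cis_null > 0) {
      dplyr::mutate(near(cis_chr, cis_bp),
                    protein = null_ids[seq_len(cfg$n_cis_null)], .before = 1)
    },
    dplyr::mutate(rand_gene(cfg$n_null_proteins - cfg$n_cis_null),
                  protein = null_ids[-seq_len(cfg$n_cis_null)], .before = 1),
    dplyr::mutate(rand_gene(cfg$n_tfs), protein = tf_ids, .before = 1)
  )

  # ---- truth --------------------------------------------------------------
  peak <- block$markers[1]
  effects <- dplyr::bind_rows(
    tibble::tibble(protein = module_ids, role = "module",
                   driver_marker = peak, driver_chr = block$chr,
                   trait_sign = ifelse(module_sign > 0, "+", "-"),
                   snp_effect = module_sign * lam * a, class = "cis"),
    tibble::tibble(protein = trans_id, role = "trans_member",
                   driver_marker = trans_marker,
                   driver_chr = mi$chr[match(trans_marker, mi$marker)],
                   trait_sign = "-", snp_effect = b9, class = "trans"),
    if (cfg$n_cis_null > 0) {
      tibble::tibble(protein = null_ids[seq_len(cfg$n_cis_null)],
                     role = "cis_null", driver_marker = cis_markers,
                     driver_chr = cis_chr, trait_sign = NA_character_,
                     snp_effect = cfg$cis_null_effect, class = "cis")
    }
  )
  truth <- structure(list(
    effects = effects,
    module_members = module_ids,
    trait_associated = tibble::tibble(
      protein = c(module_ids, trans_id),
      sign = c(ifelse(module_sign > 0, "+", "-"), "-")
    ),
    paths = tibble::tibble(a = a_med, b = b, c_prime = cc,
                           indirect = a_med * b, total = cc + a_med * b,
                           a_latent = a),
    strain_truth = tibble::tibble(
      strain = strains, x_block = x, z_ntg = z_ntg,
      module_latent = L, deviation = D,
      ntg_mean_true = m_ntg, ad_mean_true = m_ad
    ),
    tf = tibble::tibble(
      tf = tf_ids[seq_len(min(2, cfg$n_tfs))],
      planted = c("marginal_cor", "bb_only")[seq_len(min(2, cfg$n_tfs))],
      value = c(cfg$tf_trait_cor, sqrt(cfg$tf_bb_r2))[seq_len(min(2, cfg$n_tfs))]
    ),
    block = block[c("markers", "chr", "start", "end")],
    calibration = cal,
    config = cfg
  ), class = "resqtl_truth")

  structure(list(phenotypes = pheno, abundance = abundance,
                 samples = samples, genes = genes, truth = truth),
            class = "resqtl_cohort")
}

#' @export
print.resqtl_cohort <- function(x, ...) {
  cat("<resqtl_cohort>\n")
  cat(sprintf("  %d animals (%d AD / %d Ntg) in %d strains\n",
              nrow(x$phenotypes), sum(x$phenotypes$group == "AD"),
              sum(x$phenotypes$group == "Ntg"),
              dplyr::n_distinct(x$phenotypes$strain)))
  cat(sprintf("  %d features x %d proteomic samples; planted module of %d (+1 trans)\n",
              nrow(x$abundance), nrow(x$samples),
              length(x$truth$module_members)))
  invisible(x)
}

#' @export
print.resqtl_truth <- function(x, ...) {
  cat("<resqtl_truth>\n")
  cat(sprintf("  %d planted effects; paths a=%.2f b=%.2f c'=%.2f (indirect %.3f)\n",
              nrow(x$effects), x$paths$a, x$paths$b, x$paths$c_prime,
              x$paths$indirect))
  invisible(x)
}
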