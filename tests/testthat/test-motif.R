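write_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("BED ingestion parses sites and validates structure", {
  p <- write_bed("chr1\t100\t110\tNr1d1:MA1531.2")
  sites <- read_motif_sites(p)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$tf, "Nr1d1")
  expect_equal(sites$accession, "MA1531.2")
  expect_equal(sites$end - sites$start, 10L)
  expect_equal(sites$chr, "1")

  # empty file: empty table
  empty <- read_motif_sites(write_bed(character(0)))
  expect_equal(nrow(empty), 0)

  # malformed line numbers are reported; inverted intervals rejected
  expect_error(read_motif_sites(write_bed(c("chr1\t1\t2\tA:1", "chr1\tx"))),
               "line\\(s\\): 2")
  expect_error(read_motif_sites(write_bed("chr1\t500\t100\tA:1")),
               "start \\(500\\) must be < end")
})

test_that("a 484-site fixture parses completely", {
  lines <- sprintf("chr1\t%d\t%d\tTF%03d:MA%04d.1",
                   seq(1000, by = 500, length.out = 484),
                   seq(1015, by = 500, length.out = 484),
                   1:484, 1:484)
  sites <- read_motif_sites(write_bed(lines))
  expect_equal(nrow(sites), 484)
})

test_that("SNP-in-site intersection fixes the coordinate conversion", {
  sites <- tibble::tibble(chr = "1", start = 100L, end = 110L,
                          tf = "Nr1d1", accession = "MA1531.2")
  snps <- tibble::tibble(marker = sprintf("s%d", 1:4), chr = 1,
                         bp = c(100, 101, 110, 111))
  hits <- snps_in_sites(snps, sites)
  # 1-based bp 101..110 fall inside the half-open 0-based [100, 110)
  expect_setequal(hits$marker, c("s2", "s3"))
})

test_that("intersection agrees with an exhaustive double loop", {
  set.seed(51)
  n_snp <- 400; n_site <- 25
  snps <- tibble::tibble(marker = sprintf("s%03d", 1:n_snp),
                         chr = sample(1:3, n_snp, TRUE),
                         bp = sample(1:2000, n_snp, TRUE))
  starts <- sample(0:1900, n_site, TRUE)
  sites <- tibble::tibble(chr = as.character(sample(1:3, n_site, TRUE)),
                          start = starts,
                          end = starts + sample(5:120, n_site, TRUE),
                          tf = sprintf("TF%02d", 1:n_site),
                          accession = NA_character_)
  hits <- snps_in_sites(snps, sites)
  brute <- 0L
  for (i in seq_len(n_snp)) {
    for (j in seq_len(n_site)) {
      inside <- snps$chr[i] == as.integer(sites$chr[j]) &&
        sites$start[j] <= snps$bp[i] - 1 && snps$bp[i] - 1 < sites$end[j]
      if (inside) {
        brute <- brute + 1L
        expect_true(any(hits$marker == snps$marker[i] &
                          hits$tf == sites$tf[j]))
      }
    }
  }
  expect_equal(nrow(hits), brute)
})

test_that("the shipped synthetic fixtures intersect as documented", {
  sites <- read_motif_sites(system.file("extdata",
                                        "tfbs_sites_synthetic.bed",
                                        package = "resqtl"))
  expect_equal(nrow(sites), 10)
  snps <- readr::read_tsv(system.file("extdata",
                                      "haplotype_snps_synthetic.tsv",
                                      package = "resqtl"),
                          show_col_types = FALSE)
  hits <- snps_in_sites(snps, sites)
  nr <- hits[hits$tf == "Nr1d1", ]
  expect_equal(nr$marker, "rs46128598")
  expect_equal(nr$allele_b6, "A")
  expect_equal(nr$allele_d2, "G")
  expect_equal(nr$accession, "MA1531.2")
})

test_that("TF-trait correlations report r, p and ordering", {
  set.seed(52)
  tr <- tibble::tibble(strain = sprintf("S%02d", 1:15), resilience = rnorm(15))
  m <- rbind(same = tr$resilience, anti = -tr$resilience, noise = rnorm(15),
             flat = rep(1, 15))
  colnames(m) <- tr$strain
  expect_message(out <- tf_trait_correlation(ab_tbl(m), tr), "constant")
  expect_equal(out$r[out$tf == "same"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$tf == "anti"], -1, tolerance = 1e-12)
  expect_false("flat" %in% out$tf)
  expect_equal(out$tf[1], "same")            # sorted by r
  expect_true(all(out$q >= out$p))
})

test_that("the planted TF track correlates at the configured strength", {
  rs <- vapply(1:5, function(s) {
    cfg <- sim_config(n_strains = 300, n_chromosomes = 2,
                      n_markers_per_chrom = 11, n_null_proteins = 4,
                      n_cis_null = 1, n_tfs = 3, seed = 52 + s)
    co <- simulate_cohort(cfg, simulate_genotypes(cfg))
    res <- resilience_scores(co$phenotypes)
    sa <- strain_abundance(co$abundance, co$samples)
    tf <- sa[grepl("^TF", sa$feature), ]
    out <- tf_trait_correlation(tf, res$strains)
    expect_lt(out$p[out$tf == "TF01"], 1e-6)
    out$r[out$tf == "TF01"]
  }, numeric(1))
  expect_equal(mean(rs), 0.55, tolerance = 0.06 / 0.55)
})

test_that("genotype-stratified fits separate planted group structure", {
  cfg <- sim_config(n_strains = 200, n_chromosomes = 2,
                    n_markers_per_chrom = 11, n_null_proteins = 4,
                    n_cis_null = 1, n_tfs = 3, seed = 54)
  g <- simulate_genotypes(cfg)
  co <- simulate_cohort(cfg, g)
  res <- resilience_scores(co$phenotypes)
  sa <- strain_abundance(co$abundance, co$samples)
  peak <- genotype_block(g)$markers[1]
  # TF02 is planted to track the trait only in B/B strains
  out <- genotype_stratified_fit(res$strains, sa, g, peak, "TF02")
  r2_bb <- out$r.squared[out$genotype == "BB"]
  r2_bd <- out$r.squared[out$genotype == "BD"]
  expect_equal(r2_bb, cfg$tf_bb_r2, tolerance = 0.2)
  expect_lt(r2_bd, 0.15)
  expect_lt(out$p[out$genotype == "BB"], 0.001)
})

test_that("the unstratified fit ties correlation and regression together", {
  # r from the correlation module equals sign(slope) * sqrt(R^2) of the
  # trait-on-TF regression run without stratification
  set.seed(55)
  tr <- tibble::tibble(strain = sprintf("S%02d", 1:30),
                       resilience = rnorm(30))
  m <- matrix(0.6 * tr$resilience + 0.8 * rnorm(30), 1, 30,
              dimnames = list("TFx", tr$strain))
  ct <- tf_trait_correlation(ab_tbl(m), tr)
  fit <- summary(lm(tr$resilience ~ m[1, ]))
  expect_equal(ct$r,
               sign(fit$coefficients[2, 1]) * sqrt(fit$r.squared),
               tolerance = 1e-10)
})

test_that("small genotype groups are omitted with a warning", {
  set.seed(56)
  codes <- matrix(c(rep(0L, 8), 1L, 1L), 1, 10,
                  dimnames = list("mk", sprintf("S%02d", 1:10)))
  g <- tibble::tibble(marker = "mk", chr = 1L, bp = 1e6) |>
    dplyr::bind_cols(tibble::as_tibble(codes))
  tr <- tibble::tibble(strain = colnames(codes), resilience = rnorm(10))
  m <- matrix(rnorm(10), 1, 10, dimnames = list("TFx", colnames(codes)))
  expect_warning(out <- genotype_stratified_fit(tr, ab_tbl(m), g, "mk", "TFx"),
                 "BD")
  expect_equal(out$genotype, "BB")
})
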