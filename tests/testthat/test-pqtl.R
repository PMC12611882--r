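toy_genotypes <- function(codes, chr = NULL, bp = NULL) {
  n_mark <- nrow(codes)
  tibble::tibble(
    marker = rownames(codes) %||% sprintf("m%02d", seq_len(n_mark)),
    chr = chr %||% rep(1L, n_mark),
    bp = bp %||% seq(1e6, by = 1e6, length.out = n_mark)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(codes))
}

test_that("the minimum-strain filter keeps proteins at the boundary", {
  m <- matrix(rnorm(33), 3, 11, dimnames = list(NULL, sprintf("S%02d", 1:11)))
  m[1, 1:2] <- NA   # observed in 9 strains
  m[2, 1] <- NA     # observed in 10 strains
  ab <- ab_tbl(m)
  out <- filter_min_strains(ab, 10)
  expect_equal(out$feature, c("f2", "f3"))
  expect_equal(filter_min_strains(ab, 1), ab)
  allna <- ab
  allna[1, -1] <- NA
  expect_false("f1" %in% filter_min_strains(allna, 1)$feature)
})

test_that("the scan reproduces hand-computed regression statistics", {
  g <- toy_genotypes(matrix(c(0, 0, 1, 1), 1, 4,
                            dimnames = list("mA", sprintf("S%02d", 1:4))))
  ab <- ab_tbl(matrix(c(1.0, 1.2, 2.0, 2.2), 1, 4,
                      dimnames = list("prot", sprintf("S%02d", 1:4))))
  r <- qtl_scan(ab, g)
  expect_equal(r$beta, 1.0, tolerance = 1e-12)
  expect_equal(r$se, 0.1414, tolerance = 1e-3)
  expect_equal(r$t, 7.0711, tolerance = 1e-4)
  expect_equal(r$p, 2 * pt(-sqrt(50), 2), tolerance = 1e-10)

  # perfect fit: p underflows toward 0
  ab2 <- ab_tbl(matrix(c(0, 0, 1, 1), 1, 4,
                       dimnames = list("prot", sprintf("S%02d", 1:4))))
  r2 <- qtl_scan(ab2, g)
  expect_equal(r2$beta, 1)
  expect_lt(r2$p, 1e-12)
})

test_that("the scan matches a brute-force per-pair lm oracle", {
  set.seed(21)
  n_s <- 20; n_p <- 50; n_m <- 100
  strains <- sprintf("S%02d", seq_len(n_s))
  codes <- matrix(rbinom(n_m * n_s, 1, 0.5), n_m, n_s,
                  dimnames = list(sprintf("m%03d", seq_len(n_m)), strains))
  codes[rowSums(codes) == 0, 1] <- 1L
  codes[rowSums(codes) == n_s, 1] <- 0L
  g <- toy_genotypes(codes, chr = rep(1:4, each = 25),
                     bp = rep(seq(1e6, by = 2e6, length.out = 25), 4))
  y <- matrix(rnorm(n_p * n_s), n_p, n_s,
              dimnames = list(sprintf("P%03d", seq_len(n_p)), strains))
  y[sample(length(y), 60)] <- NA  # scattered missingness
  rec <- qtl_scan(ab_tbl(y), g)

  idx <- sample(nrow(rec), 250)
  for (i in idx) {
    yy <- y[rec$protein[i], ]
    xx <- codes[rec$marker[i], ]
    fit <- summary(lm(yy ~ xx))
    expect_equal(rec$beta[i], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(rec$t[i], fit$coefficients[2, 3], tolerance = 1e-10)
    expect_equal(rec$p[i], fit$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("all planted-block markers receive identical statistics", {
  co <- small_cohort(seed = 13)
  sa <- strain_abundance(co$abundance, co$samples)
  rec <- qtl_scan(sa, co$genotypes)
  blk <- genotype_block(co$genotypes)$markers
  sub <- rec[rec$marker %in% blk & rec$protein == "P001", ]
  expect_equal(nrow(sub), length(blk))
  expect_equal(diff(range(sub$p)), 0, tolerance = 1e-12)
  expect_equal(diff(range(sub$beta)), 0, tolerance = 1e-12)
})

test_that("monomorphic markers are skipped and reported", {
  codes <- rbind(m1 = c(0L, 0L, 0L, 0L, 0L), m2 = c(0L, 1L, 0L, 1L, 1L))
  colnames(codes) <- sprintf("S%02d", 1:5)
  g <- toy_genotypes(codes)
  ab <- ab_tbl(matrix(rnorm(5), 1, 5, dimnames = list("p", colnames(codes))))
  expect_message(rec <- qtl_scan(ab, g), "monomorphic")
  expect_equal(attr(rec, "skipped"), "m1")
  expect_equal(unique(rec$marker), "m2")
})

test_that("BH q-values are shared, monotone and order-invariant", {
  set.seed(4)
  p <- c(runif(40), 1e-6, 1e-4)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  expect_equal(q, p.adjust(p, "BH"))
  # monotone in p
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  # invariant to ordering
  perm <- sample(length(p))
  expect_equal(adjust_bh(p[perm])[order(perm)], q)
  expect_error(adjust_bh(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("cis/trans classification respects the 5 Mb window", {
  genes <- tibble::tibble(protein = "P", chr = 1L,
                          start = 10e6, end = 10.02e6)
  rec <- tibble::tibble(
    protein = "P",
    marker = c("in_window", "out_window", "other_chr"),
    chr = c(1L, 1L, 2L),
    bp = c(10.02e6 + 5e6 - 1, 10.02e6 + 5e6 + 1, 10e6)
  )
  out <- classify_cis_trans(rec, genes)
  expect_equal(out$class, c("cis", "trans", "trans"))
  # unknown gene position stays unclassified (with a note)
  rec2 <- dplyr::mutate(rec, protein = "unknown")
  expect_message(out2 <- classify_cis_trans(rec2, genes), "unclassified")
  expect_true(all(is.na(out2$class)))
})

test_that("LD r-squared matches hand correlations and flags degeneracy", {
  codes <- rbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 0L, 1L),
                 c = c(0L, 1L, 1L, 1L), d = c(0L, 0L, 1L, 1L),
                 mono = c(1L, 1L, 1L, 1L))
  colnames(codes) <- sprintf("S%02d", 1:4)
  g <- toy_genotypes(codes)
  expect_equal(ld_r2(g, "a", "d"), 1)
  expect_equal(ld_r2(g, "a", "b"), 0)
  expect_equal(ld_r2(g, "a", "c"), 1 / 3, tolerance = 1e-12)
  expect_equal(ld_r2(g, "a", "c"), ld_r2(g, "c", "a"))
  expect_error(ld_r2(g, "a", "mono"), "monomorphic")
  expect_error(ld_r2(g, "a", "nope"), "unknown marker")
})

test_that("haplotype blocks collect exactly the complete-LD members", {
  co <- small_cohort(seed = 14)
  blk_truth <- genotype_block(co$genotypes)
  blk <- haplotype_block(co$genotypes, blk_truth$markers[1])
  expect_setequal(blk$members$marker, blk_truth$markers)
  expect_true(blk$peak %in% blk$members$marker)
  expect_true(all(blk$members$r2 >= 1 - 1e-12))
  expect_gte(blk$interval$start, blk_truth$start)
  expect_lte(blk$interval$end, blk_truth$end)

  # threshold 0 admits every candidate on the chromosome
  mi <- marker_info(co$genotypes)
  all_chr1 <- mi$marker[mi$chr == 1]
  blk0 <- haplotype_block(co$genotypes, blk_truth$markers[1],
                          r2_threshold = 0)
  expect_setequal(blk0$members$marker, all_chr1)

  # no candidate at threshold: block is the peak alone
  cand <- setdiff(all_chr1, blk_truth$markers)
  blk1 <- haplotype_block(co$genotypes, blk_truth$markers[1],
                          candidates = cand, r2_threshold = 1)
  expect_equal(blk1$members$marker, blk_truth$markers[1])
})

test_that("planted cis drivers are recovered genome-wide at FDR < 0.05", {
  co <- small_cohort(seed = 15, n_strains = 30)
  sa <- strain_abundance(co$abundance, co$samples)
  rec <- qtl_scan(filter_min_strains(sa, 10), co$genotypes)
  cis <- co$truth$effects[co$truth$effects$role == "cis_null", ]
  for (i in seq_len(nrow(cis))) {
    hit <- rec[rec$protein == cis$protein[i] &
                 rec$marker == cis$driver_marker[i], ]
    expect_equal(nrow(hit), 1)
    expect_lt(hit$q, 0.05)
  }
})
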