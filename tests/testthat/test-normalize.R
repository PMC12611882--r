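test_that("median normalization equalizes sample medians on the log2 scale", {
  # samples with log2 medians 10 and 12 are shifted by -1/+1 to the global
  # median 11
  m <- rbind(2^c(9, 11), 2^c(10, 12), 2^c(11, 13))
  colnames(m) <- c("s1", "s2")
  out <- abundance_matrix(normalize_log2_median(ab_tbl(m)))
  expect_equal(unname(apply(out, 2, median)), c(11, 11))
  expect_equal(out[, "s1"], log2(m[, "s1"]) + 1, ignore_attr = TRUE)

  # already-common median: identity
  m2 <- rbind(2^c(5, 5), 2^c(6, 6), 2^c(7, 7))
  colnames(m2) <- c("a", "b")
  expect_equal(abundance_matrix(normalize_log2_median(ab_tbl(m2))),
               log2(m2), ignore_attr = TRUE)

  # single sample unchanged
  m3 <- matrix(2^c(1, 2, 3), ncol = 1, dimnames = list(NULL, "only"))
  expect_equal(abundance_matrix(normalize_log2_median(ab_tbl(m3)))[, 1],
               c(1, 2, 3), ignore_attr = TRUE)
})

test_that("median normalization rejects bad input and preserves structure", {
  m <- matrix(c(1, -2, 3, 4), 2, dimnames = list(NULL, c("s1", "s2")))
  expect_error(normalize_log2_median(ab_tbl(m)), "positive")
  m2 <- matrix(c(NA, NA, 1, 2), 2, dimnames = list(NULL, c("s1", "s2")))
  expect_error(normalize_log2_median(ab_tbl(m2)), "no observed values")
  # missing values preserved; within-sample ranks unchanged
  m3 <- matrix(2^c(1, 5, NA, 2, 9, 4), 3,
               dimnames = list(NULL, c("s1", "s2")))
  out <- abundance_matrix(normalize_log2_median(ab_tbl(m3)))
  expect_true(is.na(out[3, 1]))
  expect_equal(order(out[, 2]), order(m3[, 2]))
})

test_that("batch correction equalizes batch means and matches lm residuals", {
  set.seed(1)
  n <- 12
  batch <- rep(c("A", "B"), each = n / 2)
  samples <- tibble::tibble(sample = sprintf("s%02d", 1:n), batch = batch)
  base <- matrix(rnorm(5 * n, 20), 5, n,
                 dimnames = list(NULL, samples$sample))
  shifted <- base + 2 * (rep(batch, each = 5) == "B")
  out <- abundance_matrix(remove_batch_effect(ab_tbl(shifted), samples))
  for (i in 1:5) {
    expect_lt(abs(mean(out[i, batch == "A"]) - mean(out[i, batch == "B"])),
              1e-10)
    # equals lm residuals + grand mean
    fit <- lm(shifted[i, ] ~ factor(batch))
    expect_equal(unname(out[i, ]), unname(resid(fit) + mean(shifted[i, ])),
                 tolerance = 1e-12)
  }
  # idempotence
  out2 <- abundance_matrix(remove_batch_effect(matrix_abundance(out), samples))
  expect_lt(max(abs(out2 - out)), 1e-10)
})

test_that("batch correction agrees with limma's removeBatchEffect", {
  set.seed(2)
  n <- 10
  batch <- rep(c("A", "B"), each = 5)
  samples <- tibble::tibble(sample = sprintf("s%02d", 1:n), batch = batch)
  m <- matrix(rnorm(4 * n, 18), 4, n, dimnames = list(NULL, samples$sample))
  ours <- abundance_matrix(remove_batch_effect(ab_tbl(m), samples))
  theirs <- limma::removeBatchEffect(m, batch = batch)
  # same correction up to the per-feature constant (we re-add the grand
  # mean, limma keeps the intercept): compare after row-centering
  expect_equal(ours - rowMeans(ours), theirs - rowMeans(theirs),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("degenerate batch designs are rejected", {
  samples1 <- tibble::tibble(sample = c("s1", "s2", "s3"), batch = "A")
  m <- matrix(1:6, 2, 3, dimnames = list(NULL, samples1$sample))
  expect_error(remove_batch_effect(ab_tbl(m), samples1), "at least 2 batches")
  samples2 <- tibble::tibble(sample = c("s1", "s2", "s3"),
                             batch = c("A", "A", "B"))
  expect_error(remove_batch_effect(ab_tbl(m), samples2), "single sample")
})

test_that("protein roll-up sums in linear space and merges identical sets", {
  # two peptides with linear values 3 and 5 give protein log2(8) = 3
  ab <- tibble::tibble(feature = c("p1", "p2"), s1 = log2(c(3, 5)))
  map <- tibble::tibble(feature = c("p1", "p2"), protein = "PROT1")
  out <- rollup_proteins(ab, map)
  expect_equal(out$s1, 3)

  # one peptide per protein: rows relabeled, values unchanged
  ab2 <- tibble::tibble(feature = c("p1", "p2"), s1 = c(1.5, 2.5))
  map2 <- tibble::tibble(feature = c("p1", "p2"), protein = c("X", "Y"))
  out2 <- rollup_proteins(ab2, map2)
  expect_equal(sort(out2$feature), c("X", "Y"))
  expect_equal(sort(out2$s1), c(1.5, 2.5))

  # unmapped peptides: error by default, droppable with a warning
  expect_error(rollup_proteins(ab2, map2[1, ]), "unmapped")
  expect_warning(out4 <- rollup_proteins(ab2, map2[1, ], on_unmapped = "drop"),
                 "dropping")
  expect_equal(out4$feature, "X")
})

test_that("indistinguishable protein ids with identical peptide sets merge", {
  ab <- tibble::tibble(feature = c("pa", "pb"), s1 = c(1, 2), s2 = c(2, 3))
  # two protein ids, both mapping to {pa, pb}, collapse into one node
  map <- tibble::tibble(feature = c("pa", "pb", "pa", "pb"),
                        protein = c("G1", "G1", "G2", "G2"))
  out <- rollup_proteins(ab, map)
  expect_equal(out$feature, "G1;G2")
  expect_equal(out$s1, log2(2^1 + 2^2))
  # distinct sets stay separate
  out2 <- rollup_proteins(ab, map[1:2, ][c(1, 2), ] |>
                            dplyr::mutate(protein = c("G1", "G2")))
  expect_equal(sort(out2$feature), c("G1", "G2"))
})

test_that("PCA quality check reports normalized fractions and separation", {
  set.seed(3)
  n <- 16
  batch <- rep(c("A", "B"), each = n / 2)
  samples <- tibble::tibble(sample = sprintf("s%02d", 1:n), batch = batch)
  m <- matrix(rnorm(30 * n), 30, n, dimnames = list(NULL, samples$sample))
  qc <- pca_qc(ab_tbl(m), samples)
  expect_equal(sum(qc$variance_fractions), 1, tolerance = 1e-12)
  # batch-free data: separation near the chance level (k-1)/(n-1)
  expect_lt(qc$batch_separation, 0.35)
  # planted separation is detected
  qc2 <- pca_qc(ab_tbl(m + 3 * (rep(batch, each = 30) == "B")), samples)
  expect_gt(qc2$batch_separation, 0.8)
})

test_that("PCA quality check rejects degenerate input", {
  m <- matrix(1, 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_error(pca_qc(ab_tbl(m)), "zero total variance")
  m2 <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m2[1, 1] <- NA
  expect_error(pca_qc(ab_tbl(m2)), "complete-case")
  expect_error(pca_qc(ab_tbl(matrix(rnorm(4), 2, 2,
                                    dimnames = list(NULL, c("a", "b"))))),
               "3 samples")
})

test_that("roll-up then scan equals scanning the protein matrix directly", {
  co <- small_cohort(seed = 12)
  prot <- co$abundance
  # noise-free duplicate peptides: each protein observed twice, offset only
  pm <- abundance_matrix(prot)
  pep <- rbind(pm + 0.3, pm - 0.7)
  rownames(pep) <- c(paste0(rownames(pm), "_pep1"), paste0(rownames(pm), "_pep2"))
  map <- tibble::tibble(feature = rownames(pep),
                        protein = rep(rownames(pm), 2))
  rolled <- rollup_proteins(matrix_abundance(pep), map)
  sa1 <- strain_abundance(rolled, co$samples)
  sa2 <- strain_abundance(prot, co$samples)
  r1 <- qtl_scan(sa1, co$genotypes)
  r2 <- qtl_scan(sa2, co$genotypes)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})
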