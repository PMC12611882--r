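# Quantitative signal processing: linear peptide intensities -> log2
# median-normalized -> batch-corrected residuals -> protein roll-up, with a
# PCA check that batch structure is gone. Mirrors the Level 2 -> 3A -> 3B
# processing semantics of DIA proteomics exports.

#' Log2-transform and median-normalize sample intensities
#'
#' Values must be strictly positive (linear scale). Each sample is shifted
#' on the log2 scale by a constant so that its median equals the global
#' median of the per-sample medians; missing values are ignored in the
#' medians and preserved in the output. Within-sample rank order is
#' unchanged.
#'
#' @param abundance Wide abundance tibble (linear-scale intensities).
#' @return Wide abundance tibble on the normalized log2 scale.
#' @export
#' @examples
#' ab <- tibble::tibble(feature = c("a", "b"), s1 = c(4, 16), s2 = c(8, 32))
#' normalize_log2_median(ab)
normalize_log2_median <- function(abundance) {
  m <- abundance_matrix(abundance)
  if (any(m <= 0, na.rm = TRUE)) {
    abort("intensities must be strictly positive before log2 transform.")
  }
  lg <- log2(m)
  med <- apply(lg, 2, median, na.rm = TRUE)
  if (any(is.na(med))) {
    abort(sprintf("sample(s) with no observed values: %s",
                  paste(colnames(m)[is.na(med)], collapse = ", ")))
  }
  target <- median(med)
  matrix_abundance(sweep(lg, 2, med - target, "-"))
}

#' Regress out batch effects, feature by feature
#'
#' Fits, for each feature, a linear model of log2 abundance on batch
#' (categorical, one-hot) and returns the residuals plus the feature's
#' grand mean, so abundances stay on an interpretable scale while per-batch
#' feature means become equal to numerical precision. For a one-way batch
#' design these residuals are exactly `value - batch mean + grand mean`.
#' The operation is idempotent.
#'
#' @param abundance Wide log2 abundance tibble.
#' @param samples Sample metadata with `sample` and `batch` columns.
#' @return Batch-corrected wide abundance tibble.
#' @export
remove_batch_effect <- function(abundance, samples) {
  m <- abundance_matrix(abundance)
  if (!all(c("sample", "batch") %in% names(samples))) {
    abort("`samples` needs `sample` and `batch` columns.")
  }
  batch <- samples$batch[match(colnames(m), samples$sample)]
  if (anyNA(batch)) abort("every sample needs a batch label.")
  tab <- table(batch)
  if (length(tab) < 2) abort("need at least 2 batches to correct for batch.")
  if (any(tab < 2)) {
    abort(sprintf("batch(es) with a single sample: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")))
  }
  out <- m
  grand <- rowMeans(m, na.rm = TRUE)
  for (b in names(tab)) {
    idx <- which(batch == b)
    bm <- rowMeans(m[, idx, drop = FALSE], na.rm = TRUE)
    out[, idx] <- m[, idx, drop = FALSE] - bm + grand
  }
  matrix_abundance(out)
}

#' Roll peptides up to protein-group abundances
#'
#' Peptide quantities are back-transformed to the linear scale, summed
#' within each protein group (intensities are physically additive), and
#' re-logged. Protein groups that share an identical peptide set are
#' indistinguishable and are merged into a single node whose id joins the
#' member ids with `";"`.
#'
#' @param abundance Wide log2 peptide abundance tibble.
#' @param peptide_map Tibble mapping `feature` (peptide) to `protein`.
#' @param on_unmapped `"error"` (default) or `"drop"` (drop with a warning)
#'   for peptides absent from `peptide_map`.
#' @return Wide log2 protein abundance tibble.
#' @export
#' @examples
#' ab <- tibble::tibble(feature = c("p1", "p2"), s1 = c(log2(3), log2(5)))
#' map <- tibble::tibble(feature = c("p1", "p2"), protein = "PROT1")
#' rollup_proteins(ab, map)  # log2(8) = 3
rollup_proteins <- function(abundance, peptide_map, on_unmapped = c("error", "drop")) {
  on_unmapped <- match.arg(on_unmapped)
  m <- abundance_matrix(abundance)
  mapped <- rownames(m) %in% peptide_map$feature
  if (!all(mapped)) {
    missing <- rownames(m)[!mapped]
    if (on_unmapped == "error") {
      abort(sprintf("unmapped peptide(s): %s", paste(head(missing, 5), collapse = ", ")))
    }
    warn(sprintf("dropping %d unmapped peptide(s).", length(missing)))
    m <- m[mapped, , drop = FALSE]
  }
  map <- peptide_map[peptide_map$feature %in% rownames(m), ]
  # merge protein groups with identical peptide sets (indistinguishable
  # clusters; the map may legitimately list one peptide under several ids)
  pep_sets <- lapply(split(map$feature, map$protein),
                     function(p) sort(unique(p)))
  key <- vapply(pep_sets, paste, "", collapse = "|")
  groups <- split(names(pep_sets), key)

  lin <- 2^m
  rows <- lapply(groups, function(ids) {
    peps <- pep_sets[[ids[1]]]
    sub <- lin[peps, , drop = FALSE]
    v <- colSums(sub, na.rm = TRUE)
    v[colSums(!is.na(sub)) == 0] <- NA
    v
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(groups, function(ids) paste(sort(ids), collapse = ";"), "")
  matrix_abundance(log2(out[order(rownames(out)), , drop = FALSE]))
}

#' PCA quality check for residual batch structure
#'
#' Centers complete-case features, runs a sample-space PCA, and summarizes
#' how strongly samples cluster by batch in the first two components as a
#' between-batch over total sum-of-squares ratio (the chance level for k
#' batches over n samples is roughly `(k - 1)/(n - 1)`).
#'
#' @param abundance Wide log2 abundance tibble (>= 3 samples).
#' @param samples Optional metadata with `sample` and `batch`; without it
#'   only variance fractions and scores are returned.
#' @return List of class `resqtl_pca_qc`: `variance_fractions` (sums to 1),
#'   `scores` (tibble of sample scores), and `batch_separation` (or `NA`).
#' @export
pca_qc <- function(abundance, samples = NULL) {
  m <- abundance_matrix(abundance)
  if (ncol(m) < 3) abort("PCA quality check needs at least 3 samples.")
  complete <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(complete) < 2) abort("fewer than 2 complete-case features.")
  xt <- t(complete)
  xt <- sweep(xt, 2, colMeans(xt))
  if (sum(xt^2) < 1e-12) abort("zero total variance: samples are identical.")
  pc <- stats::prcomp(xt, center = FALSE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample = colnames(m)), scores)
  sep <- NA_real_
  if (!is.null(samples)) {
    batch <- samples$batch[match(colnames(m), samples$sample)]
    if (!anyNA(batch) && length(unique(batch)) > 1) {
      sc <- as.matrix(scores[, -1, drop = FALSE])
      centered <- sweep(sc, 2, colMeans(sc))
      total <- sum(centered^2)
      grand <- colMeans(sc)
      between <- sum(vapply(split(seq_len(nrow(sc)), batch), function(idx) {
        length(idx) * sum((colMeans(sc[idx, , drop = FALSE]) - grand)^2)
      }, numeric(1)))
      sep <- between / total
    }
  }
  structure(list(variance_fractions = frac, scores = scores,
                 batch_separation = sep),
            class = "resqtl_pca_qc")
}

#' @export
print.resqtl_pca_qc <- function(x, ...) {
  cat("<resqtl_pca_qc>\n")
  cat(sprintf("  PC1/PC2 variance fractions: %.3f / %.3f; batch separation %.3f\n",
              x$variance_fractions[1], x$variance_fractions[2],
              x$batch_separation))
  invisible(x)
}
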