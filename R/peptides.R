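#' Expand a protein matrix into batched peptide-level intensities
#'
#' Emulates the peptide-level export of a DIA experiment: each protein is
#' observed through 2--5 peptides with fixed per-peptide ionization offsets
#' plus small measurement noise, samples are assigned to batches balanced by
#' strain (round-robin over a strain-ordered layout of 14 cortex samples per
#' batch), every batch receives two pooled reference samples, and batch `b`
#' is shifted by `(b - 1) * batch_shift` log2 units. Values are returned on
#' the linear intensity scale, ready for [normalize_log2_median()].
#'
#' @param abundance Protein-level log2 abundance tibble (features x samples).
#' @param samples Sample metadata tibble with `sample` and `strain`.
#' @param cfg A [sim_config()]; uses `batch_count`, `batch_shift` and `seed`.
#' @return List with `abundance` (linear-scale peptide tibble), `samples`
#'   (metadata including `batch`, references flagged by
#'   `group == "reference"`), and `peptide_map` (`feature`, `protein`).
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 6, n_chromosomes = 2, n_null_proteins = 2,
#'                   n_cis_null = 0, n_tfs = 1, seed = 5)
#' cohort <- simulate_cohort(cfg, simulate_genotypes(cfg))
#' pep <- simulate_peptides(cohort$abundance, cohort$samples, cfg)
#' table(pep$samples$batch)
simulate_peptides <- function(abundance, samples, cfg) {
  if (!is.null(cfg$batch_count) && cfg$batch_count < 1) {
    abort("`batch_count` must be at least 1.")
  }
  set.seed(substream_seed(cfg$seed, "peptides"))
  prot <- abundance_matrix(abundance)
  n_samp <- ncol(prot)
  n_batch <- cfg$batch_count %||% ceiling(n_samp / 14)

  # balanced assignment: order samples by strain, deal round-robin
  ord <- samples$sample[order(samples$strain, samples$sample)]
  batch_of <- setNames(rep(seq_len(n_batch), length.out = length(ord)), ord)
  batch_of <- batch_of[colnames(prot)]

  n_pep <- sample(2:5, nrow(prot), replace = TRUE)
  pep_protein <- rep(rownames(prot), n_pep)
  pep_ids <- paste0(pep_protein, "_pep", unlist(lapply(n_pep, seq_len)))
  offsets <- rnorm(length(pep_ids), 0, 0.8)

  pep_log2 <- prot[pep_protein, , drop = FALSE] + offsets +
    matrix(rnorm(length(pep_ids) * n_samp, 0, 0.05), nrow = length(pep_ids))
  rownames(pep_log2) <- pep_ids

  # two pooled reference samples per batch, built from the grand profile
  ref_ids <- as.vector(outer(seq_len(n_batch), 1:2,
                             function(b, k) sprintf("REF%02d_%d", b, k)))
  ref_batch <- rep(seq_len(n_batch), 2)
  ref_log2 <- matrix(rowMeans(pep_log2), nrow = nrow(pep_log2),
                     ncol = length(ref_ids)) +
    matrix(rnorm(nrow(pep_log2) * length(ref_ids), 0, 0.05),
           nrow = nrow(pep_log2))
  colnames(ref_log2) <- ref_ids

  all_log2 <- cbind(pep_log2, ref_log2)
  all_batch <- c(batch_of, setNames(ref_batch, ref_ids))
  shifted <- sweep(all_log2, 2, (all_batch - 1) * cfg$batch_shift, "+")
  linear <- 2^shifted

  meta <- dplyr::bind_rows(
    dplyr::mutate(samples, batch = sprintf("B%02d", batch_of[samples$sample])),
    tibble::tibble(sample = ref_ids, strain = "reference",
                   group = "reference", batch = sprintf("B%02d", ref_batch))
  )
  list(
    abundance = matrix_abundance(linear),
    samples = meta,
    peptide_map = tibble::tibble(feature = pep_ids, protein = pep_protein)
  )
}
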