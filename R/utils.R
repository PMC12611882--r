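# Shared low-level helpers: the single BH routine used by every module,
# the seed-splitting rule, and converters between the wide tibble
# representations and plain matrices.

#' Benjamini-Hochberg adjusted p-values
#'
#' The single FDR routine shared by the pQTL scan, both differential
#' expression designs and the TF correlation table, so that all modules
#' control the false discovery rate identically. Thin wrapper around
#' [stats::p.adjust()] that preserves `NA`s and validates its input.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Numeric vector of BH q-values, same length and order as `p`.
#'   q-values are always greater than or equal to their p-values.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.9))
adjust_bh <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one integer seed. Stages and
#' repeated draws derive their own seeds with this labelling rule (a
#' 31-multiplier string fold modulo 2^31 - 1), so any stage can be rerun in
#' isolation and still reproduce the pipeline's draws.
#'
#' @param seed Integer master seed.
#' @param label Character label naming the substream (e.g. `"genotypes"`).
#' @return A positive integer seed below 2^31.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) s <- (s * 31 + ch) %% m
  as.integer(max(1, s))
}

# ---- wide-table <-> matrix converters ------------------------------------

#' Convert a wide abundance tibble to a numeric matrix
#'
#' Abundance tables in resqtl are tibbles whose first column (`feature`)
#' names the peptide or protein and whose remaining columns are samples or
#' strains. This strips the id column into rownames.
#'
#' @param abundance Wide abundance tibble.
#' @param id Name of the feature id column.
#' @return Numeric matrix, features in rows.
#' @export
abundance_matrix <- function(abundance, id = "feature") {
  if (!id %in% names(abundance)) {
    abort(sprintf("abundance table must have a `%s` column.", id))
  }
  if (anyDuplicated(abundance[[id]])) abort("duplicate feature ids.")
  m <- as.matrix(abundance[setdiff(names(abundance), id)])
  if (!is.numeric(m)) abort("non-numeric abundance columns.")
  rownames(m) <- abundance[[id]]
  m
}

#' @rdname abundance_matrix
#' @param m Numeric matrix with feature rownames.
#' @export
matrix_abundance <- function(m, id = "feature") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id := rownames(m)), out)
  out
}

# Genotype tables are tibbles with marker/chr/bp columns then one 0/1 column
# per strain.
genotype_meta_cols <- c("marker", "chr", "bp")

#' Extract the marker-by-strain code matrix from a genotype table
#'
#' @param genotypes Genotype tibble (`marker`, `chr`, `bp`, strain columns).
#' @return Integer matrix of 0/1 codes, markers in rows, named by marker.
#' @export
genotype_codes <- function(genotypes) {
  check_genotypes(genotypes)
  m <- as.matrix(genotypes[setdiff(names(genotypes), genotype_meta_cols)])
  rownames(m) <- genotypes$marker
  storage.mode(m) <- "integer"
  m
}

#' @rdname genotype_codes
#' @export
marker_info <- function(genotypes) {
  check_genotypes(genotypes)
  genotypes[genotype_meta_cols]
}

check_genotypes <- function(genotypes) {
  if (!all(genotype_meta_cols %in% names(genotypes))) {
    abort("genotype table needs `marker`, `chr` and `bp` columns.")
  }
  strains <- setdiff(names(genotypes), genotype_meta_cols)
  if (length(strains) == 0) abort("genotype table has no strain columns.")
  codes <- unlist(genotypes[strains], use.names = FALSE)
  if (!all(codes %in% c(0L, 1L))) {
    abort("genotype codes must be 0 (BB homozygous) or 1 (BD heterozygous).")
  }
  invisible(genotypes)
}

# mean replicate count used by heritability calibration and h2_rix
mean_replicates <- function(n_by_strain) mean(n_by_strain)

# Simple deterministic content hash (FNV-1a, 32 bit) for run manifests.
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
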