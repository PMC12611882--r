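# Transcription-factor motif integration: BED-interval ingestion,
# SNP-in-site intersection (with the 1-based SNP vs 0-based half-open BED
# conversion fixed in one place), TF-trait correlation, and
# genotype-stratified fits.

#' Read transcription-factor binding sites from a BED file
#'
#' Expects at least four tab- or space-separated columns: chromosome,
#' start, end (0-based, half-open) and a name of the form
#' `"TF:accession"` (e.g. `Nr1d1:MA1531.2`). Malformed lines are rejected
#' with their line numbers.
#'
#' @param path Path to the BED file.
#' @param strip_chr Drop a leading `"chr"` from chromosome names so they
#'   match numeric genotype chromosomes (default `TRUE`).
#' @return Tibble: `chr`, `start`, `end`, `tf`, `accession`.
#' @export
read_motif_sites <- function(path, strip_chr = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(chr = character(), start = integer(),
                          end = integer(), tf = character(),
                          accession = character()))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- integer(0)
  rows <- purrr::map2(fields, lineno, function(f, ln) {
    if (length(f) < 4) { bad <<- c(bad, ln); return(NULL) }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) { bad <<- c(bad, ln); return(NULL) }
    if (start >= end) {
      abort(sprintf("line %d: start (%s) must be < end (%s).", ln, f[2], f[3]))
    }
    name <- strsplit(f[4], ":", fixed = TRUE)[[1]]
    chr <- if (strip_chr) sub("^chr", "", f[1]) else f[1]
    tibble::tibble(chr = chr, start = as.integer(start), end = as.integer(end),
                   tf = name[1],
                   accession = if (length(name) > 1) name[2] else NA_character_)
  })
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line(s): %s", paste(bad, collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}

#' Intersect SNPs with binding-site intervals
#'
#' A SNP at 1-based position `bp` lies in the half-open site `[start, end)`
#' iff `start <= bp - 1 < end`; the 0/1-based conversion happens here and
#' nowhere else. Implemented as a non-equi join; an exhaustive double-loop
#' gives the same answer (see the package tests).
#'
#' @param snps Tibble with `marker`, `chr`, `bp` (1-based), and optionally
#'   allele columns, which are carried through.
#' @param sites Sites from [read_motif_sites()].
#' @return Tibble of intersections (possibly empty): SNP columns plus
#'   `tf`, `accession`, `start`, `end`.
#' @export
snps_in_sites <- function(snps, sites) {
  s <- dplyr::mutate(snps, chr = as.character(.data$chr), pos0 = .data$bp - 1)
  w <- dplyr::mutate(sites, chr = as.character(.data$chr))
  out <- dplyr::inner_join(
    s, w,
    by = dplyr::join_by("chr", "pos0" >= "start", "pos0" < "end")
  )
  dplyr::select(out, -"pos0")
}

#' Correlate TF abundance with the resilience trait
#'
#' Pearson correlation (two-sided t-based p) of each TF's strain-level
#' abundance with the per-strain trait, over shared strains; raw p-values
#' are reported as the primary column with BH q added alongside. Results
#' are sorted by decreasing r.
#'
#' @param abundance Wide strain-level abundance tibble of TF proteins.
#' @param trait Tibble with `strain` and trait column.
#' @param trait_col Trait column name (default `"resilience"`).
#' @return Tibble: `tf`, `n`, `r`, `p`, `q`.
#' @export
tf_trait_correlation <- function(abundance, trait, trait_col = "resilience") {
  m <- abundance_matrix(abundance)
  tr <- setNames(trait[[trait_col]], trait$strain)
  common <- intersect(colnames(m), names(tr))
  if (length(common) < 4) abort("need >= 4 shared strains.")
  tv <- as.numeric(tr[common])
  skipped <- character(0)
  rows <- purrr::map(rownames(m), function(f) {
    y <- as.numeric(m[f, common])
    ok <- !is.na(y) & !is.na(tv)
    if (sum(ok) < 4) return(NULL)
    if (sd(y[ok]) < 1e-12 || sd(tv[ok]) < 1e-12) {
      skipped <<- c(skipped, f)
      return(NULL)
    }
    ct <- cor.test(y[ok], tv[ok])
    tibble::tibble(tf = f, n = sum(ok), r = unname(ct$estimate),
                   p = ct$p.value)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no testable TFs.")
  out <- dplyr::arrange(dplyr::mutate(out, q = adjust_bh(.data$p)),
                        dplyr::desc(.data$r))
  if (length(skipped) > 0) {
    inform(sprintf("skipped %d constant TF track(s).", length(skipped)))
  }
  out
}

#' Trait-on-TF regression stratified by genotype
#'
#' Within each genotype group at `marker` (B/B = 0, B/D = 1), ordinary
#' least squares of the per-strain trait on TF abundance; groups with
#' fewer than 3 strains are omitted with a warning.
#'
#' @param trait Tibble with `strain` and trait column.
#' @param abundance Wide strain-level abundance tibble containing `tf`.
#' @param genotypes Genotype tibble.
#' @param marker Stratifying marker id.
#' @param tf Feature id of the TF protein.
#' @param trait_col Trait column name.
#' @return Tibble: `genotype` (`"BB"`/`"BD"`), `n`, `slope`, `r.squared`,
#'   `p`.
#' @export
genotype_stratified_fit <- function(trait, abundance, genotypes, marker,
                                    tf, trait_col = "resilience") {
  m <- abundance_matrix(abundance)
  if (!tf %in% rownames(m)) abort(sprintf("unknown TF feature `%s`.", tf))
  g <- genotype_codes(genotypes)
  if (!marker %in% rownames(g)) abort(sprintf("unknown marker `%s`.", marker))
  tr <- setNames(trait[[trait_col]], trait$strain)
  common <- Reduce(intersect, list(colnames(m), colnames(g), names(tr)))
  x <- as.numeric(g[marker, common])
  ab <- as.numeric(m[tf, common])
  tv <- as.numeric(tr[common])
  rows <- purrr::map(c(BB = 0, BD = 1), function(code) {
    idx <- which(x == code & !is.na(ab) & !is.na(tv))
    if (length(idx) < 3) return(NULL)
    fit <- summary(lm(tv[idx] ~ ab[idx]))
    tibble::tibble(n = length(idx), slope = fit$coefficients[2, 1],
                   r.squared = fit$r.squared,
                   p = fit$coefficients[2, 4])
  })
  omitted <- names(rows)[vapply(rows, is.null, TRUE)]
  if (length(omitted) > 0) {
    warn(sprintf("omitting genotype group(s) with < 3 strains: %s",
                 paste(omitted, collapse = ", ")))
  }
  dplyr::bind_rows(rows, .id = "genotype")
}
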