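# Readers and writers for the plain-text interchange formats: genotype TSV
# (GeneNetwork-style: marker, chr, bp, then one column per strain coded
# B/H or 0/1), phenotype CSV, wide abundance CSV with a sidecar sample
# metadata CSV, and gene-position TSV. Writing then reading any of them is
# an identity on content.

#' Read a genotype TSV
#'
#' Header names the strain columns; each row is `marker`, `chr`, `bp`
#' followed by codes in `{B, H, 0, 1}` (`B` -> 0 homozygous, `H` -> 1
#' heterozygous). Positions must be strictly increasing within chromosome
#' and marker ids unique; unknown codes are reported with their row and
#' column.
#'
#' @param path Path to the TSV.
#' @return Genotype tibble.
#' @export
read_genotype_file <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), chr = readr::col_integer(),
    bp = readr::col_double(), .default = readr::col_character()
  ), progress = FALSE)
  if (!all(genotype_meta_cols %in% names(raw))) {
    abort("genotype file must start with columns marker, chr, bp.")
  }
  if (anyDuplicated(raw$marker)) {
    abort(sprintf("duplicate marker id(s): %s",
                  paste(unique(raw$marker[duplicated(raw$marker)]), collapse = ", ")))
  }
  for (ch in unique(raw$chr)) {
    bp <- raw$bp[raw$chr == ch]
    if (any(diff(bp) <= 0)) {
      abort(sprintf("positions not strictly increasing on chromosome %s.", ch))
    }
  }
  strains <- setdiff(names(raw), genotype_meta_cols)
  for (sc in strains) {
    v <- raw[[sc]]
    bad <- which(!v %in% c("B", "H", "0", "1"))
    if (length(bad) > 0) {
      abort(sprintf("unknown genotype code '%s' at row %d, column %s.",
                    v[bad[1]], bad[1], sc))
    }
    raw[[sc]] <- as.integer(ifelse(v %in% c("B", "0"), 0L, 1L))
  }
  raw
}

#' @rdname read_genotype_file
#' @param genotypes Genotype tibble.
#' @param codes Write numeric `0/1` (default) or letter `B/H` codes.
#' @export
write_genotype_file <- function(genotypes, path, codes = c("01", "BH")) {
  codes <- match.arg(codes)
  check_genotypes(genotypes)
  out <- genotypes
  if (codes == "BH") {
    for (sc in setdiff(names(out), genotype_meta_cols)) {
      out[[sc]] <- ifelse(out[[sc]] == 0, "B", "H")
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write a phenotype CSV
#'
#' Columns: `animal`, `strain`, `group` (`AD`/`Ntg`), `sex`, `age`, `cfm`,
#' `cfa`; freezing percentages are validated to `[0, 100]` and animal ids
#' to uniqueness.
#'
#' @param path File path.
#' @return Phenotype tibble.
#' @export
read_phenotype_file <- function(path) {
  ph <- readr::read_csv(path, col_types = readr::cols(
    animal = readr::col_character(), strain = readr::col_character(),
    group = readr::col_character(), sex = readr::col_character(),
    age = readr::col_double(), cfm = readr::col_double(),
    cfa = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(ph$animal)) abort("duplicate animal id(s).")
  for (tr in c("cfm", "cfa")) {
    v <- ph[[tr]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      abort(sprintf("`%s` must be a percent in [0, 100].", tr))
    }
  }
  if (!all(ph$group %in% c("AD", "Ntg"))) abort("group must be AD or Ntg.")
  ph
}

#' @rdname read_phenotype_file
#' @param phenotypes Phenotype tibble.
#' @export
write_phenotype_file <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path, progress = FALSE)
  invisible(path)
}

#' Read or write a wide abundance CSV (with optional sample metadata)
#'
#' @param path File path.
#' @return Wide abundance tibble.
#' @export
read_abundance_file <- function(path) {
  ab <- readr::read_csv(path, col_types = readr::cols(
    feature = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(ab$feature)) abort("duplicate feature id(s).")
  ab
}

#' @rdname read_abundance_file
#' @param abundance Wide abundance tibble.
#' @export
write_abundance_file <- function(abundance, path) {
  readr::write_csv(abundance, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_abundance_file
#' @export
read_samples_file <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' @rdname read_abundance_file
#' @param samples Sample metadata tibble.
#' @export
write_samples_file <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read or write a gene-position TSV
#'
#' Columns: `protein`, `chr`, `start`, `end`.
#' @param path File path.
#' @export
read_genes_file <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(), chr = readr::col_integer(),
    start = readr::col_double(), end = readr::col_double()
  ), progress = FALSE)
  if (any(g$start >= g$end)) abort("gene start must be < end.")
  g
}

#' @rdname read_genes_file
#' @param genes Gene-position tibble.
#' @export
write_genes_file <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}
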