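# Additive-model protein QTL scan, cis/trans classification, and
# LD/haplotype-block extraction.

#' Average sample-level abundances to strain level
#'
#' The scan runs on one value per strain; when several animals per strain
#' were profiled, their (log2) abundances are averaged.
#'
#' @param abundance Wide abundance tibble (features x samples).
#' @param samples Metadata with `sample` and `strain` (reference samples,
#'   i.e. `strain == "reference"`, are dropped).
#' @return Wide abundance tibble with one column per strain.
#' @export
strain_abundance <- function(abundance, samples) {
  m <- abundance_matrix(abundance)
  strain <- samples$strain[match(colnames(m), samples$sample)]
  keep <- !is.na(strain) & strain != "reference"
  m <- m[, keep, drop = FALSE]
  strain <- strain[keep]
  out <- vapply(split(seq_along(strain), strain), function(idx) {
    rowMeans(m[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  out[is.nan(out)] <- NA
  matrix_abundance(out)
}

#' Drop proteins observed in too few strains
#'
#' Restricts the scan to proteins with non-missing strain-level data in at
#' least `min_strains` strains (default 10), the coverage needed for a
#' stable per-marker regression.
#'
#' @param abundance Wide strain-level abundance tibble.
#' @param min_strains Minimum number of observed strains.
#' @return Filtered abundance tibble.
#' @export
filter_min_strains <- function(abundance, min_strains = 10) {
  m <- abundance_matrix(abundance)
  keep <- rowSums(!is.na(m)) >= min_strains
  abundance[keep, , drop = FALSE]
}

#' Genome scan of protein abundance on genotype
#'
#' For every protein x marker pair, fits the simple additive regression of
#' strain-level abundance on the 0/1 genotype code (BB = 0, BD = 1) over
#' the pairwise-complete strains, and reports the slope, t statistic and
#' two-sided p-value. Benjamini-Hochberg q-values are computed jointly over
#' all tests (set `per_protein_fdr = TRUE` to adjust within protein
#' instead). Markers monomorphic over the tested strains are skipped and
#' counted in the `skipped` attribute.
#'
#' @param abundance Wide strain-level abundance tibble.
#' @param genotypes Genotype tibble (`marker`, `chr`, `bp`, strain columns).
#' @param fdr Significance threshold on q (default 0.05).
#' @param per_protein_fdr Adjust within protein rather than globally.
#' @return Tibble of records: `protein`, `marker`, `chr`, `bp`, `n`,
#'   `beta`, `se`, `t`, `p`, `q`, `significant`.
#' @export
qtl_scan <- function(abundance, genotypes, fdr = 0.05,
                     per_protein_fdr = FALSE) {
  y <- abundance_matrix(abundance)
  g <- genotype_codes(genotypes)
  mi <- marker_info(genotypes)
  common <- intersect(colnames(y), colnames(g))
  if (length(common) < 4) abort("need >= 4 strains shared between matrices.")
  y <- y[, common, drop = FALSE]
  g <- g[, common, drop = FALSE]

  obs <- !is.na(y)
  y0 <- y
  y0[!obs] <- 0
  sum_y <- rowSums(y0)
  sum_y2 <- rowSums(y0^2)

  skipped <- character(0)
  res <- vector("list", nrow(g))
  for (k in seq_len(nrow(g))) {
    x <- as.numeric(g[k, ])
    if (length(unique(x)) < 2) {
      skipped <- c(skipped, rownames(g)[k])
      next
    }
    n <- rowSums(obs)
    sx <- as.numeric(obs %*% x)
    sx2 <- as.numeric(obs %*% x^2)
    sxy <- as.numeric(y0 %*% x)
    sxx <- sx2 - sx^2 / n
    sxy_c <- sxy - sx * sum_y / n
    syy <- sum_y2 - sum_y^2 / n
    ok <- n >= 4 & sxx > 1e-12
    beta <- ifelse(ok, sxy_c / sxx, NA)
    sse <- pmax(0, syy - beta * sxy_c)
    df <- n - 2
    se <- ifelse(ok, sqrt(sse / df / sxx), NA)
    tstat <- ifelse(se > 0, beta / se, ifelse(ok, sign(beta) * Inf, NA))
    p <- 2 * pt(-abs(tstat), df)
    res[[k]] <- tibble::tibble(
      protein = rownames(y)[ok], marker = rownames(g)[k],
      n = as.integer(unname(n[ok])), beta = unname(beta[ok]),
      se = unname(se[ok]), t = unname(tstat[ok]), p = unname(p[ok])
    )
  }
  records <- dplyr::bind_rows(res)
  if (nrow(records) == 0) abort("no testable protein x marker pairs.")
  records <- dplyr::left_join(records, mi, by = "marker")
  if (per_protein_fdr) {
    records <- dplyr::mutate(records, q = adjust_bh(.data$p), .by = "protein")
  } else {
    records <- dplyr::mutate(records, q = adjust_bh(.data$p))
  }
  records <- records |>
    dplyr::mutate(significant = .data$q < fdr) |>
    dplyr::select("protein", "marker", "chr", "bp", "n", "beta", "se",
                  "t", "p", "q", "significant")
  if (length(skipped) > 0) {
    inform(sprintf("skipped %d monomorphic marker(s).", length(skipped)))
  }
  attr(records, "skipped") <- skipped
  records
}

#' Peak marker per significant protein
#'
#' The peak is the minimum-p marker among a protein's records; ties break
#' by lowest chromosome, then position. Only proteins with at least one
#' significant record are reported.
#'
#' @param records Output of [qtl_scan()].
#' @return One record per significant protein.
#' @export
pqtl_peaks <- function(records) {
  records |>
    dplyr::filter(any(.data$significant), .by = "protein") |>
    dplyr::arrange(.data$p, .data$chr, .data$bp) |>
    dplyr::slice_head(n = 1, by = "protein")
}

#' Classify pQTL records as cis or trans
#'
#' A record is `cis` when its marker lies on the same chromosome as the
#' gene encoding the protein and within `window` bases of the gene
#' interval; `trans` when farther away or on a different chromosome.
#' Records whose protein has no known gene position keep `NA`.
#'
#' @param records Output of [qtl_scan()] (or any tibble with `protein`,
#'   `chr`, `bp`).
#' @param genes Tibble with `protein`, `chr`, `start`, `end`.
#' @param window Distance window in bases (default 5 Mb).
#' @return `records` with a `class` column.
#' @export
classify_cis_trans <- function(records, genes, window = 5e6) {
  g <- dplyr::rename(genes, gene_chr = "chr", gene_start = "start",
                     gene_end = "end")
  out <- dplyr::left_join(records, g, by = "protein")
  n_unknown <- sum(is.na(out$gene_chr))
  if (n_unknown > 0) {
    inform(sprintf("%d record(s) without a gene position left unclassified.",
                   n_unknown))
  }
  out |>
    dplyr::mutate(class = dplyr::case_when(
      is.na(.data$gene_chr) ~ NA_character_,
      .data$chr != .data$gene_chr ~ "trans",
      .data$bp >= .data$gene_start - window &
        .data$bp <= .data$gene_end + window ~ "cis",
      TRUE ~ "trans"
    )) |>
    dplyr::select(-"gene_chr", -"gene_start", -"gene_end")
}

#' Linkage disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of the two 0/1 code vectors over their
#' shared strains; symmetric and in `[0, 1]`.
#'
#' @param genotypes Genotype tibble.
#' @param a,b Marker ids.
#' @return r-squared.
#' @export
#' @examples
#' # identical columns give exactly 1
ld_r2 <- function(genotypes, a, b) {
  g <- genotype_codes(genotypes)
  for (mk in c(a, b)) {
    if (!mk %in% rownames(g)) abort(sprintf("unknown marker `%s`.", mk))
  }
  va <- as.numeric(g[a, ])
  vb <- as.numeric(g[b, ])
  if (length(unique(va)) < 2 || length(unique(vb)) < 2) {
    abort("monomorphic marker: r-squared undefined.")
  }
  cor(va, vb)^2
}

#' Extract the haplotype block around a peak marker
#'
#' Members are the candidate markers whose LD r-squared with the peak
#' reaches `r2_threshold` (compared with 1e-12 floating slack, so exact
#' complete linkage at threshold 1 is matched reliably). The block interval
#' spans the member positions.
#'
#' @param genotypes Genotype tibble.
#' @param peak Peak marker id (must be polymorphic).
#' @param candidates Candidate marker ids; default: all markers on the
#'   peak's chromosome.
#' @param r2_threshold Membership threshold (default 1.0, complete linkage).
#' @return Object of class `haplotype_block`: `peak`, `members` tibble
#'   (`marker`, `chr`, `bp`, `r2`), `interval`.
#' @export
haplotype_block <- function(genotypes, peak, candidates = NULL,
                            r2_threshold = 1.0) {
  g <- genotype_codes(genotypes)
  mi <- marker_info(genotypes)
  if (!peak %in% rownames(g)) abort(sprintf("unknown peak marker `%s`.", peak))
  vp <- as.numeric(g[peak, ])
  if (length(unique(vp)) < 2) abort("peak marker is monomorphic.")
  if (is.null(candidates)) {
    candidates <- mi$marker[mi$chr == mi$chr[mi$marker == peak]]
  }
  candidates <- union(candidates, peak)
  r2 <- vapply(candidates, function(mk) {
    v <- as.numeric(g[mk, ])
    if (length(unique(v)) < 2) return(NA_real_)
    cor(vp, v)^2
  }, numeric(1))
  members <- mi |>
    dplyr::filter(.data$marker %in% candidates) |>
    dplyr::mutate(r2 = r2[.data$marker]) |>
    dplyr::filter(!is.na(.data$r2), .data$r2 >= r2_threshold - 1e-12) |>
    dplyr::arrange(.data$chr, .data$bp)
  structure(list(
    peak = peak,
    members = members,
    interval = tibble::tibble(chr = members$chr[which.min(members$bp)],
                              start = min(members$bp), end = max(members$bp))
  ), class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat("<haplotype_block>\n")
  cat(sprintf("  peak %s; %d member(s); chr%s:%d-%d\n", x$peak,
              nrow(x$members), x$interval$chr, x$interval$start,
              x$interval$end))
  invisible(x)
}
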