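# Differential expression: protein-vs-resilience regression, and
# genotype-stratified group comparison with an empirical-Bayes moderated t.

#' Regress protein abundance on the resilience trait
#'
#' For each protein, ordinary least squares of strain-level abundance on
#' the per-strain resilience trait over pairwise-complete strains. BH
#' q-values are computed over the tested set -- when chained after the pQTL
#' scan this is the pQTL-significant proteins, matching the analysis design
#' in which only genetically regulated proteins are interrogated.
#'
#' @param abundance Wide strain-level abundance tibble.
#' @param trait Tibble with `strain` and a trait column (default name
#'   `resilience`), e.g. `resilience_scores(...)$strains`.
#' @param trait_col Name of the trait column in `trait`.
#' @param fdr Significance threshold on q.
#' @return Tibble: `protein`, `n`, `beta`, `se`, `t`, `p`, `q`,
#'   `direction` (`"+"`/`"-"`), `significant`. Constant-abundance proteins
#'   are skipped (`skipped` attribute).
#' @export
trait_association <- function(abundance, trait, trait_col = "resilience",
                              fdr = 0.05) {
  m <- abundance_matrix(abundance)
  tr <- setNames(trait[[trait_col]], trait$strain)
  common <- intersect(colnames(m), names(tr))
  if (length(common) < 4) abort("need >= 4 strains with abundance and trait.")
  m <- m[, common, drop = FALSE]
  tv <- as.numeric(tr[common])

  skipped <- character(0)
  rows <- purrr::map(rownames(m), function(p) {
    y <- as.numeric(m[p, ])
    ok <- !is.na(y) & !is.na(tv)
    if (sum(ok) < 4) return(NULL)
    if (sd(y[ok]) < 1e-12) {
      skipped <<- c(skipped, p)
      return(NULL)
    }
    x <- tv[ok]
    y <- y[ok]
    n <- length(y)
    sxx <- sum((x - mean(x))^2)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
    sse <- sum((y - mean(y) - beta * (x - mean(x)))^2)
    se <- sqrt(sse / (n - 2) / sxx)
    tstat <- if (se > 0) beta / se else sign(beta) * Inf
    tibble::tibble(protein = p, n = n, beta = beta, se = se, t = tstat,
                   p = 2 * pt(-abs(tstat), n - 2))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no testable proteins.")
  out <- out |>
    dplyr::mutate(q = adjust_bh(.data$p),
                  direction = ifelse(.data$beta >= 0, "+", "-"),
                  significant = .data$q < fdr)
  if (length(skipped) > 0) {
    inform(sprintf("skipped %d constant protein(s).", length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Genotype-stratified differential expression with a moderated t
#'
#' Strains are stratified by genotype at `marker` -- homozygous B/B
#' (code 0) versus heterozygous B/D (code 1) -- and each protein is
#' contrasted between groups. The log2 fold change is oriented
#' `mean(BB) - mean(BD)`, so a positive value means higher abundance in
#' B/B strains. Significance uses an empirical-Bayes moderated t: the
#' per-protein pooled variance is shrunk toward a scaled
#' inverse-chi-square prior whose degrees of freedom `d0` and scale `s0^2`
#' are estimated from the spread of the per-protein sample variances by
#' moment matching (`d0` solves `var(s^2)/mean(s^2)^2 = 2(d + d0 - 2) /
#' (d (d0 - 4))`); the moderated variance is the convex combination
#' `(d0 s0^2 + d s^2) / (d0 + d)` and the t reference has `d + d0` degrees
#' of freedom. Set `moderated = FALSE` for the ordinary t.
#'
#' @param abundance Wide strain-level log2 abundance tibble.
#' @param genotypes Genotype tibble.
#' @param marker Marker id to stratify on.
#' @param moderated Use variance shrinkage (default `TRUE`).
#' @param fdr Significance threshold on q.
#' @return Tibble: `protein`, `n_bb`, `n_bd`, `log2fc`, `t`, `df`, `p`,
#'   `q`, `direction`, `significant`, with `prior_df` and `prior_var`
#'   attributes when moderated.
#' @export
stratified_de <- function(abundance, genotypes, marker, moderated = TRUE,
                          fdr = 0.05) {
  m <- abundance_matrix(abundance)
  g <- genotype_codes(genotypes)
  if (!marker %in% rownames(g)) abort(sprintf("unknown marker `%s`.", marker))
  common <- intersect(colnames(m), colnames(g))
  x <- as.numeric(g[marker, common])
  bb <- common[x == 0]
  bd <- common[x == 1]
  if (length(bb) < 2 || length(bd) < 2) {
    abort("each genotype group needs at least 2 strains.")
  }
  mb <- m[, bb, drop = FALSE]
  md <- m[, bd, drop = FALSE]
  n1 <- rowSums(!is.na(mb))
  n2 <- rowSums(!is.na(md))
  ok <- n1 >= 2 & n2 >= 2
  mean1 <- rowMeans(mb, na.rm = TRUE)
  mean2 <- rowMeans(md, na.rm = TRUE)
  v1 <- apply(mb, 1, var, na.rm = TRUE)
  v2 <- apply(md, 1, var, na.rm = TRUE)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  log2fc <- mean1 - mean2

  prior <- list(d0 = 0, s02 = NA_real_)
  if (moderated) {
    prior <- moment_match_prior(s2[ok], d[ok])
    if (is.finite(prior$d0)) {
      s2_mod <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
      df <- d + prior$d0
    } else {
      s2_mod <- rep(prior$s02, length(s2))
      df <- rep(1e6, length(s2))
    }
  } else {
    s2_mod <- s2
    df <- d
  }
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, log2fc / se, sign(log2fc) * Inf)
  p <- 2 * pt(-abs(tstat), df)
  out <- tibble::tibble(
    protein = rownames(m), n_bb = as.integer(unname(n1)),
    n_bd = as.integer(unname(n2)), log2fc = unname(log2fc),
    t = unname(tstat), df = unname(df), p = unname(p)
  )[ok, ]
  out <- out |>
    dplyr::mutate(q = adjust_bh(.data$p),
                  direction = ifelse(.data$log2fc >= 0, "+", "-"),
                  significant = .data$q < fdr)
  attr(out, "prior_df") <- prior$d0
  attr(out, "prior_var") <- prior$s02
  out
}

# Moment-match a scaled inverse-chi-square prior to the observed sample
# variances: marginally s^2/s0^2 ~ (d0/(d0-2)) F(d, d0), so
# var/mean^2 = 2 (d + d0 - 2) / (d (d0 - 4)).
moment_match_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  d <- mean(d)
  m1 <- mean(s2)
  v <- var(s2) / m1^2
  if (v * d <= 2) return(list(d0 = Inf, s02 = m1))
  d0 <- (2 * d - 4 + 4 * v * d) / (v * d - 2)
  if (d0 <= 4) d0 <- 4.001  # keep the matched moments finite
  s02 <- m1 * (d0 - 2) / d0
  list(d0 = d0, s02 = s02)
}
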