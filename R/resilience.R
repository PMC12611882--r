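# The quantitative resilience trait: how far each transgenic animal's
# contextual fear memory falls from the expectation set by its strain's
# non-transgenic littermates, plus ANOVA heritability with the strain-mean
# (replicate-adjusted) correction.

#' Per-strain trait means
#'
#' @param phenotypes Phenotype tibble (`animal`, `strain`, `group`, trait
#'   columns such as `cfm`).
#' @param group Which transgene group to average (`"Ntg"` or `"AD"`).
#' @param trait Name of the trait column.
#' @return Tibble with `strain`, `mean`, `n`; strains without animals in
#'   the group are omitted.
#' @export
#' @examples
#' ph <- tibble::tibble(animal = c("a1", "a2"), strain = "S01",
#'                      group = "Ntg", cfm = c(30, 50))
#' strain_means(ph)  # mean 40
strain_means <- function(phenotypes, group = "Ntg", trait = "cfm") {
  if (!trait %in% names(phenotypes)) abort(sprintf("no `%s` column.", trait))
  phenotypes |>
    dplyr::filter(.data$group == !!group) |>
    dplyr::summarise(mean = mean(.data[[trait]]), n = dplyr::n(),
                     .by = "strain")
}

#' Quantitative resilience trait scores
#'
#' Regresses individual AD-animal trait values on their strain's Ntg mean
#' with weights `1/n_s` (`n_s` = AD replicates in the strain). With these
#' weights the objective separates into a within-strain constant plus the
#' strain-mean sum of squares, so the fitted slope and intercept equal the
#' unweighted regression of AD strain means on Ntg strain means exactly --
#' the property that defines the trait. Each animal's residual from this
#' line, standardized to a z-score over all included AD animals, is the
#' quantitative resilience trait; a strain's resilience is the mean of its
#' animals' z-scores.
#'
#' Heritability of the scores (ANOVA SS ratio over strains with >= 2
#' animals, plus the strain-mean form) is computed alongside.
#'
#' @param phenotypes Phenotype tibble containing both `AD` and `Ntg` rows.
#' @param trait Trait column to score (default `"cfm"`).
#' @return Object of class `resilience_result` with elements `fit` (slope,
#'   intercept, r.squared, p.value of the strain-mean regression), `animals`
#'   (per-animal residuals and z-scores), `strains` (per-strain resilience
#'   and n), and `heritability` (h2, h2_rix, n_bar).
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 12, n_chromosomes = 2, n_null_proteins = 2,
#'                   n_cis_null = 0, n_tfs = 1, seed = 11)
#' cohort <- simulate_cohort(cfg, simulate_genotypes(cfg))
#' res <- resilience_scores(cohort$phenotypes)
#' glance(res)
resilience_scores <- function(phenotypes, trait = "cfm") {
  ntg <- strain_means(phenotypes, "Ntg", trait)
  ad <- dplyr::filter(phenotypes, .data$group == "AD")
  if (nrow(ad) == 0) abort("no AD animals in the phenotype table.")
  missing_ntg <- setdiff(unique(ad$strain), ntg$strain)
  if (length(missing_ntg) > 0) {
    warn(sprintf("dropping %d AD strain(s) without an Ntg baseline: %s",
                 length(missing_ntg), paste(missing_ntg, collapse = ", ")))
    ad <- dplyr::filter(ad, !.data$strain %in% missing_ntg)
  }
  if (dplyr::n_distinct(ad$strain) < 3) {
    abort("need at least 3 strains with both AD and Ntg animals.")
  }
  ad <- ad |>
    dplyr::left_join(dplyr::rename(ntg, ntg_mean = "mean", ntg_n = "n"),
                     by = "strain") |>
    dplyr::mutate(n_s = dplyr::n(), .by = "strain")

  fit <- lm(y ~ x, data = data.frame(y = ad[[trait]], x = ad$ntg_mean),
            weights = 1 / ad$n_s)
  res <- ad[[trait]] - (coef(fit)[1] + coef(fit)[2] * ad$ntg_mean)
  if (sd(res) < 1e-12) abort("zero residual SD: AD values lie exactly on the fit.")
  z <- as.numeric(scale(res))

  sm <- dplyr::summarise(ad, ad_mean = mean(.data[[trait]]),
                         ntg_mean = .data$ntg_mean[1], .by = "strain")
  mfit <- lm(ad_mean ~ ntg_mean, data = sm)
  msum <- summary(mfit)

  animals <- tibble::tibble(
    animal = ad$animal, strain = ad$strain, value = ad[[trait]],
    ntg_mean = ad$ntg_mean, residual = res, resilience = z
  )
  strains <- dplyr::summarise(animals, resilience = mean(.data$resilience),
                              n = dplyr::n(), .by = "strain")
  her <- heritability(animals, value = "resilience", strain = "strain")
  structure(list(
    fit = tibble::tibble(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r.squared = msum$r.squared,
      p.value = stats::pf(msum$fstatistic[1], msum$fstatistic[2],
                          msum$fstatistic[3], lower.tail = FALSE),
      n_strains = nrow(sm)
    ),
    animals = animals, strains = strains, heritability = her,
    trait = trait
  ), class = "resilience_result")
}

#' ANOVA heritability with the strain-mean correction
#'
#' One-way ANOVA over strains with at least `min_n` values gives
#' `h2 = SS_strain / (SS_strain + SS_residuals)`. The strain-mean
#' (replicate-adjusted) form, appropriate for recombinant inbred panels
#' where strain means average away environmental noise, is
#' `h2_rix = h2 / (h2 + (1 - h2) / n)` with `n` the average number of
#' replicates per retained strain.
#'
#' @param data Tibble with one row per animal.
#' @param value Name of the trait column.
#' @param strain Name of the strain column.
#' @param min_n Minimum replicates for a strain to enter (default 2).
#' @return One-row tibble: `h2`, `h2_rix`, `n_bar`, `n_strains`,
#'   `ss_strain`, `ss_residual`.
#' @export
#' @examples
#' d <- tibble::tibble(strain = rep(c("A", "B"), each = 2), y = c(1, 3, 5, 7))
#' heritability(d, value = "y")  # h2 = 0.8, h2_rix = 0.889
heritability <- function(data, value = "resilience", strain = "strain",
                         min_n = 2) {
  d <- tibble::tibble(y = data[[value]], strain = as.character(data[[strain]]))
  d <- dplyr::filter(d, !is.na(.data$y))
  d <- dplyr::mutate(d, n = dplyr::n(), .by = "strain")
  d <- dplyr::filter(d, .data$n >= min_n)
  if (dplyr::n_distinct(d$strain) < 2) {
    abort(sprintf("need >= 2 strains with >= %d values.", min_n))
  }
  # one-way ANOVA sums of squares by group arithmetic (identical to
  # anova(aov(y ~ strain)), but linear in the number of animals, so panels
  # with thousands of strains stay cheap; equality with aov is asserted in
  # the test suite)
  grand <- mean(d$y)
  per <- dplyr::summarise(d, m = mean(.data$y), n = dplyr::n(),
                          ssw = sum((.data$y - mean(.data$y))^2),
                          .by = "strain")
  ss_strain <- sum(per$n * (per$m - grand)^2)
  ss_resid <- sum(per$ssw)
  if (ss_strain + ss_resid < 1e-12) abort("total sum of squares is zero.")
  h2 <- ss_strain / (ss_strain + ss_resid)
  n_bar <- mean(per$n)
  tibble::tibble(
    h2 = h2,
    h2_rix = h2_rix(h2, n_bar),
    n_bar = n_bar,
    n_strains = dplyr::n_distinct(d$strain),
    ss_strain = ss_strain, ss_residual = ss_resid
  )
}

#' Strain-mean heritability formula
#'
#' `h2 / (h2 + (1 - h2) / n)`: the fraction of strain-mean variance that is
#' genetic when each strain mean averages `n` replicates. Equals `h2` at
#' `n = 1` and approaches 1 as `n` grows (for `h2 > 0`).
#'
#' @param h2 Per-animal heritability in `[0, 1]`.
#' @param n Average replicates per strain.
#' @return `h2_rix` in `[0, 1]`.
#' @export
#' @examples
#' h2_rix(0.26, 7)  # ~0.71
h2_rix <- function(h2, n) {
  stopifnot(h2 >= 0, h2 <= 1, n >= 1)
  if (h2 == 0) return(0)
  h2 / (h2 + (1 - h2) / n)
}

#' @export
print.resilience_result <- function(x, ...) {
  cat("<resilience_result>\n")
  cat(sprintf("  strain-mean fit: slope %.3f, intercept %.2f, R2 %.3f (p %.3g)\n",
              x$fit$slope, x$fit$intercept, x$fit$r.squared, x$fit$p.value))
  cat(sprintf("  %d AD animals in %d strains; h2 %.3f, h2_rix %.3f (n %.1f)\n",
              nrow(x$animals), nrow(x$strains),
              x$heritability$h2, x$heritability$h2_rix, x$heritability$n_bar))
  invisible(x)
}

#' @rdname resilience_scores
#' @param x,object A `resilience_result`.
#' @param ... Unused.
#' @method tidy resilience_result
#' @export
tidy.resilience_result <- function(x, ...) x$strains

#' @rdname resilience_scores
#' @method glance resilience_result
#' @export
glance.resilience_result <- function(x, ...) {
  dplyr::bind_cols(x$fit, x$heritability)
}
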