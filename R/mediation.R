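# PCA over the resilience-associated protein module and Baron-Kenny
# mediation of SNP -> PC1 -> resilience with a stratified BCa bootstrap.

#' Principal components of a protein module
#'
#' Each protein is z-scored across strains (so the decomposition is of the
#' correlation structure) before the eigendecomposition. The PC1 sign is
#' fixed so that its mean loading is positive, making "higher PC1 = higher
#' average module abundance" a stable convention.
#'
#' @param abundance Wide strain-level abundance tibble.
#' @param proteins Module protein ids (default: all rows). Requires >= 2
#'   proteins and >= 3 complete-case strains.
#' @return Object of class `module_pca`: `scores` (tibble, strain x PC),
#'   `loadings` (tibble, protein x PC), `variance_fractions` (sums to 1).
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 15, n_chromosomes = 2, n_null_proteins = 2,
#'                   n_cis_null = 0, n_tfs = 1, seed = 2)
#' cohort <- simulate_cohort(cfg, simulate_genotypes(cfg))
#' ab <- strain_abundance(cohort$abundance, cohort$samples)
#' pca <- module_pca(ab, cohort$truth$module_members)
#' pca$variance_fractions[1]
module_pca <- function(abundance, proteins = NULL) {
  m <- abundance_matrix(abundance)
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, rownames(m))
    if (length(missing) > 0) {
      abort(sprintf("protein(s) not in abundance table: %s",
                    paste(missing, collapse = ", ")))
    }
    m <- m[proteins, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("module PCA needs at least 2 proteins.")
  x <- t(m)                       # strains x proteins
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) abort("module PCA needs at least 3 complete strains.")
  sds <- apply(x, 2, sd)
  if (any(sds < 1e-12)) {
    abort(sprintf("zero-variance protein(s): %s",
                  paste(colnames(x)[sds < 1e-12], collapse = ", ")))
  }
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  if (mean(pc$rotation[, 1]) < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(strain = rownames(x)),
                              tibble::as_tibble(pc$x)),
    loadings = dplyr::bind_cols(tibble::tibble(protein = colnames(x)),
                                tibble::as_tibble(pc$rotation)),
    variance_fractions = frac
  ), class = "module_pca")
}

#' @export
print.module_pca <- function(x, ...) {
  cat("<module_pca>\n")
  cat(sprintf("  %d proteins x %d strains; PC1 explains %.1f%% of variance\n",
              nrow(x$loadings), nrow(x$scores),
              100 * x$variance_fractions[1]))
  invisible(x)
}

#' @rdname module_pca
#' @param x,object A `module_pca`.
#' @param ... Unused.
#' @method tidy module_pca
#' @export
tidy.module_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"protein", names_to = "component",
                      values_to = "loading")
}

#' @rdname module_pca
#' @method glance module_pca
#' @export
glance.module_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$variance_fractions)),
                 variance_fraction = x$variance_fractions)
}

# Bias-corrected and accelerated interval from a bootstrap sample, the
# point estimate and leave-one-out jackknife values. With zero bias
# (median-unbiased bootstrap) and zero acceleration this reduces exactly
# to the percentile interval.
bca_interval <- function(boot, estimate, jack, level = c(0.025, 0.975)) {
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  accel <- if (den > 0) num / den else 0
  pr <- mean(boot < estimate) + 0.5 * mean(boot == estimate)
  pr <- pmin(pmax(pr, 1 / (2 * length(boot))), 1 - 1 / (2 * length(boot)))
  z0 <- qnorm(pr)
  zl <- qnorm(level)
  adj <- pnorm(z0 + (z0 + zl) / (1 - accel * (z0 + zl)))
  unname(quantile(boot, adj))
}

# closed-form path fits shared by the estimate, bootstrap and jackknife
fit_paths <- function(x, m, y) {
  n <- length(x)
  mx <- mean(x); mm <- mean(m); my <- mean(y)
  xc <- x - mx; mc <- m - mm; yc <- y - my
  sxx <- sum(xc^2)
  a <- sum(xc * mc) / sxx
  c_tot <- sum(xc * yc) / sxx
  # y ~ x + m via 2x2 normal equations
  smm <- sum(mc^2)
  sxm <- sum(xc * mc)
  sxy <- sum(xc * yc)
  smy <- sum(mc * yc)
  det <- sxx * smm - sxm^2
  if (abs(det) < 1e-12) return(c(a = a, b = NA, c_prime = NA, c = c_tot))
  c_prime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  c(a = a, b = b, c_prime = c_prime, c = c_tot)
}

#' Mediation of a SNP effect through a module principal component
#'
#' Baron-Kenny decomposition with X the genotype code at a haplotype SNP,
#' M the mediator (PC1 of the module), and Y the strain-mean resilience
#' trait: three least-squares fits give `a` (X to M), `b` and `c_prime`
#' (M and X in the joint model for Y), and `c` (total). On complete-case
#' data the identity `c = c_prime + a * b` holds exactly. The indirect
#' effect `a * b` gets a bias-corrected and accelerated (BCa) confidence
#' interval from a stratified case-resampling bootstrap (strains resampled
#' within genotype group, so X stays polymorphic in every replicate;
#' acceleration from a leave-one-strain-out jackknife) and a two-sided
#' bootstrap sign p-value floored at `1/(n_boot + 1)`.
#'
#' Raw correlated module proteins are not accepted as mediators -- that
#' collinearity is what the PCA step resolves; pass one principal
#' component.
#'
#' @param data Tibble with one row per strain.
#' @param x,m,y Column names (character) of the genotype code, mediator
#'   and outcome.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Interval coverage (default 0.95).
#' @return Object of class `mediation_result`.
#' @export
#' @examples
#' d <- tibble::tibble(x = rep(0:1, each = 10),
#'                     m = 2 * x + rnorm(20, sd = .1))
#' d$y <- d$m + rnorm(20, sd = .1)
#' fit <- mediate(d, "x", "m", "y", n_boot = 199, seed = 1)
#' tidy(fit)
mediate <- function(data, x, m, y, n_boot = 1000, seed = 1,
                    conf_level = 0.95) {
  d <- tibble::tibble(x = data[[x]], m = data[[m]], y = data[[y]])
  n_in <- nrow(d)
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n < 6) abort("mediation needs at least 6 complete strains.")
  if (length(unique(d$x)) < 2) {
    abort("X is monomorphic after complete-case filtering.")
  }
  est <- fit_paths(d$x, d$m, d$y)
  indirect <- est[["a"]] * est[["b"]]

  set.seed(substream_seed(seed, "mediate"))
  strata <- split(seq_len(n), d$x)
  boot_ind <- vapply(seq_len(n_boot), function(i) {
    idx <- unlist(lapply(strata, function(s) sample(s, length(s), replace = TRUE)),
                  use.names = FALSE)
    e <- fit_paths(d$x[idx], d$m[idx], d$y[idx])
    e[["a"]] * e[["b"]]
  }, numeric(1))
  boot_ind <- boot_ind[is.finite(boot_ind)]

  level <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  degenerate <- length(unique(round(boot_ind, 12))) < 2
  if (degenerate) {
    warn("degenerate bootstrap distribution; percentile interval reported.")
    ci <- unname(quantile(boot_ind, level))
    method <- "percentile"
  } else {
    jack <- vapply(seq_len(n), function(i) {
      e <- fit_paths(d$x[-i], d$m[-i], d$y[-i])
      e[["a"]] * e[["b"]]
    }, numeric(1))
    ci <- bca_interval(boot_ind, indirect, jack, level)
    method <- "bca"
  }
  p_boot <- max(2 * min(mean(boot_ind <= 0), mean(boot_ind >= 0)),
                1 / (length(boot_ind) + 1))
  p_boot <- min(p_boot, 1)

  structure(list(
    paths = tibble::tibble(
      term = c("a", "b", "c_prime", "c", "indirect"),
      estimate = c(est[["a"]], est[["b"]], est[["c_prime"]], est[["c"]],
                   indirect)
    ),
    indirect = indirect,
    ci = tibble::tibble(lower = ci[1], upper = ci[2], level = conf_level,
                        method = method),
    p_indirect = p_boot,
    n = n, n_dropped = n_in - n,
    n_boot = length(boot_ind), seed = seed,
    bootstrap = boot_ind
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  est <- setNames(x$paths$estimate, x$paths$term)
  cat("<mediation_result>\n")
  cat(sprintf("  a = %.3f, b = %.3f, direct c' = %.3f, total c = %.3f\n",
              est["a"], est["b"], est["c_prime"], est["c"]))
  cat(sprintf("  indirect a*b = %.3f, %s %d%% CI [%.3f, %.3f], p %s\n",
              est["indirect"], toupper(x$ci$method), round(100 * x$ci$level),
              x$ci$lower, x$ci$upper, format.pval(x$p_indirect, digits = 3)))
  cat(sprintf("  %d strains (%d dropped), %d bootstrap replicates, seed %d\n",
              x$n, x$n_dropped, x$n_boot, as.integer(x$seed)))
  invisible(x)
}

#' @rdname mediate
#' @param x,object A `mediation_result`.
#' @param ... Unused.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  out <- x$paths
  out$conf.low <- ifelse(out$term == "indirect", x$ci$lower, NA)
  out$conf.high <- ifelse(out$term == "indirect", x$ci$upper, NA)
  out$p.value <- ifelse(out$term == "indirect", x$p_indirect, NA)
  out
}

#' @rdname mediate
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(indirect = x$indirect, p.value = x$p_indirect,
                 conf.low = x$ci$lower, conf.high = x$ci$upper,
                 ci_method = x$ci$method, n = x$n, n_boot = x$n_boot,
                 seed = x$seed)
}
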