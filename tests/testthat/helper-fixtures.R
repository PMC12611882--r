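# Shared fixtures built in code. Small configurations keep the default test
# run fast; the acceptance tests use study-sized panels.

small_cfg <- function(seed = 1, ...) {
  args <- list(n_strains = 12, n_chromosomes = 3, n_markers_per_chrom = 12,
               n_null_proteins = 6, n_cis_null = 2, n_tfs = 3, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

small_cohort <- function(seed = 1, ...) {
  cfg <- small_cfg(seed = seed, ...)
  g <- simulate_genotypes(cfg)
  co <- simulate_cohort(cfg, g)
  co$genotypes <- g
  co$cfg <- cfg
  co
}

# three-strain worked example used throughout the resilience tests:
# Ntg means (30, 40, 50); AD animals A:(20,24), B:(30), C:(40,44,48)
toy_phenotypes <- function() {
  tibble::tibble(
    animal = sprintf("a%02d", 1:12),
    strain = c("A", "A", "B", "C", "C", "C", "A", "A", "B", "B", "C", "C"),
    group = rep(c("AD", "Ntg"), c(6, 6)),
    sex = "F", age = 6,
    cfm = c(20, 24, 30, 40, 44, 48, 28, 32, 38, 42, 48, 52),
    cfa = 50
  )
}

# tiny wide abundance table from a matrix
ab_tbl <- function(m) {
  rownames(m) <- rownames(m) %||% paste0("f", seq_len(nrow(m)))
  matrix_abundance(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
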