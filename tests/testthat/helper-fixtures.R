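# Small in-code fixtures shared across tests.

# A geno_table built directly from a genotype matrix (sites x samples).
toy_gt <- function(geno, depth = NULL, chrom = NULL, bp = NULL,
                   samples = NULL) {
  geno <- as.matrix(geno)
  n_sites <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("chr1", n_sites)
  if (is.null(bp)) bp <- seq_len(n_sites) * 1000L
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(geno)))
  colnames(geno) <- samples
  geno_table(
    markers = tibble::tibble(
      chrom = chrom, bp = bp,
      marker_id = paste0(chrom, "_", bp), ref = "A", alt = "T"
    ),
    geno = geno, depth = depth, samples = samples
  )
}

# A pedigree of sexed F2 individuals only.
toy_f2_ped <- function(samples, sexes, family = "A") {
  tibble::tibble(
    sample_id = samples, generation = "F2",
    family = rep_len(family, length(samples)),
    sex = sexes, species = NA_character_
  )
}

# Default small cross used by several suites: 5 chromosomes, study-like
# per-chromosome marker density scaled down, two families.
small_cross <- function(sd_system = "XY", seed = 1, n_f2 = 150,
                        n_markers = 1000, n_chromosomes = 5, ...) {
  cross_config(
    n_chromosomes = n_chromosomes, n_markers = n_markers, n_f2 = n_f2,
    sd_system = sd_system, sd_chromosome = 2, seed = seed, ...
  )
}

# Independent brute-force one-way ANOVA via lm/anova for the oracle tests.
anova_oracle <- function(g, y) {
  ok <- !is.na(g)
  fit <- stats::anova(stats::lm(y[ok] ~ factor(g[ok])))
  list(f = fit$`F value`[1], df = fit$Df[1], p = fit$`Pr(>F)`[1])
}
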