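#' Filter thresholds for RAD-seq style genotype data
#'
#' Defaults follow the standard cascade for reduced-representation cross
#' data: sites with > 50% missing data are excluded; individuals with mean
#' depth < 12 or > 50% missing data are excluded; site mean depths beyond
#' the overall mean + 1.5 x IQR of site means are excluded (putative
#' repeats); genotypes with depth < 10 are set missing; minor allele
#' frequency must be at least 0.05. The Hardy-Weinberg filter (P > 0.1,
#' within F2s only) and the excess-heterozygosity paralog filter (> 75% F2
#' heterozygotes removed) serve the marker-regression and allele-frequency
#' paths. Boundary semantics are as printed: strict `>` for missingness,
#' strict `<` for depth, inclusive for MAF.
#'
#' @param site_max_missing,ind_min_mean_depth,ind_max_missing,depth_iqr_mult
#'   Site/individual thresholds.
#' @param gt_min_depth Per-genotype minimum depth.
#' @param maf_min Minimum minor allele frequency (inclusive).
#' @param hwe_p_min Hardy-Weinberg exact P must exceed this (strict).
#' @param het_excess_max Maximum F2 heterozygote proportion (paralog filter).
#' @param f1_het_af_band Sex-averaged allele-frequency band taken to indicate
#'   double-heterozygous F1 parents.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(site_max_missing = 0.5,
                          ind_min_mean_depth = 12,
                          ind_max_missing = 0.5,
                          depth_iqr_mult = 1.5,
                          gt_min_depth = 10,
                          maf_min = 0.05,
                          hwe_p_min = 0.1,
                          het_excess_max = 0.75,
                          f1_het_af_band = c(0.45, 0.55)) {
  stopifnot(
    site_max_missing >= 0, site_max_missing <= 1,
    ind_max_missing >= 0, ind_max_missing <= 1,
    maf_min >= 0, maf_min <= 0.5,
    hwe_p_min >= 0, hwe_p_min <= 1,
    het_excess_max >= 0, het_excess_max <= 1,
    length(f1_het_af_band) == 2, f1_het_af_band[1] <= f1_het_af_band[2]
  )
  structure(
    list(
      site_max_missing = site_max_missing,
      ind_min_mean_depth = ind_min_mean_depth,
      ind_max_missing = ind_max_missing,
      depth_iqr_mult = depth_iqr_mult,
      gt_min_depth = gt_min_depth,
      maf_min = maf_min, hwe_p_min = hwe_p_min,
      het_excess_max = het_excess_max,
      f1_het_af_band = f1_het_af_band
    ),
    class = "filter_config"
  )
}

#' Set low-depth genotypes to missing
#'
#' @param gt A [geno_table()] with depth.
#' @param min_depth Genotypes with depth strictly below this become missing.
#' @return A `geno_table`.
#' @export
mask_low_depth <- function(gt, min_depth = 10) {
  stopifnot(inherits(gt, "geno_table"))
  if (is.null(gt$depth)) stop("genotype table has no depth")
  gt$geno[gt$depth < min_depth] <- NA_integer_
  gt
}

#' Site and individual missingness/depth cascade
#'
#' Applies, in order: site missingness (> `site_max_missing` removed),
#' individual mean depth (< `ind_min_mean_depth` removed) and individual
#' missingness (> `ind_max_missing` removed), then site missingness again,
#' then the minor-allele-frequency filter. The genotype-level depth mask and
#' the depth-IQR site filter are separate steps ([mask_low_depth()],
#' [depth_iqr_site_filter()]) so the full cascade is composable.
#'
#' @param gt A [geno_table()].
#' @param cfg A [filter_config()].
#' @return A filtered `geno_table`.
#' @export
filter_sites_individuals <- function(gt, cfg = filter_config()) {
  stopifnot(inherits(gt, "geno_table"))
  site_miss <- rowMeans(is.na(gt$geno))
  gt <- gt_subset(gt, sites = site_miss <= cfg$site_max_missing)
  if (nrow(gt$geno) == 0) stop("all sites removed by missingness filter")
  keep_ind <- rep(TRUE, length(gt$samples))
  if (!is.null(gt$depth)) {
    keep_ind <- keep_ind & colMeans(gt$depth, na.rm = TRUE) >= cfg$ind_min_mean_depth
  }
  keep_ind <- keep_ind & colMeans(is.na(gt$geno)) <= cfg$ind_max_missing
  if (!any(keep_ind)) stop("all individuals removed by depth/missingness filter")
  gt <- gt_subset(gt, samples = keep_ind)
  site_miss <- rowMeans(is.na(gt$geno))
  gt <- gt_subset(gt, sites = site_miss <= cfg$site_max_missing)
  gt <- maf_filter(gt, cfg$maf_min)
  if (nrow(gt$geno) == 0) stop("all sites removed by filter cascade")
  gt
}

#' Remove sites with outlying mean depth
#'
#' Keeps sites whose mean depth is below the overall mean of site means plus
#' `mult` times the interquartile range of site means — an upper-tail guard
#' against collapsed repeats. With fewer than 4 sites the IQR is not
#' meaningful and the table passes through with a warning.
#'
#' @param gt A [geno_table()] with depth.
#' @param mult IQR multiplier.
#' @return A filtered `geno_table`.
#' @export
depth_iqr_site_filter <- function(gt, mult = 1.5) {
  stopifnot(inherits(gt, "geno_table"))
  if (is.null(gt$depth)) stop("genotype table has no depth")
  if (nrow(gt$geno) < 4) {
    warning("fewer than 4 sites; depth-IQR filter skipped")
    return(gt)
  }
  site_mean <- rowMeans(gt$depth, na.rm = TRUE)
  bound <- mean(site_mean) + mult * stats::IQR(site_mean)
  if (!is.finite(bound)) {
    return(gt)
  }
  gt_subset(gt, sites = site_mean <= bound)
}

site_allele_freq <- function(geno) {
  # alt-allele frequency per site from non-missing genotype codes
  alt <- rowSums(geno, na.rm = TRUE)
  n2 <- 2 * rowSums(!is.na(geno))
  ifelse(n2 > 0, alt / n2, NA_real_)
}

#' Minor allele frequency filter
#'
#' @param gt A [geno_table()].
#' @param maf_min Sites with MAF below this (strict) are removed.
#' @return A filtered `geno_table`.
#' @export
maf_filter <- function(gt, maf_min = 0.05) {
  stopifnot(inherits(gt, "geno_table"))
  af <- site_allele_freq(gt$geno)
  maf <- pmin(af, 1 - af)
  gt_subset(gt, sites = !is.na(maf) & maf >= maf_min)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test conditional on the observed allele counts: the P
#' value is the total probability of heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @return P value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) {
    return(1)
  }
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  het_values <- seq(rare %% 2, rare, by = 2)
  # log-probability of each heterozygote count conditional on allele counts
  logp <- vapply(het_values, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lfactorial(n) -
      (lfactorial(h) + lfactorial(hom_r) + lfactorial(hom_c)) +
      lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, het_values)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Hardy-Weinberg equilibrium site filter
#'
#' Retains sites whose exact HWE P value, computed within the F2 offspring
#' only, exceeds `p_min` (strict), removing markers with distorted genotype
#' proportions before marker regression.
#'
#' @param gt A [geno_table()].
#' @param ped Pedigree tibble.
#' @param p_min Threshold.
#' @return A filtered `geno_table`.
#' @export
hwe_filter <- function(gt, ped, p_min = 0.1) {
  stopifnot(inherits(gt, "geno_table"))
  f2 <- ped$sample_id[ped$generation == "F2"]
  g <- gt$geno[, gt$samples %in% f2, drop = FALSE]
  pvals <- vapply(seq_len(nrow(g)), function(i) {
    row <- g[i, ]
    hwe_exact_test(
      sum(row == 0L, na.rm = TRUE),
      sum(row == 1L, na.rm = TRUE),
      sum(row == 2L, na.rm = TRUE)
    )
  }, numeric(1))
  gt_subset(gt, sites = pvals > p_min)
}

#' Diagnostic sites fixed between the grandparental species
#'
#' Returns indices of sites where the two F0 are opposite homozygotes
#' (homozygous-alternative), optionally requiring every F1 to be
#' heterozygous with no missing data among F0/F1. In surrogate mode (no
#' F0/F1 sequenced) all surrogates of one species must share one homozygote
#' and all surrogates of the other species the other.
#'
#' @param gt A [geno_table()].
#' @param ped Pedigree tibble.
#' @param require_f1_het Require all F1 heterozygous (pedigree mode).
#' @param mode `"pedigree"` or `"species_surrogate"`.
#' @return Integer vector of site indices.
#' @export
select_f0_diagnostic_sites <- function(gt, ped, require_f1_het = TRUE,
                                       mode = c("pedigree", "species_surrogate")) {
  stopifnot(inherits(gt, "geno_table"))
  mode <- match.arg(mode)
  opposite_hom <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    ok & ((a == 0L & b == 2L) | (a == 2L & b == 0L))
  }
  if (mode == "pedigree") {
    f0 <- ped$sample_id[ped$generation == "F0"]
    if (length(f0) < 2) stop("pedigree has no two F0 individuals")
    f0 <- intersect(f0, gt$samples)
    if (length(f0) < 2) stop("F0 individuals absent from genotype table")
    a <- gt$geno[, f0[1]]
    b <- gt$geno[, f0[2]]
    sel <- opposite_hom(a, b)
    if (require_f1_het) {
      f1 <- intersect(ped$sample_id[ped$generation == "F1"], gt$samples)
      if (length(f1) > 0) {
        g1 <- gt$geno[, f1, drop = FALSE]
        sel <- sel & rowSums(is.na(g1)) == 0 & rowSums(g1 == 1L) == length(f1)
      }
    }
  } else {
    sur <- ped[ped$generation == "species_surrogate", , drop = FALSE]
    if (nrow(sur) == 0) stop("pedigree has no species surrogates")
    spp <- sort(unique(sur$species))
    if (length(spp) != 2) stop("surrogate mode needs exactly two species")
    ga <- gt$geno[, intersect(sur$sample_id[sur$species == spp[1]], gt$samples), drop = FALSE]
    gb <- gt$geno[, intersect(sur$sample_id[sur$species == spp[2]], gt$samples), drop = FALSE]
    all_same_hom <- function(g, code) {
      rowSums(is.na(g)) == 0 & rowSums(g == code) == ncol(g)
    }
    sel <- (all_same_hom(ga, 0L) & all_same_hom(gb, 2L)) |
      (all_same_hom(ga, 2L) & all_same_hom(gb, 0L))
  }
  unname(which(sel))
}

#' Infer double-heterozygous-F1 sites from F2 allele frequencies
#'
#' When F1 genotypes are unavailable, sites where both F1 parents were
#' heterozygous are recognisable by an alternative-allele frequency near 0.5
#' in the F2. The frequency is computed separately among F2 males and among
#' F2 females and the two are averaged, so a sex-linked site (e.g. 0.3 in
#' one sex, 0.7 in the other) still qualifies. Sites with F2 heterozygote
#' proportion above `het_excess_max` are then removed as likely collapsed
#' paralogs.
#'
#' @param gt A [geno_table()].
#' @param ped Pedigree tibble with sexed F2.
#' @param band Two-element frequency band (inclusive).
#' @param het_excess_max Paralog filter threshold (strict `>` removed).
#' @return Integer vector of site indices.
#' @export
infer_f1_het_sites_by_af <- function(gt, ped, band = c(0.45, 0.55),
                                     het_excess_max = 0.75) {
  stopifnot(inherits(gt, "geno_table"))
  sx <- f2_by_sex(ped)
  if (length(sx$males) == 0 || length(sx$females) == 0) {
    stop("need F2 individuals of both sexes")
  }
  g_m <- gt$geno[, gt$samples %in% sx$males, drop = FALSE]
  g_f <- gt$geno[, gt$samples %in% sx$females, drop = FALSE]
  af <- (site_allele_freq(g_m) + site_allele_freq(g_f)) / 2
  g_all <- gt$geno[, gt$samples %in% c(sx$males, sx$females), drop = FALSE]
  het <- rowSums(g_all == 1L, na.rm = TRUE) / rowSums(!is.na(g_all))
  unname(which(!is.na(af) & af >= band[1] & af <= band[2] &
    !is.na(het) & het <= het_excess_max))
}

#' Allelic-balance correction of founder heterozygotes
#'
#' Heterozygous F0 calls supported by a strongly skewed read balance are
#' recoded to the majority homozygote. Read counts per allele are not
#' retained in a genotype matrix, so the skew is supplied directly as a
#' minor-read fraction matrix (sites x F0 samples); calls with minor-read
#' fraction below `min_fraction` are recoded. This is an approximation of
#' read-level allelic-balance correction and is documented as such.
#'
#' @param gt A [geno_table()].
#' @param ped Pedigree tibble.
#' @param minor_fraction Matrix of minor-allele read fractions for the F0
#'   columns (sites x n_F0), or `NULL` to skip.
#' @param major_allele Matrix of the majority read allele as a genotype code
#'   (0 = REF, 2 = ALT), same shape as `minor_fraction`; defaults to REF.
#' @param min_fraction Threshold below which a het call is recoded.
#' @return A `geno_table`.
#' @export
correct_f0_allelic_balance <- function(gt, ped, minor_fraction = NULL,
                                       major_allele = NULL,
                                       min_fraction = 0.2) {
  stopifnot(inherits(gt, "geno_table"))
  if (is.null(minor_fraction)) {
    return(gt)
  }
  f0 <- intersect(ped$sample_id[ped$generation == "F0"], gt$samples)
  minor_fraction <- as.matrix(minor_fraction)
  stopifnot(nrow(minor_fraction) == nrow(gt$geno), ncol(minor_fraction) == length(f0))
  if (is.null(major_allele)) {
    major_allele <- matrix(0L, nrow(minor_fraction), ncol(minor_fraction))
  }
  for (j in seq_along(f0)) {
    col <- match(f0[j], gt$samples)
    skew <- !is.na(gt$geno[, col]) & gt$geno[, col] == 1L &
      !is.na(minor_fraction[, j]) & minor_fraction[, j] < min_fraction
    gt$geno[skew, col] <- as.integer(major_allele[skew, j])
  }
  gt
}
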