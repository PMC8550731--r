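#' Sex-contrasted per-site genotype statistics
#'
#' For each selected site, computes among non-missing F2 genotypes of each
#' sex: the frequency of the grandpaternal homozygous genotype (code 2), the
#' heterozygote proportion, and their male-minus-female difference. At sites
#' where both F1 parents are heterozygous, an autosomal locus shows the
#' grandpaternal homozygote at ~25% in both sexes, while a fully sex-linked
#' locus shows ~50% in the heterogametic-determined sex and ~0% in the
#' other.
#'
#' @param gt A [geno_table()] with grandmother-polarized codes.
#' @param ped Pedigree tibble with sexed F2.
#' @param sites Integer site indices (e.g. from
#'   [select_f0_diagnostic_sites()] or [infer_f1_het_sites_by_af()]);
#'   `NULL` uses all sites.
#' @param family Restrict to one family label, or `NULL` for all.
#' @return A tibble with one row per site: `site`, `chrom`, `bp`,
#'   `marker_id`, `freq_gp_m`, `freq_gp_f`, `h_m`, `h_f`, `het_diff`,
#'   `n_m`, `n_f`. Frequencies are `NA` where a sex has no non-missing
#'   genotypes.
#' @export
sex_site_stats <- function(gt, ped, sites = NULL, family = NULL) {
  stopifnot(inherits(gt, "geno_table"))
  if (is.null(sites)) sites <- seq_len(nrow(gt$geno))
  sx <- f2_by_sex(ped, family)
  if (length(sx$males) == 0 || length(sx$females) == 0) {
    stop("need sexed F2 individuals of both sexes")
  }
  g_m <- gt$geno[sites, gt$samples %in% sx$males, drop = FALSE]
  g_f <- gt$geno[sites, gt$samples %in% sx$females, drop = FALSE]
  dimnames(g_m) <- NULL
  dimnames(g_f) <- NULL
  n_m <- rowSums(!is.na(g_m))
  n_f <- rowSums(!is.na(g_f))
  frac <- function(g, code, n) {
    out <- rowSums(g == code, na.rm = TRUE) / n
    out[n == 0] <- NA_real_
    out
  }
  tibble::tibble(
    site = sites,
    chrom = gt$markers$chrom[sites],
    bp = gt$markers$bp[sites],
    marker_id = gt$markers$marker_id[sites],
    freq_gp_m = frac(g_m, 2L, n_m),
    freq_gp_f = frac(g_f, 2L, n_f),
    h_m = frac(g_m, 1L, n_m),
    h_f = frac(g_f, 1L, n_f),
    het_diff = frac(g_m, 1L, n_m) - frac(g_f, 1L, n_f),
    n_m = n_m, n_f = n_f
  )
}

#' Permutation test of sex differences in heterozygote frequency
#'
#' Permutes the sex assignments of the F2 individuals `n_perm` times (one
#' shuffled label vector per replicate, shared across all sites) and
#' recomputes the male-minus-female heterozygote-frequency difference at
#' every site. The observed sign defines the one-sided tail per site;
#' permuted values equal to the observed count as extreme. A site is flagged
#' significant when at most `max_extreme` of the `n_perm` permutations are as
#' or more extreme (with the default 10,000 permutations this is an
#' empirical one-sided P below 1e-4); the reported `p_emp` uses the add-one
#' correction `(1 + extreme) / (1 + n_perm)` so downstream ranking never
#' sees a zero.
#'
#' @param gt A [geno_table()].
#' @param ped Pedigree tibble with sexed F2.
#' @param sites Site indices; `NULL` for all.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param max_extreme Flag rule: significant when `extreme <= max_extreme`.
#' @param family Restrict to one family, or `NULL`.
#' @param block_size Permutations per matrix-multiplication block (memory
#'   control).
#' @return The [sex_site_stats()] tibble with `n_extreme`, `p_emp` and
#'   `significant` columns appended.
#' @export
permutation_test <- function(gt, ped, sites = NULL, n_perm = 10000,
                             seed = 1L, max_extreme = 1L, family = NULL,
                             block_size = 2000L) {
  stopifnot(inherits(gt, "geno_table"))
  if (is.null(sites)) sites <- seq_len(nrow(gt$geno))
  sx <- f2_by_sex(ped, family)
  if (length(sx$males) < 2 || length(sx$females) < 2) {
    stop("need at least two F2 individuals of each sex")
  }
  stats <- sex_site_stats(gt, ped, sites, family)
  ids <- c(sx$males, sx$females)
  g <- gt$geno[sites, match(ids, gt$samples), drop = FALSE]
  n_ind <- length(ids)
  n_m <- length(sx$males)
  het <- (g == 1L)
  het[is.na(het)] <- FALSE
  het <- matrix(as.numeric(het), nrow = nrow(g))
  obs <- matrix(as.numeric(!is.na(g)), nrow = nrow(g))
  observed <- stats$het_diff

  set.seed(seed)
  n_extreme <- integer(length(sites))
  done <- 0L
  while (done < n_perm) {
    nb <- min(block_size, n_perm - done)
    # column b of S indicates the permuted "male" labels of replicate b
    S <- vapply(
      seq_len(nb),
      function(b) {
        v <- numeric(n_ind)
        v[sample.int(n_ind, n_m)] <- 1
        v
      },
      numeric(n_ind)
    )
    het_m <- het %*% S
    n_m_mat <- obs %*% S
    het_f <- het %*% (1 - S)
    n_f_mat <- obs %*% (1 - S)
    diff <- het_m / n_m_mat - het_f / n_f_mat
    sgn <- sign(observed)
    cmp <- sweep(diff, 1, sgn, `*`) >= abs(observed) - 1e-12
    cmp[is.na(cmp)] <- FALSE
    n_extreme <- n_extreme + rowSums(cmp)
    done <- done + nb
  }
  # het_diff == 0 has no direction: every permutation is as extreme
  n_extreme[!is.na(observed) & observed == 0] <- n_perm
  n_extreme[is.na(observed)] <- NA_integer_
  stats$n_extreme <- n_extreme
  stats$p_emp <- (1 + n_extreme) / (1 + n_perm)
  stats$significant <- !is.na(n_extreme) & n_extreme <= max_extreme
  stats
}

#' Call the heterogametic system per chromosome
#'
#' A chromosome is called XY when it carries at least `min_sites` significant
#' sites of which at least `min_share` have a positive heterozygote
#' difference (males more heterozygous), ZW for the negative direction, and
#' `none` otherwise.
#'
#' @param stats Output of [permutation_test()].
#' @param min_sites Minimum number of significant sites.
#' @param min_share Minimum fraction sharing one sign.
#' @return A tibble with one row per chromosome: `chrom`, `n_significant`,
#'   `n_positive`, `n_negative`, `direction` (`"XY"`, `"ZW"` or `"none"`).
#' @export
call_heterogamety <- function(stats, min_sites = 3L, min_share = 0.8) {
  stats |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n_significant = sum(.data$significant, na.rm = TRUE),
      n_positive = sum(.data$significant & .data$het_diff > 0, na.rm = TRUE),
      n_negative = sum(.data$significant & .data$het_diff < 0, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$n_significant >= min_sites &
          .data$n_positive / .data$n_significant >= min_share ~ "XY",
        .data$n_significant >= min_sites &
          .data$n_negative / .data$n_significant >= min_share ~ "ZW",
        TRUE ~ "none"
      )
    )
}

#' Female/male sequencing-depth ratio in windows
#'
#' Computes per-site mean depth separately for F2 females and males,
#' averages the site values within half-open windows anchored at bp 0, and
#' reports the female/male ratio. Ratios near 1 everywhere indicate that
#' both sex chromosomes still map to the reference (no degeneration);
#' an elevated ratio marks male-depleted (Y-deleted) spans.
#'
#' @param gt A [geno_table()] with depth.
#' @param ped Pedigree tibble with sexed F2.
#' @param window_bp Window size in bp.
#' @return A tibble: `chrom`, `start`, `end`, `n_sites`, `depth_f`,
#'   `depth_m`, `ratio_fm`. Windows without sites are reported with `NA`.
#' @export
depth_ratio_windows <- function(gt, ped, window_bp = 5e6) {
  stopifnot(inherits(gt, "geno_table"))
  if (is.null(gt$depth)) stop("genotype table has no depth")
  sx <- f2_by_sex(ped)
  d_m <- rowMeans(gt$depth[, gt$samples %in% sx$males, drop = FALSE], na.rm = TRUE)
  d_f <- rowMeans(gt$depth[, gt$samples %in% sx$females, drop = FALSE], na.rm = TRUE)
  site_tbl <- tibble::tibble(
    chrom = gt$markers$chrom, bp = gt$markers$bp, d_m = d_m, d_f = d_f,
    win = (gt$markers$bp %/% window_bp)
  )
  grid <- site_tbl |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(win = seq(0, max(.data$win))) # tile through last used window
  site_tbl |>
    dplyr::group_by(.data$chrom, .data$win) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      depth_f = mean(.data$d_f), depth_m = mean(.data$d_m),
      .groups = "drop"
    ) |>
    dplyr::right_join(grid, by = c("chrom", "win")) |>
    dplyr::mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      start = .data$win * window_bp,
      end = (.data$win + 1) * window_bp,
      ratio_fm = .data$depth_f / .data$depth_m
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select(
      "chrom", "start", "end", "n_sites", "depth_f", "depth_m", "ratio_fm"
    )
}
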