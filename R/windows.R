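#' Site filters for divergence and heterozygosity estimation
#'
#' Applies, in order: removal of sites with more than 25% missing data,
#' masking of genotypes with depth below `min_depth` reads, and removal of
#' SNPs whose minor allele is carried by only one or two allele copies
#' across the retained individuals (likely sequencing errors).
#'
#' @param gt A [geno_table()].
#' @param max_missing Maximum site missingness (strict `>` removed).
#' @param min_depth Per-genotype depth threshold (strict `<` masked); only
#'   applied when depth is available.
#' @param min_copies Minimum minor-allele copy count (sites with fewer than
#'   or exactly `min_copies` copies removed when `min_copies = 2`, i.e.
#'   singletons and doubletons).
#' @return A filtered `geno_table`.
#' @export
divergence_site_filter <- function(gt, max_missing = 0.25, min_depth = 10,
                                   min_copies = 2L) {
  stopifnot(inherits(gt, "geno_table"))
  gt <- gt_subset(gt, sites = rowMeans(is.na(gt$geno)) <= max_missing)
  if (!is.null(gt$depth)) gt <- mask_low_depth(gt, min_depth)
  alt <- rowSums(gt$geno, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(gt$geno))
  minor <- pmin(alt, tot - alt)
  # keep monomorphic sites (minor == 0) and sites beyond the error band
  gt_subset(gt, sites = minor == 0 | minor > min_copies)
}

window_index <- function(bp, window_bp) bp %/% window_bp

#' Windowed per-individual heterozygosity
#'
#' For one individual, the proportion of heterozygous genotypes among
#' callable positions in half-open windows anchored at bp 0. With SNP-only
#' input the denominator defaults to the individual's non-missing genotyped
#' sites per window; when `callable_bp` (total sequenced positions per
#' window, e.g. from a BED of callable sites) is supplied, proportions are
#' per sequenced position, matching the usual definition of individual
#' heterozygosity over monomorphic and polymorphic sites.
#'
#' @param gt A [geno_table()].
#' @param individual Sample id.
#' @param window_bp Window size.
#' @param callable_bp Optional tibble `chrom`, `start`, `n_callable` giving
#'   the denominator per window.
#' @return A tibble: `chrom`, `start`, `end`, `n_sites`, `n_het`,
#'   `heterozygosity`.
#' @export
individual_heterozygosity_windows <- function(gt, individual,
                                              window_bp = 1e6,
                                              callable_bp = NULL) {
  stopifnot(inherits(gt, "geno_table"))
  if (!individual %in% gt$samples) stop("unknown sample: ", individual)
  g <- gt$geno[, individual]
  tb <- tibble::tibble(
    chrom = gt$markers$chrom,
    start = window_index(gt$markers$bp, window_bp) * window_bp,
    het = !is.na(g) & g == 1L,
    obs = !is.na(g)
  ) |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(
      n_sites = sum(.data$obs), n_het = sum(.data$het),
      .groups = "drop"
    ) |>
    dplyr::mutate(end = .data$start + window_bp)
  if (!is.null(callable_bp)) {
    tb <- tb |>
      dplyr::left_join(callable_bp, by = c("chrom", "start")) |>
      dplyr::mutate(
        heterozygosity = ifelse(.data$n_callable > 0,
          .data$n_het / .data$n_callable, NA_real_
        )
      ) |>
      dplyr::select(-"n_callable")
  } else {
    tb <- dplyr::mutate(tb,
      heterozygosity = ifelse(.data$n_sites > 0,
        .data$n_het / .data$n_sites, NA_real_
      )
    )
  }
  dplyr::select(
    tb, "chrom", "start", "end", "n_sites", "n_het", "heterozygosity"
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Windowed between-group divergence (d_xy)
#'
#' Per site, the mean pairwise allele difference between the two groups in
#' frequency form, \eqn{p_A (1 - p_B) + p_B (1 - p_A)}, averaged over the
#' sites of each half-open window (or divided by `callable_bp` when
#' supplied).
#'
#' @param gt A [geno_table()].
#' @param group_a,group_b Character vectors of sample ids.
#' @param window_bp Window size.
#' @param callable_bp Optional per-window callable-position counts
#'   (`chrom`, `start`, `n_callable`).
#' @return A tibble: `chrom`, `start`, `end`, `n_sites`, `dxy`.
#' @export
dxy_windows <- function(gt, group_a, group_b, window_bp = 1e6,
                        callable_bp = NULL) {
  stopifnot(inherits(gt, "geno_table"))
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  miss <- c(setdiff(group_a, gt$samples), setdiff(group_b, gt$samples))
  if (length(miss) > 0) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  pa <- site_allele_freq(gt$geno[, group_a, drop = FALSE])
  pb <- site_allele_freq(gt$geno[, group_b, drop = FALSE])
  d_site <- pa * (1 - pb) + pb * (1 - pa)
  tb <- tibble::tibble(
    chrom = gt$markers$chrom,
    start = window_index(gt$markers$bp, window_bp) * window_bp,
    d = d_site
  ) |>
    dplyr::filter(!is.na(.data$d)) |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(
      n_sites = dplyr::n(), d_sum = sum(.data$d),
      .groups = "drop"
    ) |>
    dplyr::mutate(end = .data$start + window_bp)
  if (!is.null(callable_bp)) {
    tb <- tb |>
      dplyr::left_join(callable_bp, by = c("chrom", "start")) |>
      dplyr::mutate(dxy = ifelse(.data$n_callable > 0,
        .data$d_sum / .data$n_callable, NA_real_
      )) |>
      dplyr::select(-"n_callable")
  } else {
    tb <- dplyr::mutate(tb, dxy = .data$d_sum / .data$n_sites)
  }
  dplyr::select(tb, "chrom", "start", "end", "n_sites", "dxy") |>
    dplyr::arrange(.data$chrom, .data$start)
}
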