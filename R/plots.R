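#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

chrom_offsets <- function(chrom, bp) {
  d <- tibble::tibble(chrom = chrom, bp = bp) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$bp), .groups = "drop")
  d$offset <- cumsum(dplyr::lag(d$len, default = 0))
  d
}

#' Genome-wide LOD curve
#'
#' @param object A `sexqtl_scan` (from [scan_markers()] or
#'   [interval_scan_binary()]).
#' @param threshold Optional LOD threshold line(s).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sexqtl_scan <- function(object, threshold = NULL, ...) {
  off <- chrom_offsets(object$chrom, object$bp)
  d <- dplyr::left_join(tibble::as_tibble(unclass(object)), off, by = "chrom") |>
    dplyr::mutate(
      x = .data$bp + .data$offset,
      chrom_parity = factor(match(.data$chrom, off$chrom) %% 2)
    )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$lod, colour = .data$chrom_parity)) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey40", "steelblue4")) +
    ggplot2::labs(x = "genome position (bp, chromosomes concatenated)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = threshold,
      linetype = c("dotted", "dashed")[seq_along(threshold)]
    )
  }
  p
}

#' Sex difference in heterozygote frequency along the genome
#'
#' Significant sites (permutation flag) are drawn larger, coloured by
#' direction: blue for male-biased heterozygosity (XY-like), red for
#' female-biased (ZW-like).
#'
#' @param stats Output of [permutation_test()].
#' @return A ggplot.
#' @export
plot_het_diff <- function(stats) {
  off <- chrom_offsets(stats$chrom, stats$bp)
  d <- dplyr::left_join(stats, off, by = "chrom") |>
    dplyr::mutate(
      x = .data$bp + .data$offset,
      class = dplyr::case_when(
        .data$significant & .data$het_diff > 0 ~ "XY-like",
        .data$significant & .data$het_diff < 0 ~ "ZW-like",
        TRUE ~ "ns"
      )
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$het_diff,
    colour = .data$class, size = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c("XY-like" = "royalblue3", "ZW-like" = "red3", ns = "grey60")
    ) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 1.8, `FALSE` = 0.6), guide = "none") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "genome position (bp, chromosomes concatenated)",
      y = "heterozygote proportion, males - females", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Grandpaternal-genotype frequencies by sex
#'
#' @param stats Output of [sex_site_stats()] or [permutation_test()].
#' @return A ggplot with male (blue) and female (red) frequencies of the
#'   grandpaternal homozygous genotype per site.
#' @export
plot_grandpaternal_freq <- function(stats) {
  off <- chrom_offsets(stats$chrom, stats$bp)
  d <- dplyr::left_join(stats, off, by = "chrom") |>
    dplyr::mutate(x = .data$bp + .data$offset) |>
    tidyr::pivot_longer(c("freq_gp_m", "freq_gp_f"),
      names_to = "sex", values_to = "freq"
    ) |>
    dplyr::mutate(sex = ifelse(.data$sex == "freq_gp_m", "males", "females"))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$freq, colour = .data$sex)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(males = "royalblue3", females = "red3")) +
    ggplot2::geom_hline(yintercept = c(0, 0.25, 0.5), linetype = "dotted") +
    ggplot2::labs(
      x = "genome position (bp, chromosomes concatenated)",
      y = "grandpaternal homozygote frequency", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Windowed female/male depth ratio
#'
#' @param windows Output of [depth_ratio_windows()].
#' @return A ggplot.
#' @export
plot_depth_ratio <- function(windows) {
  off <- chrom_offsets(windows$chrom, windows$end)
  d <- dplyr::left_join(windows, off, by = "chrom") |>
    dplyr::mutate(x = (.data$start + .data$end) / 2 + .data$offset)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$ratio_fm)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(
      x = "genome position (bp, chromosomes concatenated)",
      y = "female / male mean depth"
    ) +
    ggplot2::theme_minimal()
}
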