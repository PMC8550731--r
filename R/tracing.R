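#' Select Y- or W-linked sites
#'
#' In pedigree mode, returns sites where every F0 and F1 individual of the
#' putative heterogametic sex is heterozygous and every F0 and F1 of the
#' homogametic sex is homozygous — the
#' signature of a Y- or W-linked variant (missing parental genotypes are
#' tolerated as long as `min_obs` individuals are observed per side and all
#' observed ones match). In surrogate mode the same
#' contrast is applied to species surrogates of the heterogametic-side
#' species (heterozygous in its heterogametic-sex individuals, homozygous in
#' the other species' individuals).
#'
#' @param gt A [geno_table()].
#' @param ped Pedigree tibble.
#' @param heterogametic_sex `"M"` (XY) or `"F"` (ZW).
#' @param mode `"pedigree"` or `"species_surrogate"`.
#' @param chrom Restrict to one chromosome label, or `NULL` for genome-wide.
#' @param min_obs Minimum observed (non-missing) individuals required on
#'   each side of the contrast.
#' @return Integer vector of site indices ordered by position (possibly
#'   empty).
#' @export
select_sex_linked_sites <- function(gt, ped, heterogametic_sex = c("M", "F"),
                                    mode = c("pedigree", "species_surrogate"),
                                    chrom = NULL, min_obs = 2L) {
  stopifnot(inherits(gt, "geno_table"))
  heterogametic_sex <- match.arg(heterogametic_sex)
  mode <- match.arg(mode)
  homogametic_sex <- setdiff(c("M", "F"), heterogametic_sex)
  if (mode == "pedigree") {
    par <- ped[ped$generation %in% c("F0", "F1"), , drop = FALSE]
    het_ids <- intersect(par$sample_id[par$sex == heterogametic_sex], gt$samples)
    hom_ids <- intersect(par$sample_id[par$sex == homogametic_sex], gt$samples)
  } else {
    sur <- ped[ped$generation == "species_surrogate", , drop = FALSE]
    if (nrow(sur) == 0) stop("pedigree has no species surrogates")
    # heterogametic-side species: grandfather's under XY, grandmother's under ZW
    f0 <- ped[ped$generation == "F0", , drop = FALSE]
    het_species <- if (heterogametic_sex == "M") {
      if (nrow(f0) > 0) f0$species[f0$sex == "M"][1] else sort(unique(sur$species))[2]
    } else {
      if (nrow(f0) > 0) f0$species[f0$sex == "F"][1] else sort(unique(sur$species))[1]
    }
    het_ids <- intersect(
      sur$sample_id[sur$species == het_species & sur$sex == heterogametic_sex],
      gt$samples
    )
    hom_ids <- intersect(
      sur$sample_id[sur$species != het_species],
      gt$samples
    )
  }
  if (length(het_ids) == 0 || length(hom_ids) == 0) {
    return(integer(0))
  }
  g_het <- gt$geno[, het_ids, drop = FALSE]
  g_hom <- gt$geno[, hom_ids, drop = FALSE]
  # every observed parent must match the pattern, with at least min_obs
  # observed on each side (missing parental genotypes do not disqualify an
  # otherwise consistent site)
  n_het_obs <- rowSums(!is.na(g_het))
  n_hom_obs <- rowSums(!is.na(g_hom))
  sel <- n_het_obs >= min(min_obs, length(het_ids)) &
    n_hom_obs >= min(min_obs, length(hom_ids)) &
    rowSums(g_het == 1L, na.rm = TRUE) == n_het_obs &
    rowSums(g_hom != 1L, na.rm = TRUE) == n_hom_obs
  if (!is.null(chrom)) sel <- sel & gt$markers$chrom == chrom
  idx <- unname(which(sel))
  idx[order(gt$markers$chrom[idx], gt$markers$bp[idx])]
}

#' Smooth short discordant genotype runs
#'
#' Replaces runs of up to `max_run` equal genotypes that differ from the
#' `flank` genotypes on both sides — which must all equal each other — by
#' the flanking genotype. This removes isolated genotyping artifacts (e.g.
#' allelic dropout) from ordered site vectors before composition calls.
#' The pass is left-to-right over the original vector: replacements do not
#' cascade onto already-replaced values. Missing genotypes break both runs
#' and flanks; runs longer than `max_run` and flanks shorter than `flank`
#' leave the vector unchanged.
#'
#' @param g Integer genotype vector (codes 0/1/2, NA missing) in site order.
#' @param max_run Maximum run length eligible for replacement.
#' @param flank Required number of equal genotypes on each side.
#' @return The smoothed vector.
#' @export
smooth_genotype_runs <- function(g, max_run = 3L, flank = 5L) {
  n <- length(g)
  if (n == 0) {
    return(g)
  }
  out <- g
  rl <- rle(ifelse(is.na(g), -1L, g))
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  for (k in seq_along(rl$lengths)) {
    if (rl$values[k] == -1L || rl$lengths[k] > max_run) next
    left_ok <- k > 1 && rl$values[k - 1] != -1L && rl$lengths[k - 1] >= flank
    right_ok <- k < length(rl$lengths) && rl$values[k + 1] != -1L &&
      rl$lengths[k + 1] >= flank
    if (left_ok && right_ok && rl$values[k - 1] == rl$values[k + 1] &&
      rl$values[k - 1] != rl$values[k]) {
      out[starts[k]:ends[k]] <- rl$values[k - 1]
    }
  }
  out
}

# Decode the two-site genotype combination into allele labels.
# `no_det_code` is the homozygous code carried by the homogametic parents at
# the Y/W-diagnostic site (so `2 - no_det_code` means two determiner-linked
# alleles); it keeps the decode independent of REF/ALT orientation.
decode_composition <- function(g_ydiag, g_origin, heterogametic_sex,
                               no_det_code = 0L) {
  het_letter <- if (heterogametic_sex == "M") "Y" else "W"
  hom_letter <- if (heterogametic_sex == "M") "X" else "Z"
  het_species <- if (heterogametic_sex == "M") "B" else "A" # grandfather / grandmother
  hom_other <- setdiff(c("A", "B"), het_species)
  if (is.na(g_ydiag) && is.na(g_origin)) {
    return(list(a1 = NA_character_, a2 = NA_character_, unresolved = TRUE))
  }
  het_lab <- paste0(het_letter, "_", het_species)
  carries <- if (!is.na(g_ydiag)) {
    if (g_ydiag == 1L) 1L else if (g_ydiag == 2L - no_det_code) 2L else 0L
  } else {
    NA_integer_
  }
  # the origin site (fixed between species, grandmother-polarized):
  # 0 = two grandmaternal copies, 1 = one each, 2 = two grandpaternal
  origin_labs <- if (!is.na(g_origin)) {
    switch(as.character(g_origin),
      "0" = c(paste0(hom_letter, "_A"), paste0(hom_letter, "_A")),
      "1" = c(paste0(hom_letter, "_A"), paste0(hom_letter, "_B")),
      "2" = c(paste0(hom_letter, "_B"), paste0(hom_letter, "_B"))
    )
  } else {
    NULL
  }
  if (is.na(carries)) {
    if (is.null(origin_labs)) {
      return(list(a1 = NA_character_, a2 = NA_character_, unresolved = TRUE))
    }
    return(list(a1 = origin_labs[1], a2 = origin_labs[2], unresolved = FALSE))
  }
  if (carries == 2L) {
    return(list(a1 = het_lab, a2 = het_lab, unresolved = FALSE))
  }
  if (carries == 1L) {
    # the determiner-linked chromosome descends from the heterogametic
    # founder's species, so at the origin site it carries that species'
    # allele; the partner chromosome explains the remainder
    partner <- if (!is.null(origin_labs)) {
      same_species_hom <- if (het_species == "B") 2L else 0L
      if (g_origin == same_species_hom) {
        paste0(hom_letter, "_", het_species)
      } else {
        paste0(hom_letter, "_", hom_other)
      }
    } else {
      paste0(hom_letter, "_", hom_other) # unknowable; default cross-species
    }
    return(list(a1 = partner, a2 = het_lab, unresolved = FALSE))
  }
  if (is.null(origin_labs)) {
    return(list(a1 = NA_character_, a2 = NA_character_, unresolved = TRUE))
  }
  list(a1 = origin_labs[1], a2 = origin_labs[2], unresolved = FALSE)
}

#' Assign each F2 a sex-chromosome composition
#'
#' Combines the genotypes at two maximally sex-linked sites to label each
#' F2's two sex-chromosome copies with their grandparental species of
#' origin (e.g. `X_A Y_B`): a Y/W-diagnostic site (heterozygous in the
#' heterogametic F0 and F1) reveals whether the individual carries the
#' determiner-linked allele, and a species-diagnostic origin site (fixed
#' between the founder species) reveals whether the homogametic copies come
#' from the grandmother (A) or grandfather (B). "Most strongly sex-linked"
#' is ranked by permutation `p_emp`, ties broken by largest absolute
#' heterozygote difference, then position.
#'
#' @param gt A [geno_table()] (grandmother-polarized).
#' @param ped Pedigree tibble.
#' @param ydiag_sites Candidate Y/W-diagnostic site indices (from
#'   [select_sex_linked_sites()]).
#' @param origin_sites Candidate origin site indices (from
#'   [select_f0_diagnostic_sites()] restricted to the sex chromosome).
#' @param heterogametic_sex `"M"` or `"F"`.
#' @param stats Optional [permutation_test()] tibble used for ranking; when
#'   absent, sites are ranked by absolute heterozygote difference from
#'   [sex_site_stats()].
#' @param smooth Apply [smooth_genotype_runs()] along the candidate sites of
#'   each individual before reading off the two chosen sites.
#' @return A tibble of class `sexqtl_composition`, one row per sexed F2:
#'   `sample_id`, `sex`, `allele_1`, `allele_2`, `composition`,
#'   `carries_het_allele`, `predicted_sex`, `discordant`, `unresolved`.
#' @export
assign_composition <- function(gt, ped, ydiag_sites, origin_sites,
                               heterogametic_sex = c("M", "F"),
                               stats = NULL, smooth = TRUE) {
  stopifnot(inherits(gt, "geno_table"))
  heterogametic_sex <- match.arg(heterogametic_sex)
  if (length(ydiag_sites) == 0) stop("no Y/W-diagnostic sites supplied")
  if (length(origin_sites) == 0) stop("no origin sites supplied")
  # Y/W sites: strongest heterozygote-difference signal (permutation p when
  # available). Origin (species-diagnostic) sites carry no heterozygote
  # contrast; their sex linkage shows in the grandpaternal-genotype
  # frequency difference between the sexes, so they are ranked by it.
  ydiag_ranked <- if (length(ydiag_sites) == 1) {
    ydiag_sites
  } else if (!is.null(stats) && all(ydiag_sites %in% stats$site)) {
    s <- stats[match(ydiag_sites, stats$site), ]
    ydiag_sites[order(s$p_emp, -abs(s$het_diff), s$bp)]
  } else {
    s <- sex_site_stats(gt, ped, ydiag_sites)
    ydiag_sites[order(-abs(s$het_diff), s$bp)]
  }
  best_y <- ydiag_ranked[1]
  origin_ranked <- if (length(origin_sites) == 1) {
    origin_sites
  } else {
    so <- sex_site_stats(gt, ped, origin_sites)
    contrast <- abs(so$freq_gp_m - so$freq_gp_f)
    # the frequency contrast plateaus near the determiner, so within one
    # sampling standard error of the maximum, prefer the site closest to the
    # strongest Y/W-linked site
    near_max <- contrast >= max(contrast, na.rm = TRUE) -
      sqrt(0.25 / pmax(pmin(so$n_m, so$n_f), 1))
    near_max[is.na(near_max)] <- FALSE
    dist_to_y <- abs(so$bp - gt$markers$bp[best_y]) +
      ifelse(so$chrom == gt$markers$chrom[best_y], 0, Inf)
    origin_sites[order(!near_max, dist_to_y, -contrast)]
  }
  best_o <- origin_ranked[1]

  f2 <- ped[ped$generation == "F2" & ped$sex %in% c("M", "F"), , drop = FALSE]
  ids <- intersect(f2$sample_id, gt$samples)
  sexes <- f2$sex[match(ids, f2$sample_id)]

  # Read the chosen site per panel after run-smoothing each individual's
  # position-ordered vector (within each panel separately; the two panels
  # segregate differently, so runs are only meaningful within a panel).
  # Individuals missing at the chosen site fall back to the next-ranked
  # site, which stands in for the imputation step of read-level pipelines.
  read_panel <- function(panel, ranked) {
    panel <- sort(unique(panel))
    g_sub <- gt$geno[panel, match(ids, gt$samples), drop = FALSE]
    if (smooth && length(panel) >= 3) {
      g_sub <- apply(g_sub, 2, smooth_genotype_runs)
      g_sub <- matrix(g_sub, nrow = length(panel))
    }
    out <- rep(NA_integer_, length(ids))
    for (site in ranked) {
      fill <- is.na(out)
      if (!any(fill)) break
      out[fill] <- g_sub[match(site, panel), fill]
    }
    out
  }
  gy <- read_panel(ydiag_sites, ydiag_ranked)
  go <- read_panel(origin_sites, origin_ranked)

  # the homogametic parents' homozygous code at the chosen Y/W site anchors
  # the decode (robust to REF/ALT orientation)
  homog <- setdiff(c("M", "F"), heterogametic_sex)
  par_ids <- intersect(
    ped$sample_id[ped$generation %in% c("F0", "F1", "species_surrogate") &
      ped$sex == homog],
    gt$samples
  )
  no_det_code <- 0L
  if (length(par_ids) > 0) {
    gp <- gt$geno[best_y, par_ids]
    gp <- gp[!is.na(gp) & gp != 1L]
    if (length(gp) > 0) no_det_code <- as.integer(round(mean(gp)))
  }

  calls <- purrr::map2_dfr(seq_along(ids), sexes, function(i, sx) {
    dec <- decode_composition(gy[i], go[i], heterogametic_sex, no_det_code)
    carries <- !dec$unresolved && !is.na(dec$a2) &&
      substr(dec$a2, 1, 1) %in% c("Y", "W")
    pred <- if (dec$unresolved) {
      NA_character_
    } else if (carries) {
      heterogametic_sex
    } else {
      setdiff(c("M", "F"), heterogametic_sex)
    }
    tibble::tibble(
      sample_id = ids[i], sex = sx,
      allele_1 = dec$a1, allele_2 = dec$a2,
      composition = if (dec$unresolved) {
        NA_character_
      } else {
        paste(dec$a1, dec$a2)
      },
      carries_het_allele = carries,
      predicted_sex = pred,
      discordant = !is.na(pred) & pred != sx,
      unresolved = dec$unresolved
    )
  })
  attr(calls, "sites") <- c(ydiag = best_y, origin = best_o)
  class(calls) <- c("sexqtl_composition", class(calls))
  calls
}

#' Summarise sex-chromosome compositions
#'
#' Counts compositions by phenotypic sex, computes sex-ratio-corrected
#' composition fractions (each sex reweighted to 0.5 before pooling), and
#' tests each composition's deficit against its Mendelian expectation with
#' an exact binomial test. At a site pair segregating as het x het for the
#' determiner-linked chromosome and het for the origin chromosome, the
#' Mendelian expectation is 1/4, 1/2, 1/4 over the three compositions per
#' axis; the expectation vector is supplied so other designs can be tested.
#'
#' @param calls A `sexqtl_composition` tibble.
#' @param expected Named numeric vector of expected fractions per
#'   composition (defaults to the uniform-over-observed-classes
#'   expectation when `NULL`).
#' @return A tibble: `composition`, per-sex counts, `n`, `frac_corrected`,
#'   `expected`, `p_deficit` (one-sided exact binomial against the
#'   expectation).
#' @export
composition_summary <- function(calls, expected = NULL) {
  calls <- calls[!calls$unresolved & !is.na(calls$composition), , drop = FALSE]
  if (nrow(calls) == 0) stop("no resolved composition calls")
  tab <- calls |>
    dplyr::count(.data$composition, .data$sex) |>
    tidyr::pivot_wider(
      names_from = "sex", values_from = "n", values_fill = 0L,
      names_prefix = "n_"
    )
  if (!"n_M" %in% names(tab)) tab$n_M <- 0L
  if (!"n_F" %in% names(tab)) tab$n_F <- 0L
  tot_m <- sum(tab$n_M)
  tot_f <- sum(tab$n_F)
  tab$n <- tab$n_M + tab$n_F
  # reweight each sex to 0.5 before pooling
  tab$frac_corrected <- 0.5 * (if (tot_m > 0) tab$n_M / tot_m else 0) +
    0.5 * (if (tot_f > 0) tab$n_F / tot_f else 0)
  if (is.null(expected)) {
    expected <- stats::setNames(
      rep(1 / nrow(tab), nrow(tab)), tab$composition
    )
  }
  tab$expected <- as.numeric(expected[tab$composition])
  n_tot <- sum(tab$n)
  tab$p_deficit <- vapply(seq_len(nrow(tab)), function(i) {
    if (is.na(tab$expected[i])) {
      return(NA_real_)
    }
    stats::binom.test(tab$n[i], n_tot,
      p = tab$expected[i],
      alternative = "less"
    )$p.value
  }, numeric(1))
  tab
}

#' Export a genotype matrix at sex-linked sites
#'
#' Writes a plain-text individuals x sites matrix of genotype codes for
#' diffing, and (optionally) draws the classic three-colour panel: red for
#' homozygotes of the grandmother-derived allele, orange for heterozygotes,
#' yellow for homozygotes of the grandfather-derived allele, grey for
#' missing.
#'
#' @param gt A [geno_table()].
#' @param ped Pedigree tibble (F2 rows are drawn, ordered by sex).
#' @param sites Site indices.
#' @param path Path for the text matrix (`NULL` to skip writing).
#' @return A ggplot object, invisibly; the text matrix is written to
#'   `path`.
#' @export
export_genotype_matrix_plot <- function(gt, ped, sites, path = NULL) {
  stopifnot(inherits(gt, "geno_table"))
  f2 <- ped[ped$generation == "F2", , drop = FALSE]
  ids <- intersect(f2$sample_id, gt$samples)
  ids <- ids[order(f2$sex[match(ids, f2$sample_id)])]
  g <- gt$geno[sites, match(ids, gt$samples), drop = FALSE]
  mat <- t(g) # individuals x sites
  rownames(mat) <- ids
  colnames(mat) <- gt$markers$marker_id[sites]
  if (!is.null(path)) {
    utils::write.table(
      cbind(sample_id = rownames(mat), as.data.frame(mat)),
      path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  long <- tibble::tibble(
    sample_id = rep(rownames(mat), times = ncol(mat)),
    marker_id = rep(colnames(mat), each = nrow(mat)),
    genotype = factor(as.integer(mat), levels = 0:2)
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$marker_id, levels = colnames(mat)),
    y = factor(.data$sample_id, levels = rev(rownames(mat))),
    fill = .data$genotype
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(`0` = "#d73027", `1` = "#fc8d59", `2` = "#fee090"),
      na.value = "grey85",
      labels = c("hom grandmother", "het", "hom grandfather"),
      name = NULL
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  invisible(p)
}
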