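#' Validate pipeline inputs
#'
#' Checks sample concordance between VCF and pedigree, marker concordance
#' between map and VCF, and the sex-label vocabulary.
#'
#' @param vcf Path to the VCF.
#' @param pedigree Path to the pedigree TSV.
#' @param map Optional path to the marker map TSV.
#' @return A tibble of diagnostics (`severity`, `message`); zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(vcf, pedigree, map = NULL) {
  diags <- list()
  note <- function(severity, message) {
    diags[[length(diags) + 1]] <<- tibble::tibble(
      severity = severity, message = message
    )
  }
  ped <- tryCatch(read_pedigree(pedigree), error = function(e) {
    note("error", conditionMessage(e))
    NULL
  })
  gt <- tryCatch(read_cross_vcf(vcf, ped = NULL), error = function(e) {
    note("error", conditionMessage(e))
    NULL
  })
  if (!is.null(ped) && !is.null(gt)) {
    vcf_only <- setdiff(gt$samples, ped$sample_id)
    for (s in vcf_only) {
      note("error", paste0("VCF sample absent from pedigree: ", s))
    }
    ped_only <- setdiff(ped$sample_id, gt$samples)
    for (s in ped_only) {
      note("warning", paste0("pedigree sample absent from VCF: ", s))
    }
  }
  if (!is.null(map) && !is.null(gt)) {
    mp <- tryCatch(read_marker_map(map), error = function(e) {
      note("error", conditionMessage(e))
      NULL
    })
    if (!is.null(mp)) {
      map_only <- setdiff(mp$marker_id, gt$markers$marker_id)
      if (length(map_only) > 0) {
        note("warning", paste0(
          length(map_only), " map marker(s) absent from VCF"
        ))
      }
    }
  }
  if (length(diags) == 0) {
    tibble::tibble(severity = character(0), message = character(0))
  } else {
    dplyr::bind_rows(diags)
  }
}

# Deterministic child seeds so stages are independently reproducible
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, sexstats = 23L, scan = 37L, trace = 53L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full sex-chromosome identification pipeline
#'
#' Orchestrates filter -> diagnostic-site ascertainment -> sex-contrasted
#' statistics with the permutation test -> heterogamety call -> marker
#' regression scan -> composition tracing -> sex-ratio test on in-memory
#' inputs (a genotype table and pedigree, e.g. from [simulate_cross()] or
#' [read_cross_vcf()]), and returns a machine-readable summary.
#'
#' @param gt A [geno_table()] (REF-coded; polarization is applied).
#' @param ped Pedigree tibble.
#' @param map Optional marker map with `cM` (enables the interval scan).
#' @param n_perm Permutations for the heterozygote-difference test.
#' @param max_extreme Significance rule: at most this many permutations as
#'   extreme.
#' @param filter_cfg A [filter_config()].
#' @param interval_scan Also run HMM interval mapping (slower; needs `map`
#'   with `cM`).
#' @param trace Run composition tracing on the called sex chromosome.
#' @param diagnostic_mode `"auto"`, `"pedigree"` or `"species_surrogate"`
#'   for Y/W-linked site selection.
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @return A list of class `sexqtl_run`: `summary` (one-row tibble:
#'   candidate chromosome, heterogamety, peak LOD/PVE, sex-ratio test),
#'   `het_stats`, `heterogamety`, `scan`, `interval` (or `NULL`),
#'   `composition` (or `NULL`), `log` (character vector of stage notes).
#' @export
run_pipeline <- function(gt, ped, map = NULL, n_perm = 10000,
                         max_extreme = 1L, filter_cfg = filter_config(),
                         interval_scan = FALSE, trace = TRUE,
                         diagnostic_mode = c("auto", "pedigree", "species_surrogate"),
                         seed = 1L) {
  stopifnot(inherits(gt, "geno_table"))
  diagnostic_mode <- match.arg(diagnostic_mode)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  say("seed=", seed, "; n_perm=", n_perm)

  say("input: ", nrow(gt$geno), " sites x ", length(gt$samples), " samples")
  if (!is.null(gt$depth)) gt <- mask_low_depth(gt, filter_cfg$gt_min_depth)
  gt <- filter_sites_individuals(gt, filter_cfg)
  if (!is.null(gt$depth)) {
    gt <- depth_iqr_site_filter(gt, filter_cfg$depth_iqr_mult)
  }
  say("after filters: ", nrow(gt$geno), " sites x ", length(gt$samples), " samples")
  gt <- polarize_to_grandmother(gt, ped)

  have_f1 <- any(ped$generation == "F1" & ped$sample_id %in% gt$samples)
  f1_sites <- tryCatch(
    select_f0_diagnostic_sites(gt, ped, require_f1_het = have_f1),
    error = function(e) integer(0)
  )
  if (length(f1_sites) < 10) {
    af_sites <- infer_f1_het_sites_by_af(
      gt, ped,
      band = filter_cfg$f1_het_af_band,
      het_excess_max = filter_cfg$het_excess_max
    )
    say("F1-het sites by allele frequency: ", length(af_sites))
    f1_sites <- af_sites
  } else {
    say("F0-diagnostic/F1-het sites: ", length(f1_sites))
  }
  if (length(f1_sites) == 0) stop("sexstats stage: no informative sites")

  # the heterozygote-difference contrast is informative at Y/W-linked sites,
  # which are not part of the F1-het set, so it runs genome-wide
  het_stats <- permutation_test(
    gt, ped,
    sites = NULL,
    n_perm = n_perm, seed = stage_seed(seed, "sexstats"),
    max_extreme = max_extreme
  )
  calls <- call_heterogamety(het_stats)
  called <- calls[calls$direction != "none", , drop = FALSE]
  called <- called[order(-called$n_significant), , drop = FALSE]
  het_chrom <- if (nrow(called) > 0) called$chrom[1] else NA_character_
  het_dir <- if (nrow(called) > 0) called$direction[1] else "none"
  say("heterogamety call: ", het_dir, " on ", het_chrom)

  scan <- scan_markers(gt, ped, sites = f1_sites)
  peak <- scan[which.max(scan$lod), , drop = FALSE]
  say("marker-scan peak: ", peak$chrom, " LOD=", round(peak$lod, 2))

  interval <- NULL
  if (interval_scan && !is.null(map) && "cM" %in% names(map)) {
    probs <- conditional_genotype_probs(gt, map, ped)
    interval <- interval_scan_binary(probs)
    ipk <- interval[which.max(interval$lod), ]
    say("interval-scan peak: ", ipk$chrom, " LOD=", round(ipk$lod, 2))
  }

  composition <- NULL
  if (trace && het_dir != "none") {
    het_sex <- if (het_dir == "XY") "M" else "F"
    mode <- if (diagnostic_mode == "auto") {
      if (any(ped$generation == "species_surrogate" &
        ped$sample_id %in% gt$samples) && !have_f1) {
        "species_surrogate"
      } else {
        "pedigree"
      }
    } else {
      diagnostic_mode
    }
    ydiag <- select_sex_linked_sites(gt, ped, het_sex, mode, chrom = het_chrom)
    # origin sites require heterozygous F1s where F1 genotypes exist: a
    # recombinant F1 sex chromosome otherwise makes distal sites look
    # maximally sex-linked while scrambling the species decode
    origin <- tryCatch(
      {
        os <- select_f0_diagnostic_sites(gt, ped,
          require_f1_het = have_f1,
          mode = if (mode == "pedigree") "pedigree" else "species_surrogate"
        )
        os[gt$markers$chrom[os] == het_chrom]
      },
      error = function(e) integer(0)
    )
    if (length(ydiag) > 0 && length(origin) > 0) {
      composition <- assign_composition(
        gt, ped, ydiag, origin, het_sex,
        stats = het_stats
      )
      say(
        "composition calls: ", sum(!composition$unresolved), " resolved, ",
        sum(composition$discordant, na.rm = TRUE), " discordant"
      )
    } else {
      say("tracing skipped: ydiag=", length(ydiag), " origin=", length(origin))
    }
  }

  sx <- f2_by_sex(ped)
  ratio <- binomial_sex_ratio_test(length(sx$males), length(sx$females))

  summary <- tibble::tibble(
    candidate_chrom = het_chrom,
    heterogamety = het_dir,
    n_significant_sites = if (nrow(called) > 0) called$n_significant[1] else 0L,
    scan_peak_chrom = peak$chrom,
    scan_peak_lod = peak$lod,
    scan_peak_pve = peak$pve,
    n_f2_males = ratio$n_males,
    n_f2_females = ratio$n_females,
    sex_ratio_p = ratio$p,
    seed = as.integer(seed)
  )
  structure(
    list(
      summary = summary, het_stats = het_stats, heterogamety = calls,
      scan = scan, interval = interval, composition = composition,
      filtered_gt = gt, log = log
    ),
    class = "sexqtl_run"
  )
}

#' @export
print.sexqtl_run <- function(x, ...) {
  s <- x$summary
  cat("<sexqtl_run>\n")
  cat(
    "  heterogamety: ", s$heterogamety, " on ", s$candidate_chrom,
    " (", s$n_significant_sites, " significant sites)\n",
    sep = ""
  )
  cat(
    "  marker-scan peak: ", s$scan_peak_chrom,
    sprintf(" LOD=%.2f PVE=%.1f%%", s$scan_peak_lod, s$scan_peak_pve), "\n",
    sep = ""
  )
  cat(
    "  F2 sex ratio: ", s$n_f2_males, "M / ", s$n_f2_females, "F",
    sprintf(" (binomial P=%.3g)", s$sex_ratio_p), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::glance
glance.sexqtl_run <- function(x, ...) x$summary
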