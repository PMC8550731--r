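#' Configuration for a simulated F2 interspecific cross
#'
#' Builds the parameter set for [simulate_cross()]: an F0 x F0 cross of two
#' diverged species, F1 sib-mating within families, and F2 offspring
#' genotyped at SNP markers with RAD-seq-like noise. Defaults emulate the
#' structure of reduced-representation genotyping of cichlid crosses:
#' ~10,000 SNPs over 22 chromosomes, two families, 100-220 F2, read depth in
#' the 12-50x range.
#'
#' Sex determination: `sd_system = "XY"` places a dominant male determiner on
#' one grandfather haplotype (the Y) at `sd_position_cM` on `sd_chromosome`;
#' `"ZW"` places a dominant female determiner on one grandmother haplotype
#' (the W); `"none"` assigns sex as a fair coin. `penetrance` is the
#' probability that the determiner genotype dictates phenotypic sex; with the
#' complementary probability the opposite sex is recorded. An optional
#' `modifier` locus (its allele rides on one haplotype of the chosen founder)
#' overrides the determiner with its own penetrance: the determiner is
#' evaluated first, then, in carriers of the modifier allele, the modifier
#' flips the sex to its `effect` direction with probability
#' `modifier$penetrance`.
#'
#' Marker architecture: a fraction `diagnostic_rate` of markers is fixed for
#' alternative alleles between the founder species (the informative markers
#' of an interspecific cross); the rest are monomorphic within the cross.
#' On the sex chromosome, markers within `gametolog_region_cM` of the
#' determiner become X/Y (or Z/W) gametolog variants with probability
#' `gametolog_divergence`: the heterogametic founder is heterozygous there
#' and the homogametic founder homozygous.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp,chrom_length_cM Physical and map length per
#'   chromosome (recycled).
#' @param n_markers Total marker count across the genome.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @param n_f2 Total number of F2 offspring across families.
#' @param n_families Number of F1 x F1 families.
#' @param diagnostic_rate Fraction of markers fixed between founder species,
#'   in (0, 1].
#' @param sd_system `"XY"`, `"ZW"` or `"none"`.
#' @param sd_chromosome,sd_position_cM Location of the sex determiner.
#' @param penetrance Probability the determiner dictates sex.
#' @param modifier Optional list `(chromosome, position_cM, effect =
#'   "feminizing"|"masculinizing", penetrance, origin =
#'   "grandmother"|"grandfather")`.
#' @param gametolog_divergence Per-site probability of an X/Y (Z/W) variant
#'   within the determiner-linked region.
#' @param gametolog_region_cM Half-width of the determiner-linked region.
#' @param no_recomb_window_cM Half-width of a zero-recombination window
#'   around the determiner (0 = none; young sex chromosomes recombine).
#' @param viability Optional named list mapping `"<composition>|<sex>"` to a
#'   survival probability in (0, 1]; unnamed compositions survive.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth mean and
#'   size parameter, shared across sexes.
#' @param missing_rate,genotype_error_rate Per-genotype probabilities of
#'   dropout and of being swapped to a uniformly chosen different genotype.
#' @param n_surrogates Per species, extra individuals genotyped in place of
#'   unavailable F0/F1 (0 = none).
#' @param y_deletion Optional list `(chromosome, start_bp, end_bp,
#'   depth_factor)` halving (or scaling) depth of determiner-carrying
#'   haplotype carriers over a span, to emulate Y/W degeneration.
#' @param seed Integer RNG seed; identical seed and config give identical
#'   output.
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(n_chromosomes = 22,
                         chrom_length_bp = 35e6,
                         chrom_length_cM = 70,
                         n_markers = 10000,
                         map_function = c("kosambi", "haldane"),
                         n_f2 = 150,
                         n_families = 2,
                         diagnostic_rate = 0.25,
                         sd_system = c("XY", "ZW", "none"),
                         sd_chromosome = 1,
                         sd_position_cM = NULL,
                         penetrance = 1,
                         modifier = NULL,
                         gametolog_divergence = 0.05,
                         gametolog_region_cM = 25,
                         no_recomb_window_cM = 0,
                         viability = NULL,
                         depth_mean = 30,
                         depth_dispersion = 8,
                         missing_rate = 0.02,
                         genotype_error_rate = 0.005,
                         n_surrogates = 0,
                         y_deletion = NULL,
                         seed = 1L) {
  map_function <- match.arg(map_function)
  sd_system <- match.arg(sd_system)
  if (n_chromosomes < 1 || n_markers < 1) {
    stop("need at least one chromosome and one marker")
  }
  chrom_length_bp <- rep_len(chrom_length_bp, n_chromosomes)
  chrom_length_cM <- rep_len(chrom_length_cM, n_chromosomes)
  if (is.null(sd_position_cM)) {
    sd_position_cM <- chrom_length_cM[sd_chromosome] / 2
  }
  probs <- c(
    diagnostic_rate = diagnostic_rate, penetrance = penetrance,
    gametolog_divergence = gametolog_divergence,
    missing_rate = missing_rate, genotype_error_rate = genotype_error_rate
  )
  if (any(probs < 0) || any(probs > 1)) {
    stop("rates and probabilities must lie in [0, 1]")
  }
  if (diagnostic_rate == 0) stop("diagnostic_rate must be in (0, 1]")
  if (sd_system != "none") {
    if (sd_chromosome < 1 || sd_chromosome > n_chromosomes) {
      stop("sd_chromosome out of range")
    }
    if (sd_position_cM > chrom_length_cM[sd_chromosome]) {
      stop("sd_position_cM exceeds chromosome map length")
    }
  }
  if (!is.null(modifier)) {
    stopifnot(
      modifier$effect %in% c("feminizing", "masculinizing"),
      modifier$penetrance >= 0, modifier$penetrance <= 1
    )
    if (is.null(modifier$origin)) modifier$origin <- "grandmother"
  }
  structure(
    list(
      n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
      chrom_length_cM = chrom_length_cM, n_markers = n_markers,
      map_function = map_function, n_f2 = n_f2, n_families = n_families,
      diagnostic_rate = diagnostic_rate, sd_system = sd_system,
      sd_chromosome = sd_chromosome, sd_position_cM = sd_position_cM,
      penetrance = penetrance, modifier = modifier,
      gametolog_divergence = gametolog_divergence,
      gametolog_region_cM = gametolog_region_cM,
      no_recomb_window_cM = no_recomb_window_cM,
      viability = viability, depth_mean = depth_mean,
      depth_dispersion = depth_dispersion, missing_rate = missing_rate,
      genotype_error_rate = genotype_error_rate,
      n_surrogates = n_surrogates, y_deletion = y_deletion,
      seed = as.integer(seed)
    ),
    class = "cross_config"
  )
}

# ---- founder architecture ---------------------------------------------------

# Locus table: markers plus pseudo-loci (determiner "__SD__", modifier
# "__MOD__") inserted in map order; pseudo-loci carry no genotype but are
# tracked through meiosis so sex and composition are exact.
build_loci <- function(config) {
  m_per_chrom <- diff(round(
    seq(0, config$n_markers, length.out = config$n_chromosomes + 1)
  ))
  m_per_chrom[m_per_chrom == 0] <- 1L
  loci <- purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    m <- m_per_chrom[ch]
    bp <- sort(sample.int(config$chrom_length_bp[ch], m))
    tibble::tibble(
      chrom = paste0("chr", ch), chrom_i = ch, bp = bp,
      cM = bp / config$chrom_length_bp[ch] * config$chrom_length_cM[ch],
      marker_id = sprintf("chr%d_%d", ch, bp),
      pseudo = FALSE
    )
  })
  add_pseudo <- function(loci, chrom_i, pos_cM, id) {
    len_bp <- config$chrom_length_bp[chrom_i]
    len_cM <- config$chrom_length_cM[chrom_i]
    row <- tibble::tibble(
      chrom = paste0("chr", chrom_i), chrom_i = chrom_i,
      bp = round(pos_cM / len_cM * len_bp), cM = pos_cM,
      marker_id = id, pseudo = TRUE
    )
    dplyr::arrange(dplyr::bind_rows(loci, row), chrom_i, cM, bp)
  }
  if (config$sd_system != "none") {
    loci <- add_pseudo(loci, config$sd_chromosome, config$sd_position_cM, "__SD__")
  }
  if (!is.null(config$modifier)) {
    loci <- add_pseudo(
      loci, config$modifier$chromosome, config$modifier$position_cM, "__MOD__"
    )
  }
  loci
}

# Founder haplotype alleles: 4 x n_loci matrix of 0/1 (hap 1,2 = grandmother;
# 3,4 = grandfather; hap 1 carries W under ZW, hap 3 carries Y under XY).
build_founder_alleles <- function(config, loci) {
  n <- nrow(loci)
  diag_site <- !loci$pseudo & stats::runif(n) < config$diagnostic_rate
  alleles <- matrix(0L, nrow = 4, ncol = n)
  alleles[3:4, diag_site] <- 1L
  if (config$sd_system != "none" && config$gametolog_divergence > 0) {
    in_region <- !loci$pseudo &
      loci$chrom_i == config$sd_chromosome &
      abs(loci$cM - config$sd_position_cM) <= config$gametolog_region_cM
    gametolog <- in_region & stats::runif(n) < config$gametolog_divergence
    het_hap <- if (config$sd_system == "XY") 3L else 1L
    alleles[, gametolog] <- 0L
    alleles[het_hap, gametolog] <- 1L
    diag_site[gametolog] <- FALSE
  } else {
    gametolog <- rep(FALSE, n)
  }
  list(alleles = alleles, diagnostic = diag_site, gametolog = gametolog)
}

# ---- meiosis ----------------------------------------------------------------

# One or many gametes from a parent, per chromosome. hap_a/hap_b: founder-id
# vectors over that chromosome's loci (map order); r: per-interval
# recombination fractions (length L-1). Returns L x n matrix of founder ids.
gamete_batch <- function(hap_a, hap_b, r, n) {
  L <- length(hap_a)
  if (L == 1) {
    pick <- stats::rbinom(n, 1, 0.5)
    return(matrix(ifelse(pick == 0, hap_a, hap_b), nrow = 1))
  }
  switches <- matrix(
    stats::rbinom(n * (L - 1), 1, rep(r, times = n)),
    nrow = L - 1
  )
  start <- stats::rbinom(n, 1, 0.5)
  phase <- (rep(start, each = L) +
    as.vector(rbind(0L, apply(switches, 2, cumsum)))) %% 2
  phase <- matrix(phase, nrow = L)
  out <- matrix(hap_a, nrow = L, ncol = n)
  out[phase == 1] <- matrix(hap_b, nrow = L, ncol = n)[phase == 1]
  out
}

# Per-chromosome interval recombination fractions, honouring the optional
# zero-recombination window around the determiner.
interval_r <- function(config, loci_chr) {
  d <- diff(loci_chr$cM)
  r <- recomb_fraction(d, config$map_function)
  if (config$sd_system != "none" && config$no_recomb_window_cM > 0 &&
    loci_chr$chrom_i[1] == config$sd_chromosome) {
    lo <- config$sd_position_cM - config$no_recomb_window_cM
    hi <- config$sd_position_cM + config$no_recomb_window_cM
    mid <- (loci_chr$cM[-1] + loci_chr$cM[-nrow(loci_chr)]) / 2
    r[mid >= lo & mid <= hi] <- 0
  }
  r
}

#' Simulate one meiosis across the genome
#'
#' Produces a gamete as a founder-haplotype-id vector over all loci. Used
#' internally by [simulate_cross()]; exported so the recombination process
#' can be tested directly against the map-function closed forms.
#'
#' @param hap_a,hap_b Founder-id vectors over all loci (map order).
#' @param loci Locus tibble from the simulator (needs `chrom_i`, `cM`).
#' @param config A [cross_config()].
#' @param n Number of gametes.
#' @return Matrix, loci x n, of founder haplotype ids.
#' @export
meiosis <- function(hap_a, hap_b, loci, config, n = 1) {
  idx <- split(seq_len(nrow(loci)), loci$chrom_i)
  out <- matrix(0L, nrow = nrow(loci), ncol = n)
  for (ii in idx) {
    r <- interval_r(config, loci[ii, , drop = FALSE])
    out[ii, ] <- gamete_batch(hap_a[ii], hap_b[ii], r, n)
  }
  out
}

# ---- sex assignment ---------------------------------------------------------

carrier_at <- function(hap_m, hap_p, locus_row, hap_id) {
  hap_m[locus_row, ] == hap_id | hap_p[locus_row, ] == hap_id
}

# Determiner first, then modifier override in carriers. Returns "M"/"F".
assign_sex <- function(config, carries_det, carries_mod) {
  n <- length(carries_det)
  if (config$sd_system == "none") {
    return(ifelse(stats::runif(n) < 0.5, "M", "F"))
  }
  det_sex <- if (config$sd_system == "XY") "M" else "F"
  other <- if (det_sex == "M") "F" else "M"
  obey <- stats::runif(n) < config$penetrance
  sex <- ifelse(carries_det,
    ifelse(obey, det_sex, other),
    ifelse(obey, other, det_sex)
  )
  if (!is.null(config$modifier)) {
    mod_sex <- if (config$modifier$effect == "feminizing") "F" else "M"
    hit <- carries_mod & stats::runif(n) < config$modifier$penetrance
    sex[hit] <- mod_sex
  }
  sex
}

composition_labels <- function(config, hap_m, hap_p, sd_row) {
  lab_one <- function(id) {
    if (config$sd_system == "XY") {
      c("X_A", "X_A", "Y_B", "X_B")[id]
    } else {
      c("W_A", "Z_A", "Z_B", "Z_B")[id]
    }
  }
  purrr::map2_chr(hap_m[sd_row, ], hap_p[sd_row, ], function(a, b) {
    labs <- c(lab_one(a), lab_one(b))
    ord <- order(substr(labs, 1, 1) %in% c("Y", "W"), labs)
    paste(labs[ord], collapse = " ")
  })
}

# ---- the full cross ---------------------------------------------------------

#' Simulate the founder (F0) generation
#'
#' @param config A [cross_config()].
#' @return List with `gt` (a [geno_table()] of the two F0), `ped` (pedigree
#'   tibble), and the internal `loci`, `founders` architecture reused by
#'   [simulate_cross()].
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  set.seed(config$seed)
  loci <- build_loci(config)
  founders <- build_founder_alleles(config, loci)
  mk <- !loci$pseudo
  markers <- marker_tibble(loci[mk, ])
  al <- founders$alleles[, mk, drop = FALSE]
  geno <- cbind(
    F0_GM = al[1, ] + al[2, ],
    F0_GF = al[3, ] + al[4, ]
  )
  ped <- tibble::tibble(
    sample_id = c("F0_GM", "F0_GF"), generation = "F0", family = "*",
    sex = c("F", "M"), species = c("A", "B")
  )
  list(
    gt = geno_table(markers, geno),
    ped = ped, loci = loci, founders = founders
  )
}

marker_tibble <- function(loci_mk) {
  tibble::tibble(
    chrom = loci_mk$chrom, bp = loci_mk$bp, marker_id = loci_mk$marker_id,
    ref = "A", alt = "T", cM = loci_mk$cM
  )
}

#' Simulate a full F0 -> F1 -> F2 interspecific cross
#'
#' Crosses two founder "species" individuals, mates F1 siblings within
#' `n_families` families, assigns phenotypic sex from the configured
#' sex-determination architecture, applies viability selection by rejection
#' sampling, and genotypes everyone with a negative-binomial read-depth
#' model, random dropout and symmetric genotype error.
#'
#' @param config A [cross_config()].
#' @return A list of class `sim_cross`: `gt` (a [geno_table()] of F0 + F1 +
#'   F2 and any surrogates), `ped` (pedigree tibble: `sample_id`,
#'   `generation`, `family`, `sex`, `species`), `map` (marker map tibble with
#'   `chrom`, `marker_id`, `bp`, `cM`), and `truth` (a `cross_truth`: the
#'   determiner location and system, per-F2 composition labels, carrier and
#'   recombinant flags, genotype-error positions, and founder-haplotype
#'   paintings).
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  fo <- simulate_founders(config) # seeds the RNG
  loci <- fo$loci
  founders <- fo$founders
  n_loci <- nrow(loci)
  sd_row <- which(loci$marker_id == "__SD__")
  mod_row <- which(loci$marker_id == "__MOD__")

  f0_haps <- list(
    GM = list(rep(1L, n_loci), rep(2L, n_loci)),
    GF = list(rep(3L, n_loci), rep(4L, n_loci))
  )

  # F1s: draw until each family has one female and one male (or any pair
  # under sd_system = "none")
  f1_pool <- list()
  attempts <- 0
  need_f <- config$n_families
  need_m <- config$n_families
  while ((need_f > 0 || need_m > 0) && attempts < 200 * config$n_families) {
    attempts <- attempts + 1
    hm <- meiosis(f0_haps$GM[[1]], f0_haps$GM[[2]], loci, config)[, 1]
    hp <- meiosis(f0_haps$GF[[1]], f0_haps$GF[[2]], loci, config)[, 1]
    if (config$sd_system == "none") {
      sex <- if (stats::runif(1) < 0.5) "M" else "F"
    } else {
      det_id <- if (config$sd_system == "XY") 3L else 1L
      carries <- hm[sd_row] == det_id || hp[sd_row] == det_id
      det_sex <- if (config$sd_system == "XY") "M" else "F"
      sex <- if (carries) det_sex else setdiff(c("M", "F"), det_sex)
    }
    if (sex == "F" && need_f > 0) {
      f1_pool[[length(f1_pool) + 1]] <- list(hm = hm, hp = hp, sex = "F")
      need_f <- need_f - 1
    } else if (sex == "M" && need_m > 0) {
      f1_pool[[length(f1_pool) + 1]] <- list(hm = hm, hp = hp, sex = "M")
      need_m <- need_m - 1
    }
  }
  if (need_f > 0 || need_m > 0) {
    stop("could not obtain F1 parents of both sexes")
  }
  females <- Filter(function(x) x$sex == "F", f1_pool)
  males <- Filter(function(x) x$sex == "M", f1_pool)

  fam_names <- LETTERS[seq_len(config$n_families)]
  n_per_fam <- diff(round(seq(0, config$n_f2, length.out = config$n_families + 1)))

  f2_list <- list()
  for (fi in seq_len(config$n_families)) {
    mother <- females[[fi]]
    father <- males[[fi]]
    n_need <- n_per_fam[fi]
    kept_hm <- matrix(0L, n_loci, 0)
    kept_hp <- matrix(0L, n_loci, 0)
    kept_sex <- character(0)
    tries <- 0
    while (length(kept_sex) < n_need && tries < 60) {
      tries <- tries + 1
      n_draw <- max(n_need - length(kept_sex), 8)
      hm <- meiosis(mother$hm, mother$hp, loci, config, n = n_draw)
      hp <- meiosis(father$hm, father$hp, loci, config, n = n_draw)
      if (length(sd_row) == 1) {
        det_id <- if (config$sd_system == "XY") 3L else 1L
        carries_det <- carrier_at(hm, hp, sd_row, det_id)
      } else {
        carries_det <- rep(FALSE, n_draw)
      }
      if (length(mod_row) == 1) {
        mod_id <- if (config$modifier$origin == "grandmother") 1L else 3L
        carries_mod <- carrier_at(hm, hp, mod_row, mod_id)
      } else {
        carries_mod <- rep(FALSE, n_draw)
      }
      sex <- assign_sex(config, carries_det, carries_mod)
      keep <- rep(TRUE, n_draw)
      if (!is.null(config$viability) && length(sd_row) == 1) {
        comp <- composition_labels(config, hm, hp, sd_row)
        surv <- purrr::map2_dbl(comp, sex, function(co, sx) {
          v <- config$viability[[paste0(co, "|", sx)]]
          if (is.null(v)) 1 else v
        })
        keep <- stats::runif(n_draw) < surv
      }
      kept_hm <- cbind(kept_hm, hm[, keep, drop = FALSE])
      kept_hp <- cbind(kept_hp, hp[, keep, drop = FALSE])
      kept_sex <- c(kept_sex, sex[keep])
    }
    if (length(kept_sex) < n_need) {
      stop("viability selection rejected all offspring in family ", fam_names[fi])
    }
    sel <- seq_len(n_need)
    f2_list[[fi]] <- list(
      hm = kept_hm[, sel, drop = FALSE], hp = kept_hp[, sel, drop = FALSE],
      sex = kept_sex[sel], family = fam_names[fi]
    )
  }

  hap_m <- do.call(cbind, purrr::map(f2_list, "hm"))
  hap_p <- do.call(cbind, purrr::map(f2_list, "hp"))
  f2_sex <- unlist(purrr::map(f2_list, "sex"))
  f2_fam <- rep(fam_names, times = n_per_fam)
  n_f2 <- length(f2_sex)
  f2_ids <- sprintf("F2_%s_%03d", f2_fam, unlist(lapply(n_per_fam, seq_len)))

  # genotypes from haplotype ids: allele lookup per locus
  al <- founders$alleles
  geno_from_haps <- function(h1, h2) {
    n <- ncol(h1)
    li <- rep(seq_len(n_loci), times = n)
    g <- al[cbind(as.vector(h1), li)] + al[cbind(as.vector(h2), li)]
    matrix(as.integer(g), nrow = n_loci)
  }
  f2_geno <- geno_from_haps(hap_m, hap_p)

  f1_ids <- character(0)
  f1_geno <- NULL
  f1_sex <- character(0)
  f1_fam <- character(0)
  for (fi in seq_len(config$n_families)) {
    for (who in c("F", "M")) {
      p <- if (who == "F") females[[fi]] else males[[fi]]
      f1_ids <- c(f1_ids, sprintf("F1_%s_%s", fam_names[fi], who))
      f1_geno <- cbind(f1_geno, geno_from_haps(cbind(p$hm), cbind(p$hp)))
      f1_sex <- c(f1_sex, who)
      f1_fam <- c(f1_fam, fam_names[fi])
    }
  }

  f0_geno <- cbind(al[1, ] + al[2, ], al[3, ] + al[4, ])

  # species surrogates: extra individuals of each founder species
  sur_geno <- NULL
  sur_ids <- character(0)
  sur_sex <- character(0)
  sur_species <- character(0)
  if (config$n_surrogates > 0) {
    het_species <- if (config$sd_system == "ZW") "A" else "B"
    for (sp in c("A", "B")) {
      haps <- if (sp == "A") c(1L, 2L) else c(3L, 4L)
      for (k in seq_len(config$n_surrogates)) {
        sx <- if (k %% 2 == 1) "M" else "F"
        het_hap <- if (sp == "A") 1L else 3L # W or Y carrier
        hom_hap <- if (sp == "A") 2L else 4L
        carries_sd <- config$sd_system != "none" && sp == het_species &&
          ((config$sd_system == "XY" && sx == "M") ||
            (config$sd_system == "ZW" && sx == "F"))
        pair <- if (carries_sd) c(het_hap, hom_hap) else c(hom_hap, hom_hap)
        sur_geno <- cbind(sur_geno, al[pair[1], ] + al[pair[2], ])
        sur_ids <- c(sur_ids, sprintf("SUR_%s_%02d", sp, k))
        sur_sex <- c(sur_sex, sx)
        sur_species <- c(sur_species, sp)
      }
    }
  }

  geno_all <- cbind(f0_geno, f1_geno, f2_geno, sur_geno)
  storage.mode(geno_all) <- "integer"
  ids <- c("F0_GM", "F0_GF", f1_ids, f2_ids, sur_ids)
  colnames(geno_all) <- ids

  ped <- tibble::tibble(
    sample_id = ids,
    generation = c(
      "F0", "F0", rep("F1", length(f1_ids)), rep("F2", n_f2),
      rep("species_surrogate", length(sur_ids))
    ),
    family = c("*", "*", f1_fam, f2_fam, rep("*", length(sur_ids))),
    sex = c("F", "M", f1_sex, f2_sex, sur_sex),
    species = c("A", "B", rep(NA_character_, length(f1_ids) + n_f2), sur_species)
  )

  # drop pseudo-locus rows from genotype output
  mk <- !loci$pseudo
  markers <- marker_tibble(loci[mk, ])
  geno_clean <- geno_all[mk, , drop = FALSE]

  # read depth, dropout, genotype error
  n_cells <- length(geno_clean)
  depth <- matrix(
    stats::rnbinom(n_cells, mu = config$depth_mean, size = config$depth_dispersion),
    nrow = nrow(geno_clean), dimnames = dimnames(geno_clean)
  )
  if (!is.null(config$y_deletion)) {
    del <- config$y_deletion
    span <- markers$chrom == paste0("chr", del$chromosome) &
      markers$bp >= del$start_bp & markers$bp <= del$end_bp
    det_id <- if (config$sd_system == "XY") 3L else 1L
    f1_carries <- unlist(lapply(seq_len(config$n_families), function(fi) {
      vapply(c(females[fi], males[fi]), function(p) {
        length(sd_row) == 1 &&
          (p$hm[sd_row] == det_id || p$hp[sd_row] == det_id)
      }, logical(1))
    }))
    carrier_cols <- c(
      config$sd_system == "ZW", config$sd_system == "XY", # F0 GM, GF
      f1_carries, rep(FALSE, n_f2), rep(FALSE, length(sur_ids))
    )
    if (length(sd_row) == 1) {
      carrier_cols[(2 + length(f1_ids)) + seq_len(n_f2)] <-
        carrier_at(hap_m, hap_p, sd_row, det_id)
    }
    fac <- if (is.null(del$depth_factor)) 0.5 else del$depth_factor
    depth[span, carrier_cols] <- round(depth[span, carrier_cols] * fac)
  }

  err <- matrix(stats::runif(n_cells) < config$genotype_error_rate,
    nrow = nrow(geno_clean)
  )
  if (any(err)) {
    shift <- 1L + (stats::runif(sum(err)) < 0.5)
    geno_clean[err] <- (geno_clean[err] + shift) %% 3L
  }
  miss <- matrix(stats::runif(n_cells) < config$missing_rate,
    nrow = nrow(geno_clean)
  )
  geno_clean[miss] <- NA_integer_
  err <- err & !miss # only errors that survive dropout are observable

  gt <- geno_table(
    markers[, c("chrom", "bp", "marker_id", "ref", "alt")],
    geno_clean, depth
  )

  comp <- if (length(sd_row) == 1) {
    composition_labels(config, hap_m, hap_p, sd_row)
  } else {
    rep(NA_character_, n_f2)
  }
  det_id <- if (config$sd_system == "XY") 3L else if (config$sd_system == "ZW") 1L else NA
  carries <- if (length(sd_row) == 1) {
    carrier_at(hap_m, hap_p, sd_row, det_id)
  } else {
    rep(NA, n_f2)
  }
  recomb <- rep(FALSE, n_f2)
  if (length(sd_row) == 1) {
    region <- loci$chrom_i == config$sd_chromosome &
      abs(loci$cM - config$sd_position_cM) <= config$gametolog_region_cM
    seg <- function(h) apply(h[region, , drop = FALSE], 2, function(v) length(unique(v)) > 1)
    recomb <- seg(hap_m) | seg(hap_p)
  }

  truth <- structure(
    list(
      sd_chromosome = if (config$sd_system == "none") NA_integer_ else config$sd_chromosome,
      sd_position_cM = if (config$sd_system == "none") NA_real_ else config$sd_position_cM,
      system = config$sd_system,
      modifier = config$modifier,
      records = tibble::tibble(
        sample_id = f2_ids, family = f2_fam, sex = f2_sex,
        composition = comp, carries_determiner = as.logical(carries),
        recombinant_sd = recomb
      ),
      paintings = list(
        loci = loci[, c("chrom", "bp", "cM", "marker_id", "pseudo")],
        hap_m = `colnames<-`(hap_m, f2_ids),
        hap_p = `colnames<-`(hap_p, f2_ids)
      ),
      gametolog_sites = loci$marker_id[founders$gametolog[seq_len(n_loci)] & !loci$pseudo],
      diagnostic_sites = loci$marker_id[founders$diagnostic & !loci$pseudo],
      error_mask = `dimnames<-`(err, dimnames(geno_clean))
    ),
    class = "cross_truth"
  )

  structure(
    list(gt = gt, ped = ped, map = markers, truth = truth, config = config),
    class = "sim_cross"
  )
}

#' @export
print.sim_cross <- function(x, ...) {
  cat("<sim_cross> ", x$config$sd_system, " system; ",
    sum(x$ped$generation == "F2"), " F2 in ",
    x$config$n_families, " families; ",
    nrow(x$gt$markers), " markers on ",
    x$config$n_chromosomes, " chromosomes\n",
    sep = ""
  )
  invisible(x)
}
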