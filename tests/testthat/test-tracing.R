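test_that("sex-linked site selection honours the parental contrast", {
  # sites: (1) Y-linked signature, (2) het in both sexes' parents, (3) no
  # contrast, (4) Y-linked but missing one parent (still selected)
  g <- rbind(
    c(0L, 1L, 0L, 1L, 1L, 0L),
    c(1L, 1L, 1L, 1L, 1L, 1L),
    c(0L, 0L, 0L, 0L, 1L, 0L),
    c(0L, 1L, NA, 1L, 1L, 0L)
  )
  samples <- c("F0_GM", "F0_GF", "F1_A_F", "F1_A_M", "F2_01", "F2_02")
  ped <- tibble::tibble(
    sample_id = samples,
    generation = c("F0", "F0", "F1", "F1", "F2", "F2"),
    family = c("*", "*", "A", "A", "A", "A"),
    sex = c("F", "M", "F", "M", "M", "F"),
    species = c("A", "B", NA, NA, NA, NA)
  )
  got <- select_sex_linked_sites(toy_gt(g, samples = samples), ped, "M", "pedigree")
  expect_equal(got, 1L) # site 4 lacks min_obs observed homogametic parents
  relaxed <- select_sex_linked_sites(toy_gt(g, samples = samples), ped, "M",
    "pedigree",
    min_obs = 1
  )
  expect_equal(relaxed, c(1L, 4L))
})

test_that("surrogate-mode selection contrasts heterogametic-species males", {
  g <- rbind(
    c(1L, 0L, 0L, 0L), # het in species-B male, hom in species A: selected
    c(1L, 1L, 0L, 0L), # B female het, but only B males vs A are contrasted
    c(0L, 0L, 0L, 0L) # no contrast
  )
  samples <- c("SB_M", "SB_F", "SA_M", "SA_F")
  ped <- tibble::tibble(
    sample_id = samples, generation = "species_surrogate", family = "*",
    sex = c("M", "F", "M", "F"), species = c("B", "B", "A", "A")
  )
  got <- select_sex_linked_sites(
    toy_gt(g, samples = samples), ped, "M", "species_surrogate",
    min_obs = 1
  )
  expect_equal(got, c(1L, 2L))
})

test_that("selected sites are mostly true gametolog variants in simulation", {
  sim <- simulate_cross(small_cross(
    "XY",
    seed = 71, n_f2 = 150, genotype_error_rate = 0.01
  ))
  gt <- polarize_to_grandmother(mask_low_depth(sim$gt, 10), sim$ped)
  got <- select_sex_linked_sites(gt, sim$ped, "M", "pedigree")
  precision <- mean(gt$markers$marker_id[got] %in% sim$truth$gametolog_sites)
  expect_gte(precision, 0.9)
})

test_that("run smoothing replaces only short flanked runs", {
  # run of 3 inside >=5 equal genotypes each side: replaced
  v <- c(rep(0L, 5), rep(1L, 3), rep(0L, 5))
  expect_equal(smooth_genotype_runs(v), rep(0L, 13))
  # run of 4: unchanged
  v4 <- c(rep(0L, 5), rep(1L, 4), rep(0L, 5))
  expect_equal(smooth_genotype_runs(v4), v4)
  # flank of only 4: unchanged
  v_flank <- c(rep(0L, 4), rep(1L, 3), rep(0L, 5))
  expect_equal(smooth_genotype_runs(v_flank), v_flank)
  # differing flanks: unchanged
  v_diff <- c(rep(0L, 5), rep(1L, 2), rep(2L, 5))
  expect_equal(smooth_genotype_runs(v_diff), v_diff)
  # missing data break runs and flanks
  v_na <- c(rep(0L, 5), 1L, NA, 1L, rep(0L, 5))
  expect_equal(smooth_genotype_runs(v_na), v_na)
  v_na_flank <- c(rep(0L, 4), NA, rep(1L, 3), rep(0L, 5))
  expect_equal(smooth_genotype_runs(v_na_flank), v_na_flank)
})

test_that("smoothing output alphabet never leaves the input alphabet", {
  set.seed(83)
  for (rep in 1:50) {
    v <- sample(c(0:2, NA), 40, replace = TRUE, prob = c(.4, .25, .25, .1))
    out <- smooth_genotype_runs(v)
    expect_true(all(out[!is.na(out)] %in% v[!is.na(v)]))
    expect_equal(is.na(out), is.na(v))
    # runs of length >= 4 in the input survive untouched
    rl <- rle(ifelse(is.na(v), -1L, v))
    ends <- cumsum(rl$lengths)
    for (k in which(rl$lengths >= 4 & rl$values != -1L)) {
      idx <- (ends[k] - rl$lengths[k] + 1):ends[k]
      expect_equal(out[idx], v[idx])
    }
  }
})

test_that("two-site decode follows the documented table for XY", {
  # Y-diagnostic site: het = one Y; origin site: 0/1/2 = A-A/A-B/B-B
  samples <- sprintf("I%d", 1:6)
  g <- rbind(
    c(1L, 1L, 0L, 0L, 2L, 1L), # ydiag
    c(1L, 2L, 0L, 1L, 2L, 0L) # origin
  )
  ped <- toy_f2_ped(samples, c("M", "M", "F", "F", "M", "M"))
  calls <- assign_composition(
    toy_gt(g, samples = samples), ped,
    ydiag_sites = 1L, origin_sites = 2L,
    heterogametic_sex = "M", smooth = FALSE
  )
  expect_equal(calls$composition, c(
    "X_A Y_B", # het Y, origin 1 -> partner X_A
    "X_B Y_B", # het Y, origin 2 -> partner X_B
    "X_A X_A", # no Y, origin 0
    "X_A X_B", # no Y, origin 1
    "Y_B Y_B", # two Y copies
    "X_A Y_B" # het Y, origin 0 (recombinant origin): partner X_A
  ))
  expect_equal(calls$carries_het_allele, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(calls$predicted_sex, c("M", "M", "F", "F", "M", "M"))
  expect_false(any(calls$discordant))
})

test_that("decode marks double-missing individuals unresolved", {
  samples <- c("I1", "I2")
  g <- rbind(c(NA, 1L), c(NA, 1L))
  ped <- toy_f2_ped(samples, c("M", "M"))
  calls <- assign_composition(
    toy_gt(g, samples = samples), ped,
    ydiag_sites = 1L, origin_sites = 2L, heterogametic_sex = "M",
    smooth = FALSE
  )
  expect_true(calls$unresolved[1])
  expect_false(calls$unresolved[2])
})

test_that("error-free compositions match truth exactly; noisy ones stay above 95%", {
  cfg0 <- small_cross(
    "XY",
    seed = 75, n_f2 = 100, n_markers = 2700, n_chromosomes = 6,
    missing_rate = 0, genotype_error_rate = 0, no_recomb_window_cM = 10
  )
  sim <- simulate_cross(cfg0)
  gt <- polarize_to_grandmother(sim$gt, sim$ped)
  ydiag <- select_sex_linked_sites(gt, sim$ped, "M", "pedigree", chrom = "chr2")
  origin <- select_f0_diagnostic_sites(gt, sim$ped, require_f1_het = TRUE)
  origin <- origin[gt$markers$chrom[origin] == "chr2"]
  calls <- assign_composition(gt, sim$ped, ydiag, origin, "M")
  m <- merge(as.data.frame(calls), as.data.frame(sim$truth$records), by = "sample_id")
  expect_equal(mean(m$composition.x == m$composition.y), 1)
  expect_false(any(calls$discordant))

  cfg1 <- small_cross(
    "XY",
    seed = 76, n_f2 = 200, n_markers = 2700, n_chromosomes = 6,
    genotype_error_rate = 0.01, no_recomb_window_cM = 10
  )
  sim1 <- simulate_cross(cfg1)
  gt1 <- polarize_to_grandmother(mask_low_depth(sim1$gt, 10), sim1$ped)
  ydiag1 <- select_sex_linked_sites(gt1, sim1$ped, "M", "pedigree", chrom = "chr2")
  origin1 <- select_f0_diagnostic_sites(gt1, sim1$ped, require_f1_het = TRUE)
  origin1 <- origin1[gt1$markers$chrom[origin1] == "chr2"]
  calls1 <- assign_composition(gt1, sim1$ped, ydiag1, origin1, "M")
  m1 <- merge(as.data.frame(calls1), as.data.frame(sim1$truth$records), by = "sample_id")
  expect_gte(mean(m1$composition.x == m1$composition.y, na.rm = TRUE), 0.95)
})

test_that("composition summary corrects for sex ratio and detects deficits", {
  calls <- tibble::tibble(
    composition = c(rep("Z_A Z_B", 10), rep("Z_B Z_B", 30), rep("Z_B W_A", 40)),
    sex = c(rep("M", 40), rep("F", 40)),
    unresolved = FALSE
  )
  expected <- c("Z_A Z_B" = 0.25, "Z_B Z_B" = 0.25, "Z_B W_A" = 0.5)
  s <- composition_summary(calls, expected)
  expect_equal(sum(s$frac_corrected), 1)
  expect_equal(s$frac_corrected[s$composition == "Z_B W_A"], 0.5)
  # the 10/80 class against expectation 0.25 is a clear deficit
  expect_lt(s$p_deficit[s$composition == "Z_A Z_B"], 0.05)
  expect_error(composition_summary(calls[0, ]), "no resolved")
})

test_that("viability-depleted compositions are flagged in most simulations", {
  hits <- 0
  runs <- 20
  for (seed in seq_len(runs)) {
    cfg <- small_cross(
      "XY",
      seed = 500 + seed, n_f2 = 150, n_markers = 2700,
      n_chromosomes = 6, no_recomb_window_cM = 10,
      viability = list("X_A X_B|M" = 0.2, "X_A X_B|F" = 0.2)
    )
    sim <- simulate_cross(cfg)
    gt <- polarize_to_grandmother(mask_low_depth(sim$gt, 10), sim$ped)
    ydiag <- select_sex_linked_sites(gt, sim$ped, "M", "pedigree", chrom = "chr2")
    origin <- select_f0_diagnostic_sites(gt, sim$ped, require_f1_het = TRUE)
    origin <- origin[gt$markers$chrom[origin] == "chr2"]
    if (length(ydiag) == 0 || length(origin) == 0) next
    calls <- assign_composition(gt, sim$ped, ydiag, origin, "M")
    # F1 parents are X_A X_B x X_A Y_B, so the four offspring classes are
    # equally likely without selection
    expected <- c(
      "X_A X_A" = 0.25, "X_A X_B" = 0.25, "X_A Y_B" = 0.25, "X_B Y_B" = 0.25
    )
    s <- composition_summary(calls, expected)
    p <- s$p_deficit[s$composition == "X_A X_B"]
    hits <- hits + (length(p) == 1 && !is.na(p) && p < 0.05)
  }
  expect_gte(hits / runs, 0.8)
})

test_that("genotype matrix export round-trips through the text file", {
  sim <- simulate_cross(small_cross(seed = 78, n_f2 = 10, n_markers = 100))
  gt <- polarize_to_grandmother(sim$gt, sim$ped)
  sites <- 1:6
  path <- withr::local_tempfile(fileext = ".tsv")
  p <- export_genotype_matrix_plot(gt, sim$ped, sites, path)
  expect_s3_class(p, "ggplot")
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(back), 10)
  f2 <- sim$ped$sample_id[sim$ped$generation == "F2"]
  mat <- as.matrix(back[, -1])
  rownames(mat) <- back$sample_id
  for (s in f2) {
    expect_equal(
      unname(mat[s, ]),
      unname(gt$geno[sites, s])
    )
  }
})
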