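test_that("low-depth masking is strict at the boundary", {
  gt <- toy_gt(
    matrix(c(0L, 1L, 2L, 1L), 2, 2),
    depth = matrix(c(9, 10, 30, 2), 2, 2)
  )
  out <- mask_low_depth(gt, 10)
  expect_equal(unname(out$geno[, 1]), c(NA_integer_, 1L)) # depth 9 -> NA, 10 kept
  expect_equal(unname(out$geno[, 2]), c(2L, NA_integer_))
  expect_identical(mask_low_depth(gt, 10)$depth, gt$depth)
  expect_error(mask_low_depth(toy_gt(matrix(0L, 1, 1)), 10), "no depth")
})

test_that("masking agrees with elementwise brute force on random tables", {
  set.seed(42)
  for (rep in 1:20) {
    g <- matrix(sample(c(0:2, NA), 30, replace = TRUE), 6, 5)
    d <- matrix(rpois(30, 12), 6, 5)
    out <- mask_low_depth(toy_gt(g, d), 10)
    brute <- g
    for (i in 1:6) {
      for (j in 1:5) if (d[i, j] < 10) brute[i, j] <- NA
    }
    expect_equal(unname(out$geno), unname(brute))
  }
})

test_that("site and individual cascade follows the documented order", {
  # site with 3/4 missing removed; individual mean depth below 12 removed
  g <- matrix(1L, 4, 4)
  g[1, 1:3] <- NA
  d <- matrix(20, 4, 4)
  d[, 2] <- 11.9
  gt <- toy_gt(g, d)
  cfg <- filter_config(maf_min = 0)
  out <- filter_sites_individuals(gt, cfg)
  expect_equal(nrow(out$geno), 3) # high-missing site dropped
  expect_false("S02" %in% out$samples) # mean depth 11.9 < 12 dropped
})

test_that("the cascade matches an independent brute-force filter", {
  brute <- function(g, d, cfg) {
    keep_s <- rowMeans(is.na(g)) <= cfg$site_max_missing
    g <- g[keep_s, , drop = FALSE]
    d <- d[keep_s, , drop = FALSE]
    keep_i <- colMeans(d, na.rm = TRUE) >= cfg$ind_min_mean_depth &
      colMeans(is.na(g)) <= cfg$ind_max_missing
    g <- g[, keep_i, drop = FALSE]
    d <- d[, keep_i, drop = FALSE]
    keep_s2 <- rowMeans(is.na(g)) <= cfg$site_max_missing
    g <- g[keep_s2, , drop = FALSE]
    af <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
    maf <- pmin(af, 1 - af)
    keep_s3 <- !is.na(maf) & maf >= cfg$maf_min
    list(
      sites = rownames(g)[keep_s3],
      samples = colnames(g)
    )
  }
  set.seed(7)
  cfg <- filter_config()
  for (rep in 1:25) {
    g <- matrix(sample(c(0:2, NA),
      prob = c(rep(0.4, 3), 0.35),
      400,
      replace = TRUE
    ), 20, 20)
    d <- matrix(rnbinom(400, mu = 14, size = 4), 20, 20)
    gt <- toy_gt(g, d)
    expected <- brute(gt$geno, gt$depth, cfg)
    got <- tryCatch(filter_sites_individuals(gt, cfg), error = function(e) NULL)
    if (is.null(got)) {
      expect_true(length(expected$sites) == 0 || length(expected$samples) == 0)
    } else {
      expect_equal(got$markers$marker_id, expected$sites)
      expect_equal(got$samples, expected$samples)
    }
  }
})

test_that("the missingness/depth/MAF cascade is idempotent", {
  sim <- simulate_cross(small_cross(seed = 13, n_f2 = 40, n_markers = 400))
  once <- filter_sites_individuals(mask_low_depth(sim$gt, 10))
  twice <- filter_sites_individuals(mask_low_depth(once, 10))
  expect_identical(twice$geno, once$geno)
  expect_identical(twice$samples, once$samples)
})

test_that("depth-IQR filter removes outlying sites and honours edge cases", {
  d <- matrix(20, 10, 4)
  d[3, ] <- 200
  g <- matrix(1L, 10, 4)
  out <- depth_iqr_site_filter(toy_gt(g, d), 1.5)
  expect_equal(nrow(out$geno), 9)
  expect_false("chr1_3000" %in% out$markers$marker_id)
  # all equal depths: IQR 0 but every site equals the mean, none above bound
  all_eq <- depth_iqr_site_filter(toy_gt(g, matrix(20, 10, 4)), 1.5)
  expect_equal(nrow(all_eq$geno), 10)
  expect_equal(nrow(depth_iqr_site_filter(toy_gt(g, d), Inf)$geno), 10)
  expect_warning(
    depth_iqr_site_filter(toy_gt(g[1:3, ], d[1:3, ]), 1.5),
    "fewer than 4"
  )
})

test_that("MAF boundary is inclusive at the threshold", {
  # 100 alleles: 5 alt -> MAF exactly 0.05 kept; 4 alt -> removed
  g_keep <- matrix(c(rep(0L, 45), rep(1L, 5)), 1, 50)
  g_drop <- matrix(c(rep(0L, 46), rep(1L, 4)), 1, 50)
  expect_equal(nrow(maf_filter(toy_gt(g_keep), 0.05)$geno), 1)
  expect_equal(nrow(maf_filter(toy_gt(g_drop), 0.05)$geno), 0)
})

test_that("exact HWE test matches direct enumeration of the conditional law", {
  # independent oracle: enumerate heterozygote counts conditional on allele
  # counts with the standard combinatorial probability
  hwe_oracle <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    na <- 2 * n_aa + n_ab
    hets <- seq(min(na, 2 * n - na) %% 2, min(na, 2 * n - na), by = 2)
    pr <- vapply(hets, function(h) {
      naa <- (na - h) / 2
      nbb <- n - naa - h
      exp(
        lchoose(n, naa) + lchoose(n - naa, h) + h * log(2) -
          lchoose(2 * n, na)
      )
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(n_ab, hets)] + 1e-12])
  }
  set.seed(11)
  for (rep in 1:50) {
    counts <- as.vector(stats::rmultinom(1, sample(10:60, 1), c(0.3, 0.45, 0.25)))
    expect_equal(
      hwe_exact_test(counts[1], counts[2], counts[3]),
      hwe_oracle(counts[1], counts[2], counts[3]),
      tolerance = 1e-10
    )
  }
  # a site where all 20 F2 are heterozygous is strongly out of HWE
  expect_lt(hwe_exact_test(0, 20, 0), 0.1)
  # balanced HWE proportions are retained
  expect_gt(hwe_exact_test(5, 10, 5), 0.1)
})

test_that("HWE filter works within F2 only", {
  g <- rbind(
    c(0L, 2L, rep(1L, 20)), # F0s + all-het F2: removed
    c(0L, 2L, rep(c(0L, 1L, 1L, 2L), 5)) # balanced: kept
  )
  samples <- c("F0_GM", "F0_GF", sprintf("F2_%02d", 1:20))
  ped <- tibble::tibble(
    sample_id = samples,
    generation = c("F0", "F0", rep("F2", 20)),
    family = "A", sex = c("F", "M", rep(c("M", "F"), 10)),
    species = NA_character_
  )
  out <- hwe_filter(toy_gt(g, samples = samples), ped, 0.1)
  expect_equal(nrow(out$geno), 1)
})

test_that("diagnostic-site selection equals a brute-force scan", {
  sim <- simulate_cross(small_cross(
    seed = 19, n_f2 = 30, n_markers = 300,
    missing_rate = 0.05
  ))
  gt <- polarize_to_grandmother(sim$gt, sim$ped)
  got <- select_f0_diagnostic_sites(gt, sim$ped, require_f1_het = TRUE)
  f0 <- c("F0_GM", "F0_GF")
  f1 <- grep("^F1_", gt$samples, value = TRUE)
  brute <- which(vapply(seq_len(nrow(gt$geno)), function(i) {
    a <- gt$geno[i, f0[1]]
    b <- gt$geno[i, f0[2]]
    f1g <- gt$geno[i, f1]
    !is.na(a) && !is.na(b) && abs(a - b) == 2L &&
      !anyNA(f1g) && all(f1g == 1L)
  }, logical(1)))
  expect_equal(got, brute)
  expect_error(
    select_f0_diagnostic_sites(gt, sim$ped[sim$ped$generation == "F2", ]),
    "F0"
  )
})

test_that("surrogate-mode diagnostic selection contrasts the two species", {
  g <- rbind(
    c(0L, 0L, 2L, 2L), # species A hom-ref, B hom-alt: selected
    c(2L, 2L, 0L, 0L), # reversed orientation: selected
    c(0L, 1L, 2L, 2L), # het in one surrogate: rejected
    c(0L, 0L, 0L, 0L) # no contrast: rejected
  )
  samples <- c("SA1", "SA2", "SB1", "SB2")
  ped <- tibble::tibble(
    sample_id = samples, generation = "species_surrogate",
    family = "*", sex = c("M", "F", "M", "F"),
    species = c("A", "A", "B", "B")
  )
  got <- select_f0_diagnostic_sites(
    toy_gt(g, samples = samples), ped,
    mode = "species_surrogate"
  )
  expect_equal(got, c(1L, 2L))
})

test_that("sex-averaged allele-frequency band recognises double-het-F1 sites", {
  # af 0.5 in both sexes kept; af 0.3/0.7 averages to 0.5 kept; af 0.2 dropped
  males <- c(
    rep(0L, 2), rep(1L, 6), rep(2L, 2), # af 0.5
    rep(0L, 10)
  )
  g <- rbind(
    c(rep(0L, 2), rep(1L, 6), rep(2L, 2), rep(0L, 4), rep(1L, 4), rep(2L, 2)), # 0.5 / 0.4
    c(rep(0L, 4), rep(1L, 6), rep(2L, 0), rep(2L, 4), rep(1L, 6)), # 0.3 / 0.7
    c(rep(0L, 8), rep(1L, 2), rep(0L, 8), rep(1L, 2)), # 0.1 / 0.1
    c(rep(1L, 10), rep(1L, 10)) # af 0.5 but 100% het: paralog-filtered
  )
  samples <- sprintf("F2_%02d", 1:20)
  ped <- toy_f2_ped(samples, rep(c("M", "F"), each = 10))
  got <- infer_f1_het_sites_by_af(toy_gt(g, samples = samples), ped)
  expect_equal(got, c(1L, 2L))
  expect_error(
    infer_f1_het_sites_by_af(
      toy_gt(g, samples = samples),
      toy_f2_ped(samples, rep("M", 20))
    ),
    "both sexes"
  )
})

test_that("F1-het sites are recovered with high sensitivity from a cross", {
  sim <- simulate_cross(small_cross(
    seed = 23, n_f2 = 100, n_markers = 1000, depth_mean = 20
  ))
  gt <- polarize_to_grandmother(mask_low_depth(sim$gt, 10), sim$ped)
  got <- infer_f1_het_sites_by_af(gt, sim$ped)
  truth <- which(gt$markers$marker_id %in% sim$truth$diagnostic_sites)
  sensitivity <- mean(truth %in% got)
  expect_gt(sensitivity, 0.9)
})

test_that("swapping founder labels maps genotype g to 2 - g", {
  sim <- simulate_cross(small_cross(seed = 29, n_f2 = 20, n_markers = 200))
  ped_swapped <- sim$ped
  i_gm <- ped_swapped$sample_id == "F0_GM"
  i_gf <- ped_swapped$sample_id == "F0_GF"
  ped_swapped$sex[i_gm] <- "M"
  ped_swapped$sex[i_gf] <- "F"
  ped_swapped$species[i_gm] <- "B"
  ped_swapped$species[i_gf] <- "A"
  orig <- polarize_to_grandmother(sim$gt, sim$ped)
  swapped <- polarize_to_grandmother(sim$gt, ped_swapped)
  # at sites where either founder is an unambiguous homozygote the codes flip
  informative <- !is.na(sim$gt$geno[, "F0_GM"]) & !is.na(sim$gt$geno[, "F0_GF"]) &
    abs(sim$gt$geno[, "F0_GM"] - sim$gt$geno[, "F0_GF"]) == 2L
  expect_equal(
    unname(swapped$geno[informative, ]),
    unname(2L - orig$geno[informative, ])
  )
})

test_that("allelic-balance correction recodes only skewed founder hets", {
  g <- matrix(c(1L, 1L, 0L, 1L), 2, 2)
  samples <- c("F0_GM", "F0_GF")
  ped <- tibble::tibble(
    sample_id = samples, generation = "F0", family = "*",
    sex = c("F", "M"), species = c("A", "B")
  )
  minor <- matrix(c(0.1, 0.4, 0.5, 0.05), 2, 2)
  major <- matrix(c(0L, 0L, 0L, 2L), 2, 2)
  out <- correct_f0_allelic_balance(
    toy_gt(g, samples = samples), ped, minor, major
  )
  expect_equal(unname(out$geno[, 1]), c(0L, 1L)) # skewed het recoded
  expect_equal(unname(out$geno[, 2]), c(0L, 2L)) # skew in GF recoded to ALT hom
})
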