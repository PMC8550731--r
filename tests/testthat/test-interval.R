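# Exact 3-state chain posterior for a single individual by enumeration, the
# independent oracle for the HMM smoother.
enumerate_posterior <- function(obs, r_steps, error_rate) {
  n <- length(obs)
  states <- 0:2
  prior <- c(0.25, 0.5, 0.25)
  trans <- function(r) {
    matrix(c(
      (1 - r)^2, 2 * r * (1 - r), r^2,
      r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
      r^2, 2 * r * (1 - r), (1 - r)^2
    ), 3, 3, byrow = TRUE)
  }
  emit <- function(o, s) {
    if (is.na(o)) 1 else if (o == s) 1 - error_rate else error_rate / 2
  }
  paths <- expand.grid(rep(list(states), n))
  w <- apply(paths, 1, function(pth) {
    p <- prior[pth[1] + 1] * emit(obs[1], pth[1])
    for (t in 2:n) {
      p <- p * trans(r_steps[t - 1])[pth[t - 1] + 1, pth[t] + 1] *
        emit(obs[t], pth[t])
    }
    p
  })
  post <- matrix(0, n, 3)
  for (t in 1:n) {
    for (s in states) post[t, s + 1] <- sum(w[paths[[t]] == s])
  }
  post / rowSums(post)
}

# genotype table + map for hand-placed markers on one chromosome
chain_fixture <- function(geno_row, cm, sexes = NULL) {
  n_ind <- ncol(geno_row)
  samples <- sprintf("I%02d", seq_len(n_ind))
  if (is.null(sexes)) sexes <- rep(c("M", "F"), length.out = n_ind)
  gt <- toy_gt(geno_row, bp = round(cm * 1e5) + 1, samples = samples)
  map <- tibble::tibble(
    chrom = "chr1", marker_id = gt$markers$marker_id,
    bp = gt$markers$bp, cM = cm
  )
  list(gt = gt, map = map, ped = toy_f2_ped(samples, sexes))
}

test_that("posterior probabilities sum to 1 and recover observed states at zero error", {
  fx <- chain_fixture(
    matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3),
    cm = c(0, 7, 13)
  )
  pr <- conditional_genotype_probs(fx$gt, fx$map, fx$ped, error_rate = 0)
  probs <- pr$chroms[["chr1"]]$prob
  sums <- apply(probs, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  pos <- pr$chroms[["chr1"]]$positions
  mk <- which(!pos$is_pseudomarker)
  for (i in 1:2) {
    for (t in seq_along(mk)) {
      obs <- fx$gt$geno[t, i]
      expect_equal(probs[mk[t], i, obs + 1], 1, tolerance = 1e-9)
    }
  }
})

test_that("HMM posteriors match exact enumeration on short chains", {
  set.seed(77)
  for (rep in 1:15) {
    n_mark <- sample(3:5, 1)
    cm <- sort(runif(n_mark, 0, 40))
    obs <- sample(c(0:2, NA), n_mark, replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
    fx <- chain_fixture(matrix(obs, ncol = 1), cm = cm, sexes = "M")
    pr <- conditional_genotype_probs(
      fx$gt, fx$map, fx$ped,
      step_cm = 1000, # marker positions only
      error_rate = 0.05
    )
    got <- pr$chroms[["chr1"]]$prob[, 1, ]
    pos <- pr$chroms[["chr1"]]$positions
    got <- got[!pos$is_pseudomarker, , drop = FALSE]
    r_steps <- recomb_fraction(diff(cm), "kosambi")
    expected <- enumerate_posterior(obs, r_steps, 0.05)
    expect_equal(unname(got), expected, tolerance = 1e-9)
  }
})

test_that("a missing marker between identical homozygote neighbours is imputed", {
  fx <- chain_fixture(
    matrix(c(2L, NA, 2L), nrow = 3),
    cm = c(0, 1, 2), sexes = "F"
  )
  pr <- conditional_genotype_probs(fx$gt, fx$map, fx$ped, error_rate = 0)
  pos <- pr$chroms[["chr1"]]$positions
  mid <- which(!pos$is_pseudomarker)[2]
  expect_gt(pr$chroms[["chr1"]]$prob[mid, 1, 3], 0.99)
})

test_that("interval scan agrees with the marker-level binary fit at informative markers", {
  sim <- simulate_cross(small_cross(
    seed = 61, n_f2 = 100, n_markers = 200,
    missing_rate = 0, genotype_error_rate = 0
  ))
  gt <- polarize_to_grandmother(sim$gt, sim$ped)
  diag_sites <- select_f0_diagnostic_sites(gt, sim$ped)
  gt_d <- gt_subset(gt, sites = diag_sites)
  pr <- conditional_genotype_probs(gt_d, sim$map, sim$ped, error_rate = 1e-6)
  sc <- interval_scan_binary(pr)
  # direct binomial-likelihood fit on the observed genotypes
  f2 <- sim$ped[sim$ped$generation == "F2", ]
  ids <- pr$samples
  y <- as.integer(f2$sex[match(ids, f2$sample_id)] == "F")
  direct_lod <- function(g, y) {
    ok <- !is.na(g)
    g <- g[ok]
    yy <- y[ok]
    p0 <- mean(yy)
    ll0 <- sum(yy * log(p0) + (1 - yy) * log(1 - p0))
    ll1 <- 0
    for (cl in unique(g)) {
      yk <- yy[g == cl]
      pk <- min(max(mean(yk), 1e-6), 1 - 1e-6)
      ll1 <- ll1 + sum(yk * log(pk) + (1 - yk) * log(1 - pk))
    }
    (ll1 - ll0) / log(10)
  }
  mk_rows <- sc[!sc$is_pseudomarker, ]
  probe <- sample(nrow(mk_rows), 25)
  for (i in probe) {
    site <- match(mk_rows$bp[i], gt_d$markers$bp[gt_d$markers$chrom == mk_rows$chrom[i]])
    g_site <- gt_d$geno[
      gt_d$markers$chrom == mk_rows$chrom[i] & gt_d$markers$bp == mk_rows$bp[i],
      match(ids, gt_d$samples)
    ]
    expect_equal(mk_rows$lod[i], direct_lod(g_site, y), tolerance = 1e-3)
  }
})

test_that("a genotype column independent of sex scans to LOD near 0", {
  set.seed(5)
  g <- matrix(sample(0:2, 60, replace = TRUE, prob = c(.25, .5, .25)), nrow = 1)
  fx <- chain_fixture(g, cm = 10)
  pr <- conditional_genotype_probs(fx$gt, fx$map, fx$ped)
  sc <- interval_scan_binary(pr)
  expect_lt(max(sc$lod), 1.5)
})

test_that("permutation thresholds are monotone, reproducible and calibrated", {
  sim <- simulate_cross(small_cross(
    seed = 63, n_f2 = 60, n_markers = 120,
    n_chromosomes = 2, sd_system = "none"
  ))
  gt <- polarize_to_grandmother(
    filter_sites_individuals(mask_low_depth(sim$gt, 10)), sim$ped
  )
  pr <- conditional_genotype_probs(gt, sim$map, sim$ped)
  th <- permutation_threshold(pr, n_perm = 150, seed = 3)
  expect_gte(th$threshold[th$alpha == 0.05], th$threshold[th$alpha == 0.1])
  th2 <- permutation_threshold(pr, n_perm = 150, seed = 3)
  expect_identical(th, th2)
  # calibration: the fraction of null scans whose maximum exceeds the 0.05
  # threshold should be near 5% (binomial tolerance over the replicates)
  max_lods <- attr(th, "max_lods")
  exceed <- mean(max_lods > th$threshold[th$alpha == 0.05])
  expect_lte(exceed, 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("no-association scans rarely exceed the permutation threshold", {
  hits <- 0
  runs <- 25
  for (seed in seq_len(runs)) {
    sim <- simulate_cross(small_cross(
      seed = 300 + seed, n_f2 = 60, n_markers = 100,
      n_chromosomes = 2, sd_system = "none"
    ))
    gt <- polarize_to_grandmother(
      filter_sites_individuals(mask_low_depth(sim$gt, 10)), sim$ped
    )
    pr <- conditional_genotype_probs(gt, sim$map, sim$ped)
    sc <- interval_scan_binary(pr)
    th <- permutation_threshold(pr, n_perm = 100, seed = seed)
    hits <- hits + (max(sc$lod) <= th$threshold[th$alpha == 0.05])
  }
  expect_gte(hits / runs, 0.8)
})

test_that("determiner simulations put the interval-scan peak on the true chromosome", {
  for (seed in 1:5) {
    sim <- simulate_cross(small_cross("XY", seed = 400 + seed, n_f2 = 150))
    gt <- polarize_to_grandmother(
      filter_sites_individuals(mask_low_depth(sim$gt, 10)), sim$ped
    )
    diag_sites <- select_f0_diagnostic_sites(gt, sim$ped)
    pr <- conditional_genotype_probs(
      gt_subset(gt, sites = diag_sites), sim$map, sim$ped
    )
    sc <- interval_scan_binary(pr)
    expect_equal(sc$chrom[which.max(sc$lod)], "chr2")
  }
})

test_that("credible intervals concentrate on sharp peaks and widen on flat ones", {
  pos <- tibble::tibble(
    chrom = "chr1", cM = 0:50, bp = (0:50) * 1e5,
    is_pseudomarker = FALSE
  )
  sharp <- dplyr::mutate(pos, lod = ifelse(cM == 25, 20, 0))
  ci <- bayes_interval(sharp)
  expect_lte(ci$cM_hi - ci$cM_lo, 2)
  expect_true(ci$cM_lo <= 25 && ci$cM_hi >= 25)
  flat <- dplyr::mutate(pos, lod = 1)
  ci_flat <- bayes_interval(flat)
  expect_gte(ci_flat$cM_hi - ci_flat$cM_lo, 45)
})

test_that("two-peak credible interval matches direct mass summation", {
  pos <- tibble::tibble(
    chrom = "chr1", cM = 0:20, bp = (0:20) * 1e5, is_pseudomarker = FALSE,
    lod = c(rep(0, 5), 5, 6, 5, rep(0, 5), 4, 5.5, 4, rep(0, 5))
  )
  ci <- bayes_interval(pos, coverage = 0.95)
  # oracle: greedy contiguous expansion from the peak over normalized 10^lod
  w <- 10^(pos$lod - max(pos$lod))
  w <- w / sum(w)
  lo <- hi <- which.max(w)
  mass <- w[lo]
  while (mass < 0.95) {
    wl <- if (lo > 1) w[lo - 1] else -Inf
    wr <- if (hi < length(w)) w[hi + 1] else -Inf
    if (wl >= wr) {
      lo <- lo - 1
      mass <- mass + w[lo]
    } else {
      hi <- hi + 1
      mass <- mass + w[hi]
    }
  }
  expect_equal(ci$cM_lo, pos$cM[lo])
  expect_equal(ci$cM_hi, pos$cM[hi])
  expect_gte(ci$coverage_achieved, 0.95)
})
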