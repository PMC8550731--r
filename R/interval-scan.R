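# F2 intercross dosage-state transition matrix for recombination fraction r
f2_transition <- function(r) {
  matrix(c(
    (1 - r)^2, 2 * r * (1 - r), r^2,
    r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
    r^2, 2 * r * (1 - r), (1 - r)^2
  ), nrow = 3, byrow = TRUE)
}

#' Conditional genotype probabilities along the genome
#'
#' Hidden-Markov forward-backward smoothing of F2 intercross genotypes over
#' each chromosome: hidden states are the true dosages 0/1/2 with prior
#' (1/4, 1/2, 1/4), transitions follow the map function's recombination
#' fraction over the inter-position distance, and observed genotypes are
#' emitted with a symmetric error rate (`1 - error_rate` on the true state,
#' `error_rate / 2` on each other state; missing genotypes are
#' uninformative). Probabilities are computed at every marker and on a
#' pseudomarker grid with fixed `step_cm` spacing.
#'
#' @param gt A [geno_table()] (grandmother-polarized F2 codes).
#' @param map Tibble with `marker_id`, `chrom`, `bp`, `cM` covering the
#'   markers of `gt`.
#' @param ped Pedigree tibble; probabilities are computed for sexed F2.
#' @param step_cm Pseudomarker grid spacing in cM.
#' @param error_rate Assumed genotyping error rate.
#' @param map_function `"kosambi"` or `"haldane"`.
#' @param family Restrict to one family, or `NULL`.
#' @return An object of class `geno_prob`: per chromosome, a `positions`
#'   tibble (`chrom`, `cM`, `bp`, `is_pseudomarker`) and a `prob` array
#'   (positions x individuals x 3 states); plus `samples` and `sex`.
#' @export
conditional_genotype_probs <- function(gt, map, ped, step_cm = 1,
                                       error_rate = 0.05,
                                       map_function = c("kosambi", "haldane"),
                                       family = NULL) {
  stopifnot(inherits(gt, "geno_table"))
  map_function <- match.arg(map_function)
  f2 <- ped[ped$generation == "F2" & ped$sex %in% c("M", "F"), , drop = FALSE]
  if (!is.null(family)) f2 <- f2[f2$family == family, , drop = FALSE]
  ids <- intersect(f2$sample_id, gt$samples)
  sex <- f2$sex[match(ids, f2$sample_id)]
  mk <- dplyr::inner_join(
    gt$markers[, c("marker_id", "chrom", "bp")],
    map[, c("marker_id", "cM")],
    by = "marker_id"
  )
  if (nrow(mk) == 0) stop("no genotype markers found in map")
  g_all <- gt$geno[match(mk$marker_id, gt$markers$marker_id),
    match(ids, gt$samples),
    drop = FALSE
  ]
  n_ind <- length(ids)
  prior <- c(0.25, 0.5, 0.25)

  chroms <- list()
  for (ch in unique(mk$chrom)) {
    rows <- which(mk$chrom == ch)
    ord <- rows[order(mk$cM[rows])]
    cm_mark <- mk$cM[ord]
    if (is.unsorted(cm_mark)) stop("non-monotone map on ", ch)
    grid <- seq(min(cm_mark), max(cm_mark), by = step_cm)
    cm_all <- sort(unique(round(c(cm_mark, grid), 8)))
    is_marker <- cm_all %in% round(cm_mark, 8)
    n_pos <- length(cm_all)
    marker_at <- match(round(cm_mark, 8), cm_all)

    # emission array: n_pos x n_ind x 3 (1 where no marker / missing)
    E <- array(1, dim = c(n_pos, n_ind, 3))
    g_ch <- g_all[ord, , drop = FALSE]
    for (s in 0:2) {
      em <- matrix(error_rate / 2, n_pos, n_ind)
      em[marker_at, ][g_ch == s] <- 1 - error_rate
      em[marker_at, ][is.na(g_ch)] <- 1
      keep <- rep(TRUE, n_pos)
      keep[marker_at] <- FALSE
      em[keep, ] <- 1
      E[, , s + 1] <- em
    }

    r_step <- recomb_fraction(diff(cm_all), map_function)
    Ts <- lapply(r_step, f2_transition)

    alpha <- array(0, dim = c(n_pos, n_ind, 3))
    a <- matrix(prior, n_ind, 3, byrow = TRUE) * E[1, , , drop = TRUE]
    a <- matrix(a, n_ind, 3)
    a <- a / rowSums(a)
    alpha[1, , ] <- a
    for (t in 2:n_pos) {
      if (n_pos < 2) break
      a <- (a %*% Ts[[t - 1]]) * matrix(E[t, , ], n_ind, 3)
      a <- a / rowSums(a)
      alpha[t, , ] <- a
    }
    beta <- array(0, dim = c(n_pos, n_ind, 3))
    b <- matrix(1, n_ind, 3)
    beta[n_pos, , ] <- b
    if (n_pos >= 2) {
      for (t in (n_pos - 1):1) {
        b <- (b * matrix(E[t + 1, , ], n_ind, 3)) %*% t(Ts[[t]])
        b <- b / rowSums(b)
        beta[t, , ] <- b
      }
    }
    post <- alpha * beta
    norm <- apply(post, c(1, 2), sum)
    for (s in 1:3) post[, , s] <- post[, , s] / norm

    bp_at <- rep(NA_real_, n_pos)
    bp_at[marker_at] <- mk$bp[ord]
    if (sum(is_marker) >= 2) {
      bp_at <- stats::approx(cm_all[is_marker], bp_at[marker_at],
        xout = cm_all, rule = 2
      )$y
    } else {
      bp_at <- rep(mk$bp[ord][1], n_pos)
    }
    chroms[[ch]] <- list(
      positions = tibble::tibble(
        chrom = ch, cM = cm_all, bp = bp_at, is_pseudomarker = !is_marker
      ),
      prob = post
    )
  }
  structure(
    list(chroms = chroms, samples = ids, sex = sex),
    class = "geno_prob"
  )
}

# Vectorised EM fit of the single-QTL binary model at every position of a
# probability array (n_pos x n x 3). Returns list(lod, separation).
binary_scan_em <- function(P, y, max_iter = 30, tol = 1e-8) {
  n_pos <- dim(P)[1]
  n <- dim(P)[2]
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  # initialise at the probability-weighted class means
  pg <- sapply(1:3, function(g) {
    Pm <- matrix(P[, , g], n_pos, n)
    as.vector(Pm %*% y) / pmax(rowSums(Pm), 1e-12)
  })
  pg <- clamp(matrix(pg, n_pos, 3))
  ll <- rep(-Inf, n_pos)
  for (it in seq_len(max_iter)) {
    M <- array(0, dim = dim(P))
    for (g in 1:3) {
      f <- outer(pg[, g], y) + outer(1 - pg[, g], 1 - y)
      M[, , g] <- matrix(P[, , g], n_pos, n) * f
    }
    denom <- M[, , 1] + M[, , 2] + M[, , 3]
    denom <- matrix(denom, n_pos, n)
    ll_new <- rowSums(log(pmax(denom, 1e-300)))
    pg_new <- pg
    for (g in 1:3) {
      W <- matrix(M[, , g], n_pos, n) / denom
      sw <- rowSums(W)
      pg_new[, g] <- ifelse(sw > 1e-12, as.vector(W %*% y) / sw, pg[, g])
    }
    pg_new <- clamp(pg_new)
    delta <- max(abs(pg_new - pg))
    pg <- pg_new
    ll <- ll_new
    if (delta < tol) break
  }
  lod <- (ll - ll0) / log(10)
  lod <- pmax(lod, 0)
  separation <- apply(pg <= 1e-6 | pg >= 1 - 1e-6, 1, any)
  list(lod = lod, separation = separation)
}

#' Interval mapping of a binary trait
#'
#' Standard single-QTL interval mapping with the binary model: at every
#' marker and pseudomarker position, the penetrance of each genotype class
#' is fitted by maximum likelihood (EM over the conditional genotype
#' probabilities) and compared with the null model of a common penetrance;
#' LOD is the log10 likelihood ratio. At a fully informative marker this
#' reduces to the marker-level binary fit. Positions where a fitted class
#' penetrance hits the boundary (complete separation) are flagged and their
#' LOD reflects the clamped fit.
#'
#' @param probs A `geno_prob` from [conditional_genotype_probs()].
#' @param sex Optional response; defaults to the sexes carried by `probs`
#'   (F = 1).
#' @return A tibble of class `sexqtl_scan`: `chrom`, `cM`, `bp`,
#'   `is_pseudomarker`, `lod`, `pve`, `n`, `separation`.
#' @export
interval_scan_binary <- function(probs, sex = NULL) {
  stopifnot(inherits(probs, "geno_prob"))
  y <- if (is.null(sex)) {
    as.integer(probs$sex == "F")
  } else if (is.character(sex) || is.factor(sex)) {
    as.integer(as.character(sex) == "F")
  } else {
    as.integer(sex)
  }
  n <- length(y)
  out <- purrr::map_dfr(probs$chroms, function(chp) {
    fit <- binary_scan_em(chp$prob, y)
    dplyr::mutate(chp$positions,
      lod = fit$lod, pve = pve_from_lod(fit$lod, n),
      n = n, separation = fit$separation
    )
  })
  class(out) <- c("sexqtl_scan", class(out))
  out
}

#' Genome-wide LOD significance thresholds by permutation
#'
#' Permutes the binary response, reruns the interval scan, and records the
#' genome-wide maximum LOD of each replicate; thresholds are the `1 - alpha`
#' quantiles of that null distribution.
#'
#' @param probs A `geno_prob`.
#' @param n_perm Number of permutations.
#' @param alphas Genome-wide significance levels.
#' @param seed RNG seed.
#' @return A tibble: `alpha`, `threshold`; with attribute `max_lods` (the
#'   null maxima).
#' @export
permutation_threshold <- function(probs, n_perm = 1000,
                                  alphas = c(0.05, 0.1), seed = 1L) {
  stopifnot(inherits(probs, "geno_prob"))
  y <- as.integer(probs$sex == "F")
  set.seed(seed)
  max_lods <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    max(vapply(
      probs$chroms,
      function(chp) max(binary_scan_em(chp$prob, yp)$lod),
      numeric(1)
    ))
  }, numeric(1))
  out <- tibble::tibble(
    alpha = alphas,
    threshold = as.numeric(stats::quantile(max_lods, 1 - alphas))
  )
  attr(out, "max_lods") <- max_lods
  out
}

#' Bayesian credible interval for a QTL peak
#'
#' Normalizes `10^LOD` over the scan positions of one chromosome as an
#' approximate posterior, grows the smallest contiguous span containing the
#' peak until it holds at least `coverage` of the mass, and expands the
#' endpoints outward to the flanking true markers (pseudomarker endpoints
#' are widened to the nearest genotyped marker).
#'
#' @param scan A `sexqtl_scan` from [interval_scan_binary()] (needs `cM` and
#'   `is_pseudomarker`).
#' @param chrom Chromosome to summarise; defaults to the peak chromosome.
#' @param coverage Posterior mass to cover.
#' @return A one-row tibble: `chrom`, `cM_lo`, `cM_hi`, `bp_lo`, `bp_hi`,
#'   `coverage_achieved`.
#' @export
bayes_interval <- function(scan, chrom = NULL, coverage = 0.95) {
  stopifnot(all(c("chrom", "cM", "lod") %in% names(scan)))
  if (is.null(chrom)) chrom <- scan$chrom[which.max(scan$lod)]
  d <- scan[scan$chrom == chrom, , drop = FALSE]
  d <- d[order(d$cM), , drop = FALSE]
  w <- 10^(d$lod - max(d$lod))
  w <- w / sum(w)
  peak <- which.max(w)
  lo <- hi <- peak
  mass <- w[peak]
  while (mass < coverage && (lo > 1 || hi < nrow(d))) {
    w_left <- if (lo > 1) w[lo - 1] else -Inf
    w_right <- if (hi < nrow(d)) w[hi + 1] else -Inf
    if (w_left >= w_right) {
      lo <- lo - 1
      mass <- mass + w[lo]
    } else {
      hi <- hi + 1
      mass <- mass + w[hi]
    }
  }
  if ("is_pseudomarker" %in% names(d)) {
    mark_idx <- which(!d$is_pseudomarker)
    if (length(mark_idx) > 0) {
      below <- mark_idx[mark_idx <= lo]
      above <- mark_idx[mark_idx >= hi]
      if (length(below) > 0) lo <- max(below)
      if (length(above) > 0) hi <- min(above)
    }
  }
  tibble::tibble(
    chrom = chrom,
    cM_lo = d$cM[lo], cM_hi = d$cM[hi],
    bp_lo = if ("bp" %in% names(d)) d$bp[lo] else NA_real_,
    bp_hi = if ("bp" %in% names(d)) d$bp[hi] else NA_real_,
    coverage_achieved = mass
  )
}
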