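#' LOD score and variance explained from a marker ANOVA
#'
#' `lod_from_f()` converts a one-way ANOVA F statistic to a LOD score via
#' \eqn{LOD = (n/2) \log_{10}(F \cdot df/(n - df - 1) + 1)}, with `df` the
#' genotype-factor (numerator) degrees of freedom. `pve_from_lod()` converts
#' a LOD score to the percentage of phenotypic variance explained,
#' \eqn{PVE = 100 (1 - 10^{-2 LOD / n})}.
#'
#' @param f ANOVA F statistic.
#' @param df Numerator degrees of freedom (genotype classes minus 1).
#' @param n Number of individuals.
#' @return A numeric value (LOD score / PVE in percent).
#' @examples
#' pve_from_lod(21.58, 186) # 41.39
#' @export
lod_from_f <- function(f, df, n) {
  (n / 2) * log10(f * df / (n - df - 1) + 1)
}

#' @rdname lod_from_f
#' @param lod LOD score.
#' @export
pve_from_lod <- function(lod, n) {
  100 * (1 - 10^(-2 * lod / n))
}

#' Single-marker ANOVA of a binary trait
#'
#' One-way ANOVA of phenotypic sex (coded 0/1) on the genotype factor at one
#' site, with the LOD and PVE transformations above. A site with a single
#' genotype class is degenerate: F is undefined and LOD is 0 by convention.
#'
#' @param genotypes Integer codes 0/1/2 (NA = missing) for the individuals.
#' @param sex Binary response (0/1, or `"M"`/`"F"` which is coded F = 1).
#' @return A one-row tibble: `f`, `df`, `n`, `lod`, `pve`, `p`,
#'   `degenerate`.
#' @export
anova_lod <- function(genotypes, sex) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.integer(as.character(sex) == "F")
  }
  ok <- !is.na(genotypes) & !is.na(sex)
  g <- genotypes[ok]
  y <- sex[ok]
  n <- length(y)
  classes <- sort(unique(g))
  k <- length(classes)
  if (n == 0 || k < 2) {
    return(tibble::tibble(
      f = NA_real_, df = 0L, n = n, lod = 0, pve = 0, p = NA_real_,
      degenerate = TRUE
    ))
  }
  ssb <- 0
  ybar <- mean(y)
  for (cl in classes) {
    yk <- y[g == cl]
    ssb <- ssb + length(yk) * (mean(yk) - ybar)^2
  }
  sst <- sum((y - ybar)^2)
  ssw <- sst - ssb
  df1 <- k - 1L
  df2 <- n - k
  if (df2 <= 0 || ssw <= 0) {
    # complete separation of group means
    lod <- lod_from_f(.Machine$double.xmax^0.1, df1, n)
    return(tibble::tibble(
      f = Inf, df = df1, n = n, lod = lod, pve = pve_from_lod(lod, n),
      p = 0, degenerate = FALSE
    ))
  }
  f <- (ssb / df1) / (ssw / df2)
  lod <- lod_from_f(f, df1, n)
  tibble::tibble(
    f = f, df = df1, n = n, lod = lod, pve = pve_from_lod(lod, n),
    p = stats::pf(f, df1, df2, lower.tail = FALSE),
    degenerate = FALSE
  )
}

#' Genome-wide single-marker regression scan
#'
#' Runs [anova_lod()] at every requested site, vectorised over sites, with
#' Bonferroni correction across the tested markers. With
#' `covariate = "family"` the genotype effect is tested over and above the
#' family effect (sequential two-way ANOVA on the marker-regression path).
#'
#' @param gt A [geno_table()].
#' @param ped Pedigree tibble with sexed F2.
#' @param sites Site indices; `NULL` for all.
#' @param covariate `"none"` or `"family"`.
#' @param family Restrict to one family label, or `NULL`.
#' @return A tibble of class `sexqtl_scan`, one row per site: `site`,
#'   `chrom`, `bp`, `marker_id`, `f`, `df`, `n`, `lod`, `pve`, `p`,
#'   `p_bonf`.
#' @export
scan_markers <- function(gt, ped, sites = NULL, covariate = c("none", "family"),
                         family = NULL) {
  stopifnot(inherits(gt, "geno_table"))
  covariate <- match.arg(covariate)
  if (is.null(sites)) sites <- seq_len(nrow(gt$geno))
  f2 <- ped[ped$generation == "F2" & ped$sex %in% c("M", "F"), , drop = FALSE]
  if (!is.null(family)) f2 <- f2[f2$family == family, , drop = FALSE]
  cols <- match(intersect(f2$sample_id, gt$samples), gt$samples)
  g <- gt$geno[sites, cols, drop = FALSE]
  y <- as.integer(f2$sex[match(gt$samples[cols], f2$sample_id)] == "F")

  if (covariate == "family") {
    fam <- factor(f2$family[match(gt$samples[cols], f2$sample_id)])
    res <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
      gi <- g[i, ]
      ok <- !is.na(gi)
      if (length(unique(gi[ok])) < 2) {
        return(tibble::tibble(
          f = NA_real_, df = 0L, n = sum(ok), lod = 0, pve = 0, p = NA_real_,
          degenerate = TRUE
        ))
      }
      fit <- stats::aov(y[ok] ~ fam[ok] + factor(gi[ok]))
      tab <- summary(fit)[[1]]
      row <- grep("factor\\(gi", rownames(tab))
      fv <- tab[row, "F value"]
      df1 <- tab[row, "Df"]
      n <- sum(ok)
      lod <- lod_from_f(fv, df1, n)
      tibble::tibble(
        f = fv, df = as.integer(df1), n = n, lod = lod,
        pve = pve_from_lod(lod, n), p = tab[row, "Pr(>F)"], degenerate = FALSE
      )
    })
  } else {
    # vectorised one-way ANOVA via per-class indicator sums
    n_site <- nrow(g)
    obs <- !is.na(g)
    Nk <- matrix(0, n_site, 3)
    Sk <- matrix(0, n_site, 3)
    for (k in 0:2) {
      ind <- obs & g == k
      ind[is.na(ind)] <- FALSE
      ind <- matrix(as.numeric(ind), n_site)
      Nk[, k + 1] <- rowSums(ind)
      Sk[, k + 1] <- as.vector(ind %*% y)
    }
    n <- rowSums(Nk)
    s <- rowSums(Sk)
    ybar <- s / n
    keep_k <- Nk > 0
    kcl <- rowSums(keep_k)
    mk <- ifelse(Nk > 0, Sk / Nk, 0)
    ssb <- rowSums(Nk * (mk - ybar)^2)
    sst <- s - n * ybar^2 # sum y^2 = sum y for binary y
    ssw <- pmax(sst - ssb, 0)
    df1 <- pmax(kcl - 1L, 0L)
    df2 <- n - kcl
    f <- ifelse(df1 > 0 & df2 > 0 & ssw > 0, (ssb / df1) / (ssw / df2), NA_real_)
    sep <- df1 > 0 & df2 > 0 & ssw <= 0 & ssb > 0
    f[sep] <- Inf
    lod <- ifelse(df1 > 0, lod_from_f(pmin(f, 1e12), df1, n), 0)
    lod[df1 == 0] <- 0
    lod[is.na(f) & df1 > 0] <- 0
    res <- tibble::tibble(
      f = f, df = as.integer(df1), n = as.integer(n), lod = lod,
      pve = pve_from_lod(lod, n),
      p = ifelse(is.finite(f) & df1 > 0,
        stats::pf(f, df1, df2, lower.tail = FALSE),
        ifelse(sep, 0, NA_real_)
      ),
      degenerate = df1 == 0
    )
  }
  out <- dplyr::bind_cols(
    tibble::tibble(
      site = sites,
      chrom = gt$markers$chrom[sites],
      bp = gt$markers$bp[sites],
      marker_id = gt$markers$marker_id[sites]
    ),
    res
  )
  out$p_bonf <- bonferroni(out$p)
  class(out) <- c("sexqtl_scan", class(out))
  out
}

#' Bonferroni correction
#'
#' @param p Vector of P values (NAs preserved).
#' @param m Number of tests; defaults to the number of non-missing P values.
#' @return Adjusted P values, capped at 1.
#' @export
bonferroni <- function(p, m = sum(!is.na(p))) {
  pmin(1, p * max(m, 1))
}

#' Exact binomial test of the F2 sex ratio
#'
#' Two-sided exact test of equal sex ratio (method of small P values, as in
#' the conventional exact binomial test).
#'
#' @param n_males,n_females Observed counts.
#' @return A one-row tibble: `n_males`, `n_females`, `prop_f`, `p`.
#' @export
binomial_sex_ratio_test <- function(n_males, n_females) {
  stopifnot(n_males + n_females >= 1)
  p <- stats::binom.test(n_males, n_males + n_females, p = 0.5)$p.value
  tibble::tibble(
    n_males = n_males, n_females = n_females,
    prop_f = n_females / (n_males + n_females), p = p
  )
}

#' Interpolate physical positions from map positions
#'
#' Fits a cubic smoothing spline of bp on cM per chromosome (smoothing level
#' by generalized cross-validation unless `spar` is given) and returns a
#' predictor for arbitrary cM positions. Chromosomes with fewer than 4
#' mapped markers fall back to linear interpolation. Predictions are clamped
#' to the mapped bp range, which keeps them monotone-safe at the ends.
#'
#' @param map Tibble with `chrom`, `bp`, `cM`.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @return An object of class `cm_bp_spline`; use [predict_bp()].
#' @export
cm_bp_interpolate <- function(map, spar = NULL) {
  stopifnot(all(c("chrom", "bp", "cM") %in% names(map)))
  fits <- map |>
    dplyr::filter(!is.na(.data$cM)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      rng <- range(d$bp)
      fit <- if (nrow(d) >= 4 && length(unique(d$cM)) >= 4) {
        if (is.null(spar)) {
          stats::smooth.spline(d$cM, d$bp)
        } else {
          stats::smooth.spline(d$cM, d$bp, spar = spar)
        }
      } else {
        stats::approxfun(d$cM, d$bp, rule = 2)
      }
      list(chrom = key$chrom[[1]], fit = fit, range_bp = rng)
    })
  names(fits) <- vapply(fits, `[[`, "", "chrom")
  structure(list(fits = fits), class = "cm_bp_spline")
}

#' @rdname cm_bp_interpolate
#' @param object A `cm_bp_spline`.
#' @param chrom Chromosome label(s).
#' @param cM Map position(s).
#' @return For `predict_bp()`, predicted bp positions.
#' @export
predict_bp <- function(object, chrom, cM) {
  stopifnot(inherits(object, "cm_bp_spline"))
  out <- numeric(length(cM))
  for (ch in unique(chrom)) {
    f <- object$fits[[ch]]
    if (is.null(f)) {
      out[chrom == ch] <- NA_real_
      next
    }
    x <- cM[chrom == ch]
    pred <- if (inherits(f$fit, "smooth.spline")) {
      stats::predict(f$fit, x)$y
    } else {
      f$fit(x)
    }
    out[chrom == ch] <- pmin(pmax(pred, f$range_bp[1]), f$range_bp[2])
  }
  out
}

#' @exportS3Method generics::glance
glance.sexqtl_scan <- function(x, ...) {
  peak <- x[which.max(x$lod), , drop = FALSE]
  tibble::tibble(
    n_markers = nrow(x),
    peak_chrom = peak$chrom,
    peak_bp = peak$bp,
    peak_lod = peak$lod,
    peak_pve = peak$pve,
    n_bonf_significant = sum(x$p_bonf < 0.05, na.rm = TRUE)
  )
}

#' @exportS3Method generics::tidy
tidy.sexqtl_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
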