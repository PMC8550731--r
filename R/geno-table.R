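#' Genotype table container
#'
#' A `geno_table` holds a sites-by-samples matrix of coded genotypes together
#' with per-genotype read depth and marker coordinates. Genotype codes are
#' `0` = homozygous for the grandmother-species (REF) allele, `1` =
#' heterozygous, `2` = homozygous for the grandfather-species (ALT) allele,
#' and `NA` = missing. Analysis functions take a `geno_table` first so calls
#' chain with the pipe; their outputs are tibbles.
#'
#' @param markers Tibble/data frame with columns `chrom`, `bp`, `marker_id`,
#'   `ref`, `alt` (one row per site, sorted by chromosome then position).
#' @param geno Integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param depth Numeric matrix of per-genotype read depths (same shape), or
#'   `NULL` when depth is unavailable.
#' @param samples Character vector of sample ids (column order of `geno`).
#' @return An object of class `geno_table`.
#' @export
geno_table <- function(markers, geno, depth = NULL, samples = colnames(geno)) {
  markers <- tibble::as_tibble(markers)
  need <- c("chrom", "bp", "marker_id", "ref", "alt")
  missing_cols <- setdiff(need, names(markers))
  if (length(missing_cols) > 0) {
    stop("markers is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(markers)) {
    stop("geno has ", nrow(geno), " rows but markers has ", nrow(markers))
  }
  if (is.null(samples)) stop("sample ids are required")
  if (length(samples) != ncol(geno)) stop("samples length != ncol(geno)")
  bad <- geno[!is.na(geno)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(geno))) stop("depth and geno dimensions differ")
    if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  }
  dimnames(geno) <- list(markers$marker_id, samples)
  if (!is.null(depth)) dimnames(depth) <- dimnames(geno)
  structure(
    list(markers = markers, geno = geno, depth = depth, samples = samples),
    class = "geno_table"
  )
}

#' @export
print.geno_table <- function(x, ...) {
  cat(
    "<geno_table> ", nrow(x$geno), " sites x ", length(x$samples), " samples",
    if (is.null(x$depth)) " (no depth)" else "",
    "\n",
    sep = ""
  )
  cat("  chromosomes: ", length(unique(x$markers$chrom)),
    "; missing genotypes: ",
    sprintf("%.1f%%", 100 * mean(is.na(x$geno))), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.geno_table <- function(x) dim(x$geno)

#' Subset a genotype table by sites and/or samples
#'
#' @param gt A [geno_table()].
#' @param sites Integer or logical index over sites (rows), or `NULL` for all.
#' @param samples Character sample ids, or integer/logical index over
#'   samples, or `NULL` for all.
#' @return A `geno_table` restricted to the selection, order preserved as
#'   given.
#' @export
gt_subset <- function(gt, sites = NULL, samples = NULL) {
  stopifnot(inherits(gt, "geno_table"))
  si <- if (is.null(sites)) seq_len(nrow(gt$geno)) else sites
  if (is.logical(si)) si <- which(si)
  sj <- if (is.null(samples)) seq_along(gt$samples) else samples
  if (is.character(sj)) {
    miss <- setdiff(sj, gt$samples)
    if (length(miss) > 0) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    sj <- match(sj, gt$samples)
  }
  if (is.logical(sj)) sj <- which(sj)
  geno_table(
    markers = gt$markers[si, , drop = FALSE],
    geno = gt$geno[si, sj, drop = FALSE],
    depth = if (is.null(gt$depth)) NULL else gt$depth[si, sj, drop = FALSE],
    samples = gt$samples[sj]
  )
}

#' Polarize genotypes to grandparental origin
#'
#' Recodes genotypes so that `0` means homozygous for the grandmother-species
#' allele and `2` homozygous for the grandfather-species allele. Sites where
#' the grandmother-side reference individual is homozygous ALT are flipped
#' (`g -> 2 - g`); heterozygous or missing reference sites are left as coded.
#'
#' @param gt A [geno_table()] coded against REF/ALT.
#' @param ped Pedigree tibble (see [read_pedigree()]).
#' @return A `geno_table` with grandmother-polarized codes.
#' @export
polarize_to_grandmother <- function(gt, ped) {
  gm <- ped$sample_id[ped$generation == "F0" & ped$sex == "F"]
  if (length(gm) == 0) {
    gm <- ped$sample_id[ped$generation == "species_surrogate" &
      ped$species == ped$species[ped$generation == "F0" & ped$sex == "F"][1]]
  }
  if (length(gm) == 0) stop("no F0 grandmother found in pedigree")
  g <- gt$geno[, gt$samples %in% gm, drop = FALSE]
  flip <- apply(g, 1L, function(row) {
    row <- row[!is.na(row)]
    length(row) > 0 && all(row == 2L)
  })
  out <- gt
  out$geno[flip, ] <- 2L - out$geno[flip, , drop = FALSE]
  out
}

#' Tidy a genotype table into long format
#'
#' @param x A [geno_table()].
#' @param ... Unused.
#' @return A tibble with one row per site x sample: `chrom`, `bp`,
#'   `marker_id`, `sample_id`, `genotype`, `depth`.
#' @exportS3Method generics::tidy
tidy.geno_table <- function(x, ...) {
  long <- tibble::tibble(
    marker_id = rep(x$markers$marker_id, times = length(x$samples)),
    chrom = rep(x$markers$chrom, times = length(x$samples)),
    bp = rep(x$markers$bp, times = length(x$samples)),
    sample_id = rep(x$samples, each = nrow(x$geno)),
    genotype = as.integer(x$geno),
    depth = if (is.null(x$depth)) NA_real_ else as.numeric(x$depth)
  )
  long[, c("chrom", "bp", "marker_id", "sample_id", "genotype", "depth")]
}

#' @exportS3Method generics::glance
glance.geno_table <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$geno),
    n_samples = length(x$samples),
    n_chrom = length(unique(x$markers$chrom)),
    prop_missing = mean(is.na(x$geno)),
    mean_depth = if (is.null(x$depth)) NA_real_ else mean(x$depth, na.rm = TRUE)
  )
}

# F2 sample ids of known sex, optionally restricted to a family
f2_by_sex <- function(ped, family = NULL) {
  f2 <- ped[ped$generation == "F2" & ped$sex %in% c("M", "F"), , drop = FALSE]
  if (!is.null(family)) f2 <- f2[f2$family == family, , drop = FALSE]
  list(
    males = f2$sample_id[f2$sex == "M"],
    females = f2$sample_id[f2$sex == "F"]
  )
}
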