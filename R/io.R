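#' Write a genotype table as VCF 4.2
#'
#' Emits bi-allelic SNP records with per-genotype `GT:DP`, contig header
#' lines, and 1-based coordinates. Genotype codes 0/1/2 map to `0/0`, `0/1`,
#' `1/1`; missing to `./.`.
#'
#' @param gt A [geno_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cross_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "geno_table"))
  m <- gt$markers
  contigs <- unique(m$chrom)
  contig_len <- vapply(contigs, function(ch) max(m$bp[m$chrom == ch]) + 1L, numeric(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sexqtl",
    sprintf("##contig=<ID=%s,length=%d>", contigs, as.integer(contig_len)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      gt$samples
    ), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt$geno + 1L], nrow = nrow(gt$geno))
  gt_str[is.na(gt$geno)] <- "./."
  dp <- if (is.null(gt$depth)) {
    matrix(".", nrow = nrow(gt$geno), ncol = ncol(gt$geno))
  } else {
    matrix(as.character(as.integer(gt$depth)), nrow = nrow(gt$geno))
  }
  cells <- matrix(paste0(gt_str, ":", dp), nrow = nrow(gt$geno))
  body <- paste(
    m$chrom, m$bp, m$marker_id, m$ref, m$alt, ".", "PASS", ".", "GT:DP",
    apply(cells, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype table
#'
#' Loads bi-allelic SNP records with `GT` (and `DP` when present). Records
#' that are multi-allelic or not single-nucleotide substitutions are dropped
#' with a message. Every VCF sample must be present in the pedigree.
#'
#' @param path VCF path (plain or gzipped).
#' @param ped Pedigree tibble (see [read_pedigree()]); used to validate
#'   sample ids. `NULL` skips the check.
#' @return A [geno_table()] coded against REF (0 = hom REF).
#' @export
read_cross_vcf <- function(path, ped = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) fix else matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("dropped ", n_drop, " multi-allelic or non-SNP record(s)")
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt_raw)
  if (!is.null(ped)) {
    unknown <- setdiff(samples, ped$sample_id)
    if (length(unknown) > 0) {
      stop("VCF sample(s) absent from pedigree: ", paste(unknown, collapse = ", "))
    }
  }
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out
  }
  geno <- matrix(code(gt_raw), nrow = nrow(gt_raw), dimnames = dimnames(gt_raw))
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp_raw <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- dp_raw[keep, , drop = FALSE]
  }
  markers <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    bp = as.integer(fix[keep, "POS"]),
    marker_id = fix[keep, "ID"],
    ref = ref[keep], alt = alt[keep]
  )
  no_id <- is.na(markers$marker_id) | markers$marker_id == "."
  markers$marker_id[no_id] <-
    paste0(markers$chrom[no_id], "_", markers$bp[no_id])
  geno_table(markers, geno, depth, samples)
}

#' Read or write a pedigree table
#'
#' Tab-separated with columns `sample_id`, `generation` (F0/F1/F2/
#' species_surrogate), `family`, `sex` (M/F/unknown), `species`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_pedigree <- function(path) {
  ped <- tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
  need <- c("sample_id", "generation", "family", "sex")
  missing_cols <- setdiff(need, names(ped))
  if (length(missing_cols) > 0) {
    stop("pedigree is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_gen <- setdiff(unique(ped$generation), c("F0", "F1", "F2", "species_surrogate"))
  if (length(bad_gen) > 0) {
    stop("unknown generation label(s): ", paste(bad_gen, collapse = ", "))
  }
  bad_sex <- setdiff(unique(ped$sex), c("M", "F", "unknown"))
  if (length(bad_sex) > 0) {
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  }
  if (!"species" %in% names(ped)) ped$species <- NA_character_
  ped
}

#' @rdname read_pedigree
#' @param ped Pedigree tibble.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a marker map
#'
#' Tab-separated with columns `chrom`, `marker_id`, `bp` and optional `cM`.
#'
#' @param path File path.
#' @return A tibble sorted by chromosome and position.
#' @export
read_marker_map <- function(path) {
  map <- tibble::as_tibble(utils::read.delim(path))
  need <- c("chrom", "marker_id", "bp")
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols) > 0) {
    stop("map is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dplyr::arrange(map, .data$chrom, .data$bp)
}

#' @rdname read_marker_map
#' @param map Map tibble.
#' @export
write_marker_map <- function(map, path) {
  cols <- intersect(c("chrom", "marker_id", "bp", "cM"), names(map))
  utils::write.table(map[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read simulation ground truth
#'
#' The truth of a simulated cross round-trips through two tab-separated
#' files: `path` holds the determiner description and per-F2 records
#' (composition labels, carrier/recombinant flags), and `<path>.paintings`
#' holds the founder-haplotype paintings (one row per locus, two columns per
#' F2: maternal- and paternal-gamete founder haplotype id).
#'
#' @param truth A `cross_truth` from [simulate_cross()].
#' @param path Output path for the record file.
#' @return `path`, invisibly (for `write_truth`); a `cross_truth` (for
#'   `read_truth`).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "cross_truth"))
  hdr <- sprintf(
    "#sd_chromosome=%s\tsd_position_cM=%s\tsystem=%s",
    truth$sd_chromosome, truth$sd_position_cM, truth$system
  )
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(truth$records, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  close(con)
  p <- truth$paintings
  hap_cols <- as.data.frame(cbind(p$hap_m, p$hap_p))
  suffix <- function(m, sfx) {
    if (ncol(m) == 0) character(0) else paste0(colnames(m), sfx)
  }
  names(hap_cols) <- c(suffix(p$hap_m, ".m"), suffix(p$hap_p, ".p"))
  pt <- cbind(
    p$loci[, c("chrom", "bp", "cM", "marker_id", "pseudo")],
    hap_cols
  )
  utils::write.table(pt, paste0(path, ".paintings"),
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1)
  kv <- strsplit(sub("^#", "", first), "\t")[[1]]
  meta <- stats::setNames(
    lapply(strsplit(kv, "="), `[`, 2),
    vapply(strsplit(kv, "="), `[`, "", 1)
  )
  records <- tibble::as_tibble(utils::read.delim(path, skip = 1))
  records$sample_id <- as.character(records$sample_id)
  records$family <- as.character(records$family)
  pt <- utils::read.delim(paste0(path, ".paintings"), check.names = FALSE)
  hm_cols <- grep("\\.m$", names(pt), value = TRUE)
  hp_cols <- grep("\\.p$", names(pt), value = TRUE)
  hap_m <- as.matrix(pt[, hm_cols, drop = FALSE])
  hap_p <- as.matrix(pt[, hp_cols, drop = FALSE])
  colnames(hap_m) <- sub("\\.m$", "", hm_cols)
  colnames(hap_p) <- sub("\\.p$", "", hp_cols)
  structure(
    list(
      sd_chromosome = suppressWarnings(as.integer(meta$sd_chromosome)),
      sd_position_cM = suppressWarnings(as.numeric(meta$sd_position_cM)),
      system = meta$system,
      modifier = NULL,
      records = records,
      paintings = list(
        loci = tibble::as_tibble(pt[, c("chrom", "bp", "cM", "marker_id", "pseudo")]),
        hap_m = hap_m, hap_p = hap_p
      ),
      gametolog_sites = NULL, diagnostic_sites = NULL, error_mask = NULL
    ),
    class = "cross_truth"
  )
}
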