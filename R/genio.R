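# Genotype I/O and quality control.
#
# Coordinates are 1-based inclusive internally (VCF convention); interval
# exports use BED (0-based half-open). Multi-allelic VCF sites are skipped,
# not split.

gt_to_dosage <- function(gt) {
  # "0/1", "0|1", "1/1", "./.", "./1", NA -> alt-allele dosage or NA.
  # Any half-missing genotype is treated as fully missing.
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt)
  alleles <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".") || any(a == "")) {
      return(NA_integer_)
    }
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai < 0L) || any(ai > 1L)) {
      return(NA_integer_)
    }
    sum(ai)
  }, integer(1))
  out
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    divsig_log("skipping %d non-biallelic site(s)", sum(multi), level = "WARN")
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  nopos <- is.na(pos) | pos <= 0L
  if (any(nopos)) {
    divsig_log("rejecting %d SNP(s) with unknown position", sum(nopos), level = "WARN")
  }
  keep <- !multi & !nopos
  if (!any(keep)) stop("read_genotypes: no biallelic positioned sites in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(gt))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  mm <- marker_map(
    snp_id = ids, chrom = fix[, "CHROM"], pos_bp = as.integer(fix[, "POS"]),
    ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"]
  )
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    dos[, j] <- gt_to_dosage(gt[j, ])
  }
  # marker_map() sorts by (chrom, pos); mirror that ordering in the columns
  ord <- order(fix[, "CHROM"], as.integer(fix[, "POS"]))
  dos <- dos[, ord, drop = FALSE]
  genotype_matrix(dos, colnames(gt), mm)
}

write_vcf_genotypes <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=divsig",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  ), con)
  header <- paste(c(
    "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
    g$sample_ids
  ), collapse = "\t")
  writeLines(header, con)
  if (nrow(g$values) == 0L || ncol(g$values) == 0L) {
    return(invisible(path))
  }
  code <- c("0/0", "0/1", "1/1")
  m <- g$markers
  for (j in seq_len(ncol(g$values))) {
    d <- g$values[, j]
    gt <- ifelse(is.na(d), "./.", code[d + 1L])
    writeLines(paste(c(
      m$chrom[j], m$pos_bp[j], m$snp_id[j], m$ref_allele[j], m$alt_allele[j],
      ".", "PASS", ".", "GT", gt
    ), collapse = "\t"), con)
  }
  invisible(path)
}

# PLINK text dialect. PED: FID IID PAT MAT SEX PHENO + two allele columns per
# SNP ("0 0" = missing). MAP is written with 6 columns
# (chrom, snp_id, cM, pos_bp, ref_allele, alt_allele) so that the ref/alt
# assignment round-trips; a standard 4-column MAP is accepted on read, with
# alleles inferred from the PED (major allele = ref, ties alphabetical).
read_plink_genotypes <- function(path) {
  map_path <- paste0(path, ".map")
  ped_path <- paste0(path, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path)) {
    stop("read_genotypes: expected ", path, ".ped and ", path, ".map")
  }
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(map) %in% c(4L, 6L)) {
    stop("read_genotypes: MAP file must have 4 or 6 columns")
  }
  n_snp <- nrow(map)
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(ped) > 0L && ncol(ped) != 6L + 2L * n_snp) {
    stop(sprintf(
      "read_genotypes: PED has %d columns, expected %d for %d SNPs",
      ncol(ped), 6L + 2L * n_snp, n_snp
    ))
  }
  sample_ids <- if (nrow(ped)) ped[[2]] else character(0)
  a1 <- if (nrow(ped)) as.matrix(ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]) else
    matrix("0", 0, n_snp)
  a2 <- if (nrow(ped)) as.matrix(ped[, 6L + 2L * seq_len(n_snp), drop = FALSE]) else
    matrix("0", 0, n_snp)
  pos <- suppressWarnings(as.integer(map[[4]]))
  keep <- !is.na(pos) & pos > 0L
  if (any(!keep)) {
    divsig_log("rejecting %d SNP(s) with unknown position", sum(!keep), level = "WARN")
  }
  if (ncol(map) == 6L) {
    ref <- map[[5]]
    altl <- map[[6]]
  } else {
    ref <- altl <- character(n_snp)
    for (j in seq_len(n_snp)) {
      obs <- c(a1[, j], a2[, j])
      obs <- obs[obs != "0"]
      al <- sort(unique(obs))
      if (length(al) == 0L) al <- c("A", "B")
      if (length(al) == 1L) al <- c(al, setdiff(c("A", "B"), al)[1])
      if (length(al) > 2L) {
        stop(sprintf("read_genotypes: SNP %s has >2 alleles", map[[2]][j]))
      }
      cnt <- c(sum(obs == al[1]), sum(obs == al[2]))
      ref[j] <- al[which.max(cnt)]   # major allele = ref; ties -> first alphabetical
      altl[j] <- al[setdiff(1:2, which.max(cnt))]
    }
  }
  mm <- marker_map(map[[2]][keep], map[[1]][keep], pos[keep], ref[keep], altl[keep])
  # dosage = count of alt alleles; "0" allele codes missing
  dos <- matrix(NA_integer_, nrow = length(sample_ids), ncol = sum(keep))
  kidx <- which(keep)
  for (jj in seq_along(kidx)) {
    j <- kidx[jj]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == altl[j]) + (a2[, j] == altl[j])
    bad <- !miss & (!(a1[, j] %in% c(ref[j], altl[j])) | !(a2[, j] %in% c(ref[j], altl[j])))
    if (any(bad)) {
      stop(sprintf("read_genotypes: allele not in {ref, alt} at SNP %s", map[[2]][j]))
    }
    d[miss] <- NA_integer_
    dos[, jj] <- d
  }
  # columns follow the (chrom, pos)-sorted marker map
  src_ord <- order(map[[1]][keep], pos[keep])
  dos <- dos[, src_ord, drop = FALSE]
  genotype_matrix(dos, sample_ids, mm)
}

write_plink_genotypes <- function(g, path) {
  m <- g$markers
  map <- data.frame(
    chrom = m$chrom, snp_id = m$snp_id, cm = 0, pos = m$pos_bp,
    ref = m$ref_allele, alt = m$alt_allele, stringsAsFactors = FALSE
  )
  utils::write.table(map, paste0(path, ".map"),
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  con <- file(paste0(path, ".ped"), "w")
  on.exit(close(con))
  n_snp <- ncol(g$values)
  for (i in seq_len(nrow(g$values))) {
    d <- g$values[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, m$alt_allele, m$ref_allele))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, m$alt_allele, m$ref_allele))
    writeLines(paste(c(
      g$sample_ids[i], g$sample_ids[i], "0", "0", "0", "-9",
      as.vector(rbind(a1, a2))
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF or PLINK text files
#'
#' Dosage is the count of alternative alleles; phased and unphased genotypes
#' are treated identically and half-missing genotypes are mapped to missing.
#' Markers are sorted by (chrom, pos_bp). Non-biallelic VCF sites and SNPs
#' without a usable position are skipped with a logged count.
#'
#' @param path for VCF, the file path; for PLINK text, the common prefix of
#'   `<path>.ped` / `<path>.map`.
#' @param format `"VCF"` or `"PLINK_TEXT"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("VCF", "PLINK_TEXT")) {
  format <- match.arg(format)
  switch(format,
    VCF = read_vcf_genotypes(path),
    PLINK_TEXT = read_plink_genotypes(path)
  )
}

#' Write genotypes to VCF or PLINK text files
#'
#' Output round-trips through [read_genotypes()] (dosages, sample ids and
#' marker map are preserved, including missing codes).
#'
#' @param g a [genotype_matrix()].
#' @inheritParams read_genotypes
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("VCF", "PLINK_TEXT")) {
  format <- match.arg(format)
  switch(format,
    VCF = write_vcf_genotypes(g, path),
    PLINK_TEXT = write_plink_genotypes(g, path)
  )
}

#' Quality-control parameters
#'
#' Defaults follow array-genotyping practice for selection-line panels:
#' samples with call rate below 97% are removed, then SNPs with minor allele
#' frequency below 0.05 or missingness above 0.05.
#'
#' @param min_sample_call_rate minimum fraction of non-missing genotypes per
#'   sample.
#' @param min_maf minimum minor allele frequency per SNP.
#' @param max_snp_missing maximum fraction of missing genotypes per SNP.
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(min_sample_call_rate = 0.97, min_maf = 0.05,
                      max_snp_missing = 0.05) {
  p <- list(
    min_sample_call_rate = min_sample_call_rate,
    min_maf = min_maf,
    max_snp_missing = max_snp_missing
  )
  if (any(unlist(p) < 0) || any(unlist(p) > 1)) {
    stop("qc_params: all parameters must lie in [0, 1]")
  }
  class(p) <- "qc_params"
  p
}

#' Apply sample and SNP quality-control filters
#'
#' Samples failing the call-rate threshold are dropped first; SNP minor
#' allele frequency and missingness are then computed on the retained
#' samples only. The operation is idempotent on its own output.
#'
#' @param g a [genotype_matrix()].
#' @param params a [qc_params()].
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (counts dropped per criterion).
#' @export
qc_filter <- function(g, params = qc_params()) {
  if (nrow(g$values) == 0L || ncol(g$values) == 0L) {
    stop("qc_filter: empty genotype matrix")
  }
  call_rate <- rowMeans(!is.na(g$values))
  keep_s <- call_rate >= params$min_sample_call_rate
  if (!any(keep_s)) stop("qc_filter: all samples removed by call-rate filter")
  vals <- g$values[keep_s, , drop = FALSE]
  n_obs <- colSums(!is.na(vals))
  miss <- 1 - n_obs / nrow(vals)
  p_alt <- ifelse(n_obs > 0L, colSums(vals, na.rm = TRUE) / (2 * n_obs), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  drop_maf <- is.na(maf) | maf < params$min_maf
  drop_miss <- miss > params$max_snp_missing
  keep_m <- !(drop_maf | drop_miss)
  report <- list(
    n_samples_in = nrow(g$values),
    n_samples_dropped_call_rate = sum(!keep_s),
    n_snps_in = ncol(g$values),
    n_snps_dropped_maf = sum(drop_maf),
    n_snps_dropped_missing = sum(drop_miss & !drop_maf),
    n_samples_out = sum(keep_s),
    n_snps_out = sum(keep_m)
  )
  class(report) <- "qc_report"
  list(
    genotypes = genotype_matrix(
      vals[, keep_m, drop = FALSE],
      g$sample_ids[keep_s],
      g$markers[keep_m, , drop = FALSE]
    ),
    report = report
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "QC: %d/%d samples retained (%d below call rate); ",
      "%d/%d SNPs retained (%d MAF, %d missingness)\n"
    ),
    x$n_samples_out, x$n_samples_in, x$n_samples_dropped_call_rate,
    x$n_snps_out, x$n_snps_in, x$n_snps_dropped_maf, x$n_snps_dropped_missing
  ))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report` from [qc_filter()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(
    data.frame(metric = names(unclass(report)), value = unlist(report)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Per-SNP alternative-allele frequency in a sample subset
#'
#' Frequency is the alt-allele dosage sum over twice the number of
#' non-missing genotypes. SNPs with no non-missing genotype in the subset
#' propagate `NaN`, never a silent zero.
#'
#' @param g a [genotype_matrix()].
#' @param samples sample ids or row indices (default: all samples).
#' @return numeric vector, one frequency per SNP.
#' @export
allele_freq <- function(g, samples = NULL) {
  idx <- seq_along(g$sample_ids)
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, g$sample_ids) else samples
    if (anyNA(idx)) stop("allele_freq: unknown sample id(s)")
  }
  if (length(idx) == 0L) stop("allele_freq: empty sample subset")
  vals <- g$values[idx, , drop = FALSE]
  n_obs <- colSums(!is.na(vals))
  colSums(vals, na.rm = TRUE) / (2 * n_obs)
}

#' Per-SNP observed heterozygote frequency in a sample subset
#'
#' Computed directly from dosage-1 counts among non-missing genotypes (no
#' Hardy-Weinberg assumption).
#'
#' @inheritParams allele_freq
#' @return numeric vector, one heterozygote frequency per SNP.
#' @export
het_freq <- function(g, samples = NULL) {
  idx <- seq_along(g$sample_ids)
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, g$sample_ids) else samples
    if (anyNA(idx)) stop("het_freq: unknown sample id(s)")
  }
  if (length(idx) == 0L) stop("het_freq: empty sample subset")
  vals <- g$values[idx, , drop = FALSE]
  n_obs <- colSums(!is.na(vals))
  colSums(vals == 1L, na.rm = TRUE) / n_obs
}
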