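#' Marker map constructor
#'
#' A marker map describes the SNPs of a genotype matrix: identifier,
#' chromosome, 1-based physical position and the ref/alt allele pair.
#' Markers are sorted by (chrom, pos_bp); duplicate positions within a
#' chromosome and markers without a usable position are rejected.
#'
#' @param snp_id character vector of SNP identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos_bp integer vector of 1-based physical positions.
#' @param ref_allele,alt_allele character vectors of alleles.
#' @return a `data.frame` of class `marker_map`.
#' @export
marker_map <- function(snp_id, chrom, pos_bp, ref_allele, alt_allele) {
  df <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$pos_bp)) || any(df$pos_bp <= 0L)) {
    stop("marker_map: markers with unknown or non-positive position are not allowed")
  }
  if (any(df$ref_allele == "" | df$alt_allele == "")) {
    stop("marker_map: empty alleles")
  }
  if (any(df$ref_allele == df$alt_allele)) {
    stop("marker_map: ref_allele must differ from alt_allele")
  }
  ord <- order(df$chrom, df$pos_bp)
  df <- df[ord, , drop = FALSE]
  if (anyDuplicated(df[, c("chrom", "pos_bp")])) {
    stop("marker_map: duplicate (chrom, pos_bp)")
  }
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Genotype matrix constructor
#'
#' Individuals x SNPs matrix of alt-allele dosages in {0, 1, 2}, with `NA`
#' as the missing code, tied to a [marker_map()].
#'
#' @param values integer matrix, rows = individuals, columns = SNPs.
#' @param sample_ids character vector of unique sample identifiers.
#' @param markers a [marker_map()] with one row per column of `values`.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `values`, `sample_ids`, `markers`.
#' @export
genotype_matrix <- function(values, sample_ids, markers) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (!inherits(markers, "marker_map")) {
    markers <- marker_map(
      markers$snp_id, markers$chrom, markers$pos_bp,
      markers$ref_allele, markers$alt_allele
    )
  }
  if (ncol(values) != nrow(markers)) {
    stop("genotype_matrix: column count must equal marker count")
  }
  if (nrow(values) != length(sample_ids)) {
    stop("genotype_matrix: row count must equal sample count")
  }
  if (anyDuplicated(sample_ids)) stop("genotype_matrix: duplicate sample ids")
  bad <- values[!is.na(values)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype_matrix: dosages must be in {0, 1, 2} or NA")
  }
  dimnames(values) <- list(as.character(sample_ids), markers$snp_id)
  structure(
    list(
      values = values,
      sample_ids = as.character(sample_ids),
      markers = markers
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs on %d chromosome(s); %.2f%% missing\n",
    nrow(x$values), ncol(x$values), length(unique(x$markers$chrom)),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param g a [genotype_matrix()].
#' @param samples sample ids or indices to keep (default all).
#' @param snps SNP column indices or ids to keep (default all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  ridx <- seq_along(g$sample_ids)
  if (!is.null(samples)) {
    ridx <- if (is.character(samples)) match(samples, g$sample_ids) else samples
    if (anyNA(ridx)) stop("subset_genotypes: unknown sample id(s)")
  }
  cidx <- seq_len(nrow(g$markers))
  if (!is.null(snps)) {
    cidx <- if (is.character(snps)) match(snps, g$markers$snp_id) else snps
    if (anyNA(cidx)) stop("subset_genotypes: unknown snp id(s)")
  }
  genotype_matrix(
    g$values[ridx, cidx, drop = FALSE],
    g$sample_ids[ridx],
    g$markers[cidx, , drop = FALSE]
  )
}

#' Cohort table constructor
#'
#' Maps each sample to its line (BASE, HIGH or LOW) and generation.
#'
#' @param sample_id character vector.
#' @param line character vector over {"BASE", "HIGH", "LOW"}.
#' @param generation non-negative integer vector.
#' @return a `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(sample_id, line, generation) {
  line <- toupper(as.character(line))
  if (!all(line %in% c("BASE", "HIGH", "LOW"))) {
    stop("cohort_table: line must be BASE, HIGH or LOW")
  }
  generation <- as.integer(generation)
  if (any(is.na(generation)) || any(generation < 0L)) {
    stop("cohort_table: generation must be a non-negative integer")
  }
  df <- data.frame(
    sample_id = as.character(sample_id),
    line = line,
    generation = generation,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id)) stop("cohort_table: duplicate sample ids")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Select sample ids of one cohort
#'
#' @param cohorts a [cohort_table()].
#' @param line cohort line.
#' @param generation optional generation filter.
#' @return character vector of sample ids.
#' @export
cohort_samples <- function(cohorts, line, generation = NULL) {
  keep <- cohorts$line == line
  if (!is.null(generation)) keep <- keep & cohorts$generation == generation
  cohorts$sample_id[keep]
}

#' Read / write a cohort table as 3-column TSV
#'
#' @param path TSV path with columns sample_id, line, generation.
#' @return a [cohort_table()].
#' @export
read_cohorts <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
  cohort_table(df$sample_id, df$line, df$generation)
}

#' @param cohorts a [cohort_table()].
#' @rdname read_cohorts
#' @export
write_cohorts <- function(cohorts, path) {
  utils::write.table(as.data.frame(cohorts), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
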