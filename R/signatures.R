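# Integration of the three methods: putative signature sets from the
# generation-11 scan, validation against the generation-13 rerun, and the
# merged report with overlapping genes.

#' Signature set constructor
#'
#' A set of candidate-signature intervals produced by one method in one
#' analysis generation. Intervals are merged (union of overlapping or
#' adjacent intervals) so the stored set is non-overlapping.
#'
#' @param method `"ROH"`, `"FST"` or `"VARLD"`.
#' @param intervals data frame with chrom, start_bp, end_bp (1-based
#'   inclusive).
#' @param analysis_generation generation of the line cohorts analysed.
#' @param status `"PUTATIVE"` or `"TRUE"`.
#' @return list of class `signature_set`.
#' @export
signature_set <- function(method, intervals, analysis_generation,
                          status = "PUTATIVE") {
  method <- match.arg(method, c("ROH", "FST", "VARLD"))
  status <- match.arg(status, c("PUTATIVE", "TRUE"))
  if (nrow(intervals)) {
    gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
    intervals <- granges_to_intervals(gr)
  } else {
    intervals <- data.frame(
      chrom = character(0), start_bp = integer(0), end_bp = integer(0),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    method = method,
    intervals = intervals,
    analysis_generation = as.integer(analysis_generation),
    status = status
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf(
    "signature_set: %s, generation %d, %s, %d interval(s)\n",
    x$method, x$analysis_generation, x$status, nrow(x$intervals)
  ))
  invisible(x)
}

#' Validate putative signatures against a later-generation reanalysis
#'
#' A putative interval is a true signature iff it overlaps (>= 1 bp) some
#' interval of the revalidation set produced by the same method; true
#' intervals retain their original (putative-analysis) coordinates. Methods
#' are never mixed.
#'
#' @param putative a `signature_set` (e.g. the generation-11 analysis).
#' @param revalidation a `signature_set` from the same method rerun on the
#'   later cohorts.
#' @return a `signature_set` with status `"TRUE"`.
#' @export
validate_signatures <- function(putative, revalidation) {
  if (putative$method != revalidation$method) {
    stop("validate_signatures: method mismatch (", putative$method,
         " vs ", revalidation$method, ")")
  }
  gr_put <- intervals_to_granges(putative$intervals)
  gr_rev <- intervals_to_granges(revalidation$intervals)
  keep <- integer(0)
  if (length(gr_put) && length(gr_rev)) {
    hits <- GenomicRanges::findOverlaps(gr_put, gr_rev)
    keep <- sort(unique(S4Vectors::queryHits(hits)))
  }
  signature_set(
    putative$method,
    putative$intervals[keep, , drop = FALSE],
    putative$analysis_generation,
    status = "TRUE"
  )
}

#' Merge validated signature sets and overlay gene annotation
#'
#' Produces per-method interval tables, their union, per-method counts and
#' the list of genes whose annotated interval overlaps (>= 1 bp) any true
#' signature.
#'
#' @param sets list of `signature_set` objects (validated).
#' @param gene_annotation data frame with gene_id, chrom, start_bp, end_bp
#'   (1-based inclusive), or NULL.
#' @return list with `per_method` (named interval tables), `union`
#'   (interval table), `counts` (named integer vector) and `genes`
#'   (character vector of overlapping gene ids).
#' @export
merge_and_report <- function(sets, gene_annotation = NULL) {
  per_method <- stats::setNames(
    lapply(sets, function(s) s$intervals),
    vapply(sets, function(s) s$method, character(1))
  )
  all_int <- do.call(rbind, lapply(unname(sets), function(s) s$intervals))
  all_gr <- GenomicRanges::reduce(intervals_to_granges(all_int))
  counts <- vapply(sets, function(s) nrow(s$intervals), integer(1))
  names(counts) <- names(per_method)
  genes <- character(0)
  if (is.null(gene_annotation) || nrow(gene_annotation) == 0L) {
    warning("merge_and_report: empty gene annotation; no gene overlay")
  } else if (length(all_gr)) {
    gr_genes <- intervals_to_granges(gene_annotation)
    hits <- GenomicRanges::findOverlaps(gr_genes, all_gr)
    genes <- sort(unique(gene_annotation$gene_id[S4Vectors::queryHits(hits)]))
  }
  list(
    per_method = per_method,
    union = granges_to_intervals(all_gr),
    counts = counts,
    genes = genes
  )
}

#' Read a gene annotation from BED or GFF3
#'
#' BED input uses columns chrom/start/end/name (0-based half-open,
#' converted); GFF3 input keeps `gene` features only, with gene_id taken
#' from the ID or gene_id attribute.
#'
#' @param path annotation file.
#' @param format `"BED"` or `"GFF3"`.
#' @return data frame with gene_id, chrom, start_bp, end_bp.
#' @export
read_gene_annotation <- function(path, format = c("BED", "GFF3")) {
  format <- match.arg(format)
  if (format == "BED") {
    df <- read_bed(path)
    if (is.null(df$name)) df$name <- sprintf("gene%04d", seq_len(nrow(df)))
    return(data.frame(
      gene_id = df$name, chrom = df$chrom, start_bp = df$start_bp,
      end_bp = df$end_bp, stringsAsFactors = FALSE
    ))
  }
  raw <- utils::read.table(path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    comment.char = "#", quote = ""
  )
  raw <- raw[raw[[3]] == "gene", , drop = FALSE]
  attr_id <- function(s) {
    m <- regmatches(s, regexec("(?:^|;)(?:ID|gene_id)=([^;]+)", s))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  data.frame(
    gene_id = vapply(raw[[9]], attr_id, character(1), USE.NAMES = FALSE),
    chrom = as.character(raw[[1]]),
    start_bp = as.integer(raw[[4]]),
    end_bp = as.integer(raw[[5]]),
    stringsAsFactors = FALSE
  )
}

#' Run the three-method signature scan for one analysis generation
#'
#' Applies QC, then: (1) ROH calling on both lines' individuals, per-line
#' consensus and the two-line fraction rule; (2) windowed Weir-Cockerham
#' FST between the lines with percentile relevance and the MAF
#' drift-versus-selection rule (SELECTION windows only); (3) varLD over the
#' three cohort comparisons with the intersection rule (SELECTION intervals
#' only).
#'
#' @param g a [genotype_matrix()].
#' @param cohorts a [cohort_table()].
#' @param generation line generation to analyse (base cohort is always
#'   generation 0).
#' @param qc a [qc_params()] or NULL to skip QC.
#' @param roh a [roh_params()].
#' @param roh_min_count consensus minimum total coverage.
#' @param roh_fraction per-line fraction for the ROH signature rule.
#' @param fst_window_kb,fst_step_kb,fst_min_snps FST windowing.
#' @param fst_percentile FST relevance percentile.
#' @param epsilon MAF no-change tolerance of the drift rule.
#' @param varld_window_snps,varld_step_snps varLD windowing.
#' @param varld_percentile varLD relevance percentile.
#' @param run_varld set FALSE to skip the varLD stage.
#' @return named list of `signature_set` objects (`ROH`, `FST`, `VARLD`)
#'   plus a `detail` list with the intermediate tables.
#' @export
run_scan <- function(g, cohorts, generation = 11L,
                     qc = qc_params(),
                     roh = roh_params(),
                     roh_min_count = 2L,
                     roh_fraction = 0.5,
                     fst_window_kb = 500, fst_step_kb = 250, fst_min_snps = 10L,
                     fst_percentile = 0.999,
                     epsilon = 0.01,
                     varld_window_snps = 50L, varld_step_snps = 1L,
                     varld_percentile = 0.999,
                     run_varld = TRUE) {
  if (!is.null(qc)) {
    g <- qc_filter(g, qc)$genotypes
  }
  s_base <- intersect(cohort_samples(cohorts, "BASE", 0L), g$sample_ids)
  s_high <- intersect(cohort_samples(cohorts, "HIGH", generation), g$sample_ids)
  s_low <- intersect(cohort_samples(cohorts, "LOW", generation), g$sample_ids)
  if (!length(s_high) || !length(s_low)) {
    stop("run_scan: empty line cohort at generation ", generation)
  }

  # ROH
  segs <- call_roh_all(g, roh, samples = c(s_high, s_low))
  line_of <- stats::setNames(
    c(rep("HIGH", length(s_high)), rep("LOW", length(s_low))),
    c(s_high, s_low)
  )
  cons <- consensus_roh(segs, g$markers, min_count = roh_min_count,
                        lines = line_of)
  roh_sig <- roh_signatures(cons, length(s_high), length(s_low),
                            fraction = roh_fraction)
  set_roh <- signature_set("ROH", roh_sig[, c("chrom", "start_bp", "end_bp")],
                           generation)

  # FST
  fst_win <- windowed_fst(g, s_high, s_low, fst_window_kb, fst_step_kb,
                          fst_min_snps)
  fst_sel <- fst_win[0, , drop = FALSE]
  fst_rel <- fst_win[0, , drop = FALSE]
  if (nrow(fst_win)) {
    fst_rel <- relevant_windows(fst_win, fst_percentile)
    fst_rel <- classify_selection_vs_drift(fst_rel, g, s_base, s_high, s_low,
                                           epsilon)
    fst_sel <- fst_rel[fst_rel$classification == "SELECTION", , drop = FALSE]
  }
  set_fst <- signature_set("FST", fst_sel[, c("chrom", "start_bp", "end_bp"), drop = FALSE],
                           generation)

  # varLD
  vl_detail <- NULL
  vl_sel <- data.frame(chrom = character(0), start_bp = integer(0),
                       end_bp = integer(0), stringsAsFactors = FALSE)
  if (run_varld) {
    cmp <- varld_comparisons(g, s_base, s_high, s_low,
                             varld_window_snps, varld_step_snps)
    vl <- varld_signatures(cmp, varld_percentile)
    vl_sel <- vl$selection
    vl_detail <- list(comparisons = cmp, intervals = vl)
  }
  set_vl <- signature_set("VARLD", vl_sel, generation)

  list(
    ROH = set_roh, FST = set_fst, VARLD = set_vl,
    detail = list(
      roh_segments = segs, roh_consensus = cons, roh_qualifying = roh_sig,
      fst_windows = fst_win, fst_relevant = fst_rel, varld = vl_detail,
      samples = list(base = s_base, high = s_high, low = s_low)
    )
  )
}

#' Validate a generation-11 scan against a generation-13 rerun
#'
#' Reruns the full scan on the later generation's cohorts (thresholds are
#' recomputed on that generation's own distributions) and validates each
#' method's putative set by same-method overlap.
#'
#' @param scan11 result of [run_scan()] on the earlier generation.
#' @param g a [genotype_matrix()] containing the later cohorts.
#' @param cohorts a [cohort_table()].
#' @param generation validation generation.
#' @param ... passed to [run_scan()] for the rerun.
#' @return list with `true_sets` (validated `signature_set`s) and `scan13`
#'   (the rerun).
#' @export
validate_scan <- function(scan11, g, cohorts, generation = 13L, ...) {
  scan13 <- run_scan(g, cohorts, generation = generation, ...)
  methods <- c("ROH", "FST", "VARLD")
  true_sets <- lapply(methods, function(m) {
    validate_signatures(scan11[[m]], scan13[[m]])
  })
  names(true_sets) <- methods
  list(true_sets = true_sets, scan13 = scan13)
}
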