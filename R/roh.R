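# Runs of homozygosity: per-individual scanning-window calls, per-line
# consensus regions, and the two-line 50% signature rule.

#' ROH-calling parameters
#'
#' Defaults follow the scanning-window algorithm in common use for array
#' data: 50-SNP windows allowing at most one heterozygote and no missing
#' call, a SNP is in a homozygous segment when at least 5% of the windows
#' covering it pass, runs split at gaps above 1 Mb, and a run is a ROH when
#' it holds at least 50 SNPs at a density of at least one SNP per 30 kb.
#'
#' @param window_snps SNPs per scanning window.
#' @param max_het_in_window maximum heterozygous calls tolerated per window.
#' @param max_missing_in_window maximum missing calls tolerated per window.
#' @param min_hom_window_fraction minimum fraction of passing windows
#'   covering a SNP for the SNP to qualify.
#' @param max_gap_kb maximum gap (kb) between consecutive qualifying SNPs of
#'   one run.
#' @param min_snps_in_roh minimum SNPs per reported ROH.
#' @param max_kb_per_snp maximum span-to-SNP ratio (kb per SNP) of a ROH.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50L,
                       max_het_in_window = 1L,
                       max_missing_in_window = 0L,
                       min_hom_window_fraction = 0.05,
                       max_gap_kb = 1000,
                       min_snps_in_roh = 50L,
                       max_kb_per_snp = 30) {
  p <- list(
    window_snps = as.integer(window_snps),
    max_het_in_window = as.integer(max_het_in_window),
    max_missing_in_window = as.integer(max_missing_in_window),
    min_hom_window_fraction = min_hom_window_fraction,
    max_gap_kb = max_gap_kb,
    min_snps_in_roh = as.integer(min_snps_in_roh),
    max_kb_per_snp = max_kb_per_snp
  )
  if (any(unlist(p) < 0)) stop("roh_params: parameters must be non-negative")
  class(p) <- "roh_params"
  p
}

empty_roh <- function() {
  data.frame(
    sample_id = character(0), chrom = character(0), start_bp = integer(0),
    end_bp = integer(0), n_snps = integer(0), stringsAsFactors = FALSE
  )
}

call_roh_chrom <- function(dosage, pos, chrom, sample_id, params) {
  m <- length(dosage)
  w <- params$window_snps
  if (m < w) {
    return(empty_roh())
  }
  het <- !is.na(dosage) & dosage == 1L
  miss <- is.na(dosage)
  hom <- !het & !miss
  # window start s covers SNPs s..s+w-1
  nw <- m - w + 1L
  cum_het <- c(0L, cumsum(het))
  cum_mis <- c(0L, cumsum(miss))
  het_cnt <- cum_het[(w + 1L):(m + 1L)] - cum_het[1:nw]
  mis_cnt <- cum_mis[(w + 1L):(m + 1L)] - cum_mis[1:nw]
  pass <- het_cnt <= params$max_het_in_window & mis_cnt <= params$max_missing_in_window
  cum_pass <- c(0L, cumsum(pass))
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  n_pass <- cum_pass[hi + 1L] - cum_pass[lo]
  n_win <- hi - lo + 1L
  qual <- hom & (n_pass / n_win >= params$min_hom_window_fraction)

  qi <- which(qual)
  if (!length(qi)) {
    return(empty_roh())
  }
  # break runs at non-consecutive indices or gaps above max_gap_kb
  brk <- c(TRUE, diff(qi) > 1L | diff(pos[qi]) > params$max_gap_kb * 1000)
  run_id <- cumsum(brk)
  segs <- lapply(split(qi, run_id), function(run) {
    n <- length(run)
    start <- pos[run[1]]
    end <- pos[run[n]]
    span_kb <- (end - start) / 1000
    if (n >= params$min_snps_in_roh && span_kb / n <= params$max_kb_per_snp) {
      data.frame(
        sample_id = sample_id, chrom = chrom, start_bp = start, end_bp = end,
        n_snps = n, stringsAsFactors = FALSE
      )
    } else {
      NULL
    }
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) {
    return(empty_roh())
  }
  do.call(rbind, segs)
}

#' Call runs of homozygosity for one individual
#'
#' Scanning-window algorithm per chromosome: (1) all windows of
#' `window_snps` consecutive SNPs are enumerated and pass when their
#' heterozygote and missing counts are within tolerance; (2) a SNP qualifies
#' when it is homozygous non-missing and the fraction of passing windows
#' covering it reaches `min_hom_window_fraction`; (3) maximal runs of
#' qualifying SNPs are split at gaps above `max_gap_kb`; (4) runs are
#' reported as ROH when they hold at least `min_snps_in_roh` SNPs at no more
#' than `max_kb_per_snp` kb per SNP. Segments carry the outermost SNP
#' positions. Chromosomes with fewer SNPs than one window yield no ROH.
#'
#' @param dosage integer vector of alt-allele dosages for one individual
#'   (NA = missing), aligned with `markers`.
#' @param markers a [marker_map()].
#' @param params a [roh_params()].
#' @param sample_id identifier recorded in the output.
#' @return data frame with sample_id, chrom, start_bp, end_bp, n_snps.
#' @export
call_roh <- function(dosage, markers, params = roh_params(),
                     sample_id = "sample") {
  idx <- chrom_index(markers)
  out <- lapply(names(idx), function(ch) {
    ii <- idx[[ch]]
    call_roh_chrom(dosage[ii], markers$pos_bp[ii], ch, sample_id, params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call ROH for every individual of a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param params a [roh_params()].
#' @param samples sample ids to process (default all).
#' @return data frame of segments across individuals.
#' @export
call_roh_all <- function(g, params = roh_params(), samples = NULL) {
  ids <- samples %||% g$sample_ids
  out <- lapply(ids, function(s) {
    call_roh(g$values[match(s, g$sample_ids), ], g$markers, params, s)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res %||% empty_roh()
}

#' Per-line consensus regions from individual ROH segments
#'
#' For each SNP the coverage count is the number of individuals whose ROH
#' covers its position; consensus regions are maximal runs of consecutive
#' SNPs with total coverage at least `min_count`. Region boundaries coincide
#' with marker positions. When a line assignment is supplied, the per-line
#' count of a region is the minimum per-SNP per-line coverage across the
#' region (the number of animals whose ROH spans the region at its weakest
#' SNP).
#'
#' @param segments data frame from [call_roh_all()].
#' @param markers a [marker_map()].
#' @param min_count minimum total coverage defining a consensus region.
#' @param lines optional named character vector mapping sample_id to
#'   `"HIGH"`/`"LOW"` for per-line counts.
#' @return data frame with chrom, start_bp, end_bp, n_snps, count,
#'   count_high, count_low.
#' @export
consensus_roh <- function(segments, markers, min_count = 2L, lines = NULL) {
  empty <- data.frame(
    chrom = character(0), start_bp = integer(0), end_bp = integer(0),
    n_snps = integer(0), count = integer(0), count_high = integer(0),
    count_low = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(segments) == 0L) {
    return(empty)
  }
  idx <- chrom_index(markers)
  out <- list()
  per_snp <- list()
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    pos <- markers$pos_bp[ii]
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(segs) == 0L) next
    cover <- function(rows) {
      cnt <- integer(length(pos))
      for (r in rows) {
        j <- which(pos >= segs$start_bp[r] & pos <= segs$end_bp[r])
        cnt[j] <- cnt[j] + 1L
      }
      cnt
    }
    cnt_all <- cover(seq_len(nrow(segs)))
    cnt_high <- cnt_low <- NULL
    if (!is.null(lines)) {
      cnt_high <- cover(which(lines[segs$sample_id] == "HIGH"))
      cnt_low <- cover(which(lines[segs$sample_id] == "LOW"))
    }
    qual <- cnt_all >= min_count
    qi <- which(qual)
    if (!length(qi)) next
    run_id <- cumsum(c(TRUE, diff(qi) > 1L))
    regs <- lapply(split(qi, run_id), function(run) {
      data.frame(
        chrom = ch,
        start_bp = pos[run[1]],
        end_bp = pos[run[length(run)]],
        n_snps = length(run),
        count = min(cnt_all[run]),
        count_high = if (is.null(cnt_high)) NA_integer_ else min(cnt_high[run]),
        count_low = if (is.null(cnt_low)) NA_integer_ else min(cnt_low[run]),
        stringsAsFactors = FALSE
      )
    })
    out <- c(out, regs)
    per_snp[[ch]] <- data.frame(
      chrom = ch, pos_bp = pos, count = cnt_all,
      count_high = if (is.null(cnt_high)) NA_integer_ else cnt_high,
      count_low = if (is.null(cnt_low)) NA_integer_ else cnt_low,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "per_snp") <- do.call(rbind, unname(per_snp))
  res
}

#' Consensus-ROH signature rule: regions shared by both lines
#'
#' A consensus region qualifies as a candidate signature when its per-line
#' counts reach the thresholds in both lines. Thresholds are either
#' `ceiling(fraction * line size)` or explicit absolute values.
#'
#' @param consensus data frame from [consensus_roh()] with per-line counts.
#' @param n_high,n_low line sizes.
#' @param fraction fraction of each line that must share the region
#'   (default 0.5).
#' @param thresholds optional explicit `c(high, low)` absolute thresholds
#'   overriding `fraction`.
#' @return subset of `consensus` that qualifies.
#' @export
roh_signatures <- function(consensus, n_high, n_low, fraction = 0.5,
                           thresholds = NULL) {
  if (is.null(thresholds)) {
    th_high <- ceiling(fraction * n_high)
    th_low <- ceiling(fraction * n_low)
  } else {
    th_high <- thresholds[1]
    th_low <- thresholds[2]
  }
  if (th_high > n_high || th_low > n_low) {
    warning("roh_signatures: thresholds exceed line sizes; empty result")
    return(consensus[0, , drop = FALSE])
  }
  per_snp <- attr(consensus, "per_snp")
  if (!is.null(per_snp)) {
    # refine at SNP resolution: maximal runs of consecutive SNPs where both
    # lines meet their thresholds (a coarse consensus region can hold a
    # qualifying core without qualifying end to end)
    out <- list()
    for (ch in unique(per_snp$chrom)) {
      ps <- per_snp[per_snp$chrom == ch, , drop = FALSE]
      qi <- which(ps$count_high >= th_high & ps$count_low >= th_low)
      if (!length(qi)) next
      run_id <- cumsum(c(TRUE, diff(qi) > 1L))
      out <- c(out, lapply(split(qi, run_id), function(run) {
        data.frame(
          chrom = ch,
          start_bp = ps$pos_bp[run[1]],
          end_bp = ps$pos_bp[run[length(run)]],
          n_snps = length(run),
          count = min(ps$count[run]),
          count_high = min(ps$count_high[run]),
          count_low = min(ps$count_low[run]),
          stringsAsFactors = FALSE
        )
      }))
    }
    res <- if (length(out)) do.call(rbind, out) else consensus[0, , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "per_snp") <- NULL
    return(res)
  }
  keep <- consensus$count_high >= th_high & consensus$count_low >= th_low
  res <- consensus[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
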