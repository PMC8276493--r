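# Windowed Weir-Cockerham FST between the two selected lines, percentile
# relevance calling, and the drift-versus-selection MAF rule.

#' Weir-Cockerham (1984) variance components for two populations
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of the two-population
#' (r = 2) estimator from per-population diploid sample sizes, allele
#' frequencies and observed heterozygote frequencies. The per-SNP estimate
#' is theta = a / (a + b + c) when the denominator is positive; for
#' (near-)monomorphic SNPs the ratio is undefined and `NaN` is returned.
#' All arguments are vectorized over SNPs.
#'
#' @param n1,n2 diploid sample sizes (non-missing individuals per SNP).
#' @param p1,p2 alternative-allele frequencies.
#' @param h1,h2 observed heterozygote frequencies.
#' @return data frame with columns `a`, `b`, `c`, `theta`.
#' @export
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  if (any(c(n1, n2) < 1)) stop("wc_components: sample sizes must be >= 1")
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom > 0, a / denom, NaN)
  data.frame(a = a, b = b, c = cc, theta = theta)
}

# tile [1, chrom_len] into sliding windows (bp); trailing partial windows
# kept (their SNP-count filter applies downstream)
window_starts <- function(max_pos, window_bp, step_bp) {
  if (max_pos <= window_bp) {
    return(1)
  }
  seq(1, max_pos, by = step_bp)
}

#' Windowed Weir-Cockerham FST between two cohorts
#'
#' Windows tile each chromosome from position 1 with the given width and
#' step. Per window, the weighted FST is the ratio of sums
#' `sum(a) / sum(a + b + c)` over SNPs with genotype data in both cohorts
#' (per-SNP sample sizes reflect missingness); windows with fewer than
#' `min_snps` such SNPs are excluded.
#'
#' @param g a [genotype_matrix()].
#' @param samples_pop1,samples_pop2 sample id vectors of the two cohorts.
#' @param window_kb window width in kb.
#' @param step_kb step size in kb.
#' @param min_snps minimum SNPs with data per window.
#' @return data frame with chrom, start_bp, end_bp, n_snps, weighted_fst.
#' @export
windowed_fst <- function(g, samples_pop1, samples_pop2,
                         window_kb = 500, step_kb = 250, min_snps = 10L) {
  if (!length(samples_pop1) || !length(samples_pop2)) {
    stop("windowed_fst: both cohorts must be non-empty")
  }
  i1 <- match(samples_pop1, g$sample_ids)
  i2 <- match(samples_pop2, g$sample_ids)
  if (anyNA(c(i1, i2))) stop("windowed_fst: unknown sample id(s)")
  v1 <- g$values[i1, , drop = FALSE]
  v2 <- g$values[i2, , drop = FALSE]
  n1 <- colSums(!is.na(v1))
  n2 <- colSums(!is.na(v2))
  ok <- n1 >= 1L & n2 >= 1L
  p1 <- colSums(v1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(v2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(v1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(v2 == 1L, na.rm = TRUE) / n2
  comp <- data.frame(a = rep(NA_real_, ncol(g$values)), b = NA_real_, c = NA_real_)
  if (any(ok)) {
    comp[ok, c("a", "b", "c")] <- wc_components(
      n1[ok], p1[ok], h1[ok], n2[ok], p2[ok], h2[ok]
    )[, c("a", "b", "c")]
  }
  win_bp <- window_kb * 1000
  step_bp <- step_kb * 1000
  idx <- chrom_index(g$markers)
  out <- list()
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    pos <- g$markers$pos_bp[ii]
    for (st in window_starts(max(pos), win_bp, step_bp)) {
      en <- st + win_bp - 1
      in_win <- ii[pos >= st & pos <= en]
      in_win <- in_win[ok[in_win]]
      if (length(in_win) < min_snps) next
      denom <- sum(comp$a[in_win] + comp$b[in_win] + comp$c[in_win])
      wfst <- if (denom > 0) sum(comp$a[in_win]) / denom else NA_real_
      if (is.na(wfst)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = st, end_bp = en, n_snps = length(in_win),
        weighted_fst = wfst, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    warning("windowed_fst: no eligible windows")
    return(data.frame(
      chrom = character(0), start_bp = numeric(0), end_bp = numeric(0),
      n_snps = integer(0), weighted_fst = numeric(0), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select windows at or above a genome-wide percentile
#'
#' The threshold is the linear-interpolation (type 7) percentile of the
#' weighted FST distribution over all windows; windows with a value equal
#' or above the threshold are returned. Negative estimates participate in
#' the distribution (no clamping).
#'
#' @param windows data frame from [windowed_fst()] (or any window table with
#'   a score column).
#' @param percentile genome-wide percentile (default 0.999).
#' @param score_col name of the score column.
#' @return subset of `windows`, with the threshold attached as attribute
#'   `"threshold"`.
#' @export
relevant_windows <- function(windows, percentile = 0.999,
                             score_col = "weighted_fst") {
  if (nrow(windows) < 1L) stop("relevant_windows: no windows")
  thr <- percentile_threshold(windows[[score_col]], percentile)
  res <- windows[windows[[score_col]] >= thr, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}

#' Classify a relevant window as selection or drift from MAF changes
#'
#' The tracked allele of each SNP is the minor allele in the base
#' population; the same allele is tracked in all three populations, and the
#' window-level frequency is the mean per-SNP tracked-allele frequency over
#' the window's SNPs that are polymorphic in the base population. With
#' changes `dh = f_high - f_base` and `dl = f_low - f_base`: if either line
#' is unchanged within `epsilon` the window is DRIFT; if both change in the
#' same direction it is DRIFT; opposite directions give SELECTION. Windows
#' with no polymorphic base SNP are UNCLASSIFIED.
#'
#' @param windows window table (chrom, start_bp, end_bp).
#' @param g a [genotype_matrix()].
#' @param samples_base,samples_high,samples_low cohort sample ids.
#' @param epsilon tolerance below which a frequency change counts as "no
#'   change".
#' @return `windows` with added columns maf_base, maf_high, maf_low,
#'   classification.
#' @export
classify_selection_vs_drift <- function(windows, g, samples_base,
                                        samples_high, samples_low,
                                        epsilon = 0.01) {
  f_base <- allele_freq(g, samples_base)
  f_high <- allele_freq(g, samples_high)
  f_low <- allele_freq(g, samples_low)
  # track the base-population minor allele at every SNP
  flip <- !is.na(f_base) & f_base > 0.5
  f_base[flip] <- 1 - f_base[flip]
  f_high[flip] <- 1 - f_high[flip]
  f_low[flip] <- 1 - f_low[flip]
  poly <- !is.na(f_base) & f_base > 0 & f_base < 1
  windows$maf_base <- NA_real_
  windows$maf_high <- NA_real_
  windows$maf_low <- NA_real_
  windows$classification <- "UNCLASSIFIED"
  if (nrow(windows) == 0L) {
    return(windows)
  }
  for (i in seq_len(nrow(windows))) {
    in_win <- which(
      g$markers$chrom == windows$chrom[i] &
        g$markers$pos_bp >= windows$start_bp[i] &
        g$markers$pos_bp <= windows$end_bp[i] &
        poly
    )
    if (!length(in_win)) next
    fb <- mean(f_base[in_win])
    fh <- mean(f_high[in_win], na.rm = TRUE)
    fl <- mean(f_low[in_win], na.rm = TRUE)
    windows$maf_base[i] <- fb
    windows$maf_high[i] <- fh
    windows$maf_low[i] <- fl
    dh <- fh - fb
    dl <- fl - fb
    windows$classification[i] <-
      if (abs(dh) <= epsilon || abs(dl) <= epsilon) {
        "DRIFT"
      } else if (sign(dh) == sign(dl)) {
        "DRIFT"
      } else {
        "SELECTION"
      }
  }
  windows
}
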