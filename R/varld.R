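# varLD: contrast of LD structure between two populations as the summed
# absolute difference of the sorted eigenvalues of windowed r2 matrices,
# standardized per chromosome, with the three-comparison selection/drift
# logic (Base-High, Base-Low, High-Low).

#' Pairwise r-squared matrix of a genotype window
#'
#' Entry (i, j) is the squared Pearson correlation of the dosage vectors of
#' SNPs i and j over pairwise-complete samples (composite, phase-free LD).
#' The diagonal is 1. SNPs with zero dosage variance get zero off-diagonal
#' entries; this keeps windows aligned across populations instead of
#' shrinking them.
#'
#' @param dos numeric matrix, samples x SNPs.
#' @return symmetric matrix of r-squared values.
#' @export
r2_matrix <- function(dos) {
  if (nrow(dos) < 2L) stop("r2_matrix: need at least 2 samples")
  suppressWarnings(
    cc <- stats::cor(dos, use = "pairwise.complete.obs")
  )
  cc[is.na(cc)] <- 0
  r2 <- cc^2
  diag(r2) <- 1
  r2
}

#' Raw varLD score of two r-squared matrices
#'
#' Eigenvalues of each matrix are sorted in descending order; the score is
#' the sum of absolute differences of the paired eigenvalues. Symmetric in
#' its arguments, zero iff the sorted spectra coincide.
#'
#' @param m1,m2 symmetric matrices of equal dimension.
#' @return non-negative scalar.
#' @export
varld_raw_score <- function(m1, m2) {
  if (!all(dim(m1) == dim(m2))) stop("varld_raw_score: dimension mismatch")
  l1 <- eigen(m1, symmetric = TRUE, only.values = TRUE)$values
  l2 <- eigen(m2, symmetric = TRUE, only.values = TRUE)$values
  sum(abs(l1 - l2))
}

#' Raw varLD scores along a chromosome for two populations
#'
#' Sliding windows of `window_snps` SNPs with a step of `step_snps` (one SNP
#' by default); trailing windows with fewer SNPs are dropped. Window
#' coordinates are the positions of the first and last SNP.
#'
#' @param g a [genotype_matrix()].
#' @param samples_pop1,samples_pop2 cohort sample ids.
#' @param window_snps SNPs per window.
#' @param step_snps step in SNPs.
#' @return data frame with chrom, start_bp, end_bp, first_snp_index,
#'   raw_score.
#' @export
varld_scores <- function(g, samples_pop1, samples_pop2,
                         window_snps = 50L, step_snps = 1L) {
  i1 <- match(samples_pop1, g$sample_ids)
  i2 <- match(samples_pop2, g$sample_ids)
  if (anyNA(c(i1, i2))) stop("varld_scores: unknown sample id(s)")
  idx <- chrom_index(g$markers)
  out <- list()
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    m <- length(ii)
    if (m < window_snps) next
    d1 <- g$values[i1, ii, drop = FALSE]
    d2 <- g$values[i2, ii, drop = FALSE]
    # full per-chromosome r2 once per population, windows sliced from it
    r1 <- r2_matrix(d1)
    r2m <- r2_matrix(d2)
    starts <- seq(1L, m - window_snps + 1L, by = step_snps)
    pos <- g$markers$pos_bp[ii]
    sc <- vapply(starts, function(s) {
      w <- s:(s + window_snps - 1L)
      varld_raw_score(r1[w, w], r2m[w, w])
    }, numeric(1))
    out[[ch]] <- data.frame(
      chrom = ch,
      start_bp = pos[starts],
      end_bp = pos[starts + window_snps - 1L],
      first_snp_index = starts,
      raw_score = sc,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    warning("varld_scores: no chromosome holds a full window")
    return(data.frame(
      chrom = character(0), start_bp = integer(0), end_bp = integer(0),
      first_snp_index = integer(0), raw_score = numeric(0)
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standardize varLD scores per chromosome
#'
#' Each chromosome's scores are centred by their mean and scaled by their
#' sample standard deviation (n - 1 denominator), so per-chromosome
#' standardized scores have mean 0 and sd 1. When all raw scores of a
#' chromosome are equal the standardized scores are set to 0 with a
#' warning.
#'
#' @param windows data frame from [varld_scores()].
#' @return `windows` with an added `std_score` column.
#' @export
standardize_scores <- function(windows) {
  windows$std_score <- NA_real_
  for (ch in unique(windows$chrom)) {
    i <- windows$chrom == ch
    if (sum(i) < 2L) stop("standardize_scores: need >= 2 windows per chromosome")
    x <- windows$raw_score[i]
    s <- stats::sd(x)
    if (s == 0) {
      warning("standardize_scores: constant scores on ", ch, "; std_score set to 0")
      windows$std_score[i] <- 0
    } else {
      windows$std_score[i] <- (x - mean(x)) / s
    }
  }
  windows
}

#' Compute standardized varLD scores for the three cohort comparisons
#'
#' @param g a [genotype_matrix()].
#' @param samples_base,samples_high,samples_low cohort sample ids.
#' @inheritParams varld_scores
#' @return named list of window tables (`BASE_HIGH`, `BASE_LOW`,
#'   `HIGH_LOW`), each with `std_score`.
#' @export
varld_comparisons <- function(g, samples_base, samples_high, samples_low,
                              window_snps = 50L, step_snps = 1L) {
  pairs <- list(
    BASE_HIGH = list(samples_base, samples_high),
    BASE_LOW = list(samples_base, samples_low),
    HIGH_LOW = list(samples_high, samples_low)
  )
  lapply(pairs, function(p) {
    standardize_scores(
      varld_scores(g, p[[1]], p[[2]], window_snps, step_snps)
    )
  })
}

#' Selection and drift intervals from the three varLD comparisons
#'
#' A window is relevant when its standardized score is equal or above the
#' genome-wide percentile threshold of its comparison. SELECTION intervals
#' are the base-pair intersections (>= 1 bp) of relevant Base-High windows
#' with relevant Base-Low windows; DRIFT intervals are relevant High-Low
#' windows overlapping neither relevant Base-High nor Base-Low windows.
#'
#' @param comparisons named list from [varld_comparisons()].
#' @param percentile genome-wide relevance percentile per comparison.
#' @return list with interval data frames `selection` and `drift`.
#' @export
varld_signatures <- function(comparisons, percentile = 0.999) {
  stopifnot(all(c("BASE_HIGH", "BASE_LOW", "HIGH_LOW") %in% names(comparisons)))
  rel <- lapply(comparisons, function(w) {
    if (nrow(w) == 0L) {
      return(w)
    }
    relevant_windows(w, percentile, score_col = "std_score")
  })
  gr_bh <- intervals_to_granges(rel$BASE_HIGH)
  gr_bl <- intervals_to_granges(rel$BASE_LOW)
  gr_hl <- intervals_to_granges(rel$HIGH_LOW)
  sel <- GenomicRanges::reduce(GenomicRanges::intersect(
    GenomicRanges::reduce(gr_bh), GenomicRanges::reduce(gr_bl)
  ))
  base_any <- GenomicRanges::reduce(c(gr_bh, gr_bl))
  hl_red <- GenomicRanges::reduce(gr_hl)
  if (length(hl_red) && length(base_any)) {
    hits <- GenomicRanges::findOverlaps(hl_red, base_any)
    drift <- hl_red[setdiff(seq_along(hl_red), unique(S4Vectors::queryHits(hits)))]
  } else {
    drift <- hl_red
  }
  list(
    selection = granges_to_intervals(sel),
    drift = granges_to_intervals(drift)
  )
}
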