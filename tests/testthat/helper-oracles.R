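# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results by direct enumeration / scalar formulas,
# not by calling the package's vectorized implementations.

random_gmatrix <- function(n_samples, n_snps, miss_rate = 0, n_chrom = 1) {
  vals <- matrix(
    sample(0:2, n_samples * n_snps, replace = TRUE),
    nrow = n_samples
  )
  if (miss_rate > 0) {
    vals[stats::runif(length(vals)) < miss_rate] <- NA_integer_
  }
  per <- ceiling(n_snps / n_chrom)
  chrom <- rep(sprintf("chr%d", seq_len(n_chrom)), each = per)[seq_len(n_snps)]
  pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(ii) {
    sort(sample.int(1e7, length(ii)))
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  mm <- marker_map(
    sprintf("snp%04d", seq_len(n_snps)), chrom, pos, ref, alt
  )
  # marker_map() sorts; build values aligned to the sorted map
  ord <- order(chrom, pos)
  genotype_matrix(vals[, ord, drop = FALSE],
                  sprintf("S%03d", seq_len(n_samples)), mm)
}

expect_same_gmatrix <- function(a, b) {
  testthat::expect_equal(a$sample_ids, b$sample_ids)
  testthat::expect_equal(as.data.frame(a$markers), as.data.frame(b$markers))
  testthat::expect_equal(unname(a$values), unname(b$values))
}

# literal per-definition QC filter
oracle_qc <- function(g, params) {
  keep_s <- logical(length(g$sample_ids))
  for (i in seq_along(g$sample_ids)) {
    keep_s[i] <- mean(!is.na(g$values[i, ])) >= params$min_sample_call_rate
  }
  vals <- g$values[keep_s, , drop = FALSE]
  keep_m <- logical(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    n_obs <- sum(!is.na(x))
    miss <- 1 - n_obs / length(x)
    if (n_obs == 0) {
      keep_m[j] <- FALSE
      next
    }
    p <- sum(x, na.rm = TRUE) / (2 * n_obs)
    maf <- min(p, 1 - p)
    keep_m[j] <- maf >= params$min_maf && miss <= params$max_snp_missing
  }
  list(samples = g$sample_ids[keep_s], snps = g$markers$snp_id[keep_m])
}

# literal four-step ROH definition by exhaustive window enumeration
oracle_roh <- function(dosage, pos, params) {
  m <- length(dosage)
  w <- params$window_snps
  segs <- data.frame(start_bp = integer(0), end_bp = integer(0),
                     n_snps = integer(0))
  if (m < w) return(segs)
  pass <- logical(m - w + 1)
  for (s in seq_len(m - w + 1)) {
    win <- dosage[s:(s + w - 1)]
    pass[s] <- sum(!is.na(win) & win == 1L) <= params$max_het_in_window &&
      sum(is.na(win)) <= params$max_missing_in_window
  }
  qual <- logical(m)
  for (i in seq_len(m)) {
    covering <- max(1, i - w + 1):min(i, m - w + 1)
    hom <- !is.na(dosage[i]) && dosage[i] != 1L
    qual[i] <- hom &&
      mean(pass[covering]) >= params$min_hom_window_fraction
  }
  run_start <- NA
  runs <- list()
  qi <- which(qual)
  if (!length(qi)) return(segs)
  cur <- qi[1]
  prev <- qi[1]
  members <- qi[1]
  for (i in qi[-1]) {
    if (i == prev + 1 && (pos[i] - pos[prev]) <= params$max_gap_kb * 1000) {
      members <- c(members, i)
    } else {
      runs[[length(runs) + 1]] <- members
      members <- i
    }
    prev <- i
  }
  runs[[length(runs) + 1]] <- members
  for (run in runs) {
    n <- length(run)
    span_kb <- (pos[run[n]] - pos[run[1]]) / 1000
    if (n >= params$min_snps_in_roh && span_kb / n <= params$max_kb_per_snp) {
      segs <- rbind(segs, data.frame(
        start_bp = pos[run[1]], end_bp = pos[run[n]], n_snps = n
      ))
    }
  }
  segs
}

# per-SNP coverage counting by direct loops
oracle_consensus <- function(segments, pos, min_count) {
  cnt <- integer(length(pos))
  for (r in seq_len(nrow(segments))) {
    cnt <- cnt + as.integer(pos >= segments$start_bp[r] &
                              pos <= segments$end_bp[r])
  }
  qual <- cnt >= min_count
  out <- data.frame(start_bp = integer(0), end_bp = integer(0))
  i <- 1
  while (i <= length(pos)) {
    if (qual[i]) {
      j <- i
      while (j < length(pos) && qual[j + 1]) j <- j + 1
      out <- rbind(out, data.frame(start_bp = pos[i], end_bp = pos[j]))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# independent scalar transcription of the two-population Weir-Cockerham
# variance components (loop form over populations)
oracle_wc <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# eigenvalues of a symmetric 3x3 matrix from its characteristic polynomial
oracle_eigen3 <- function(m) {
  stopifnot(all(dim(m) == c(3, 3)))
  tr <- sum(diag(m))
  minors <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) +
    (m[1, 1] * m[3, 3] - m[1, 3] * m[3, 1]) +
    (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2])
  dt <- det(m)
  # lambda^3 - tr lambda^2 + minors lambda - det = 0
  roots <- polyroot(c(-dt, minors, -tr, 1))
  sort(Re(roots), decreasing = TRUE)
}

# quadratic all-pairs interval overlap (1-based inclusive)
oracle_overlaps <- function(a, b) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
            a$start_bp[i] <= b$end_bp[j] && b$start_bp[j] <= a$end_bp[i]) {
        keep[i] <- TRUE
      }
    }
  }
  keep
}

# genotype columns with exact allele/heterozygote composition: n0 hom-ref,
# n1 het, n2 hom-alt individuals
dosage_column <- function(n0, n1, n2) {
  c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
}
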