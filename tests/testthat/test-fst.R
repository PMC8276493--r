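test_that("fixed difference between populations gives theta = 1 exactly", {
  for (n in c(2, 10, 50)) {
    comp <- wc_components(n, 1, 0, n, 0, 0)
    expect_equal(comp$a, 0.5)
    expect_equal(comp$b, 0)
    expect_equal(comp$c, 0)
    expect_equal(comp$theta, 1)
  }
})

test_that("shared monomorphism gives zero components and undefined theta", {
  comp <- wc_components(12, 0, 0, 20, 0, 0)
  expect_equal(comp$a, 0)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)
  expect_true(is.nan(comp$theta))
})

test_that("variance components match an independent transcription", {
  set.seed(101)
  for (i in 1:1000) {
    n1 <- sample(2:200, 1)
    n2 <- sample(2:200, 1)
    p1 <- runif(1)
    p2 <- runif(1)
    h1 <- runif(1, 0, 2 * min(p1, 1 - p1))
    h2 <- runif(1, 0, 2 * min(p2, 1 - p2))
    got <- wc_components(n1, p1, h1, n2, p2, h2)
    want <- oracle_wc(c(n1, n2), c(p1, p2), c(h1, h2))
    expect_lt(abs(got$a - want["a"]), 1e-12)
    expect_lt(abs(got$b - want["b"]), 1e-12)
    expect_lt(abs(got$c - want["c"]), 1e-12)
  }
})

test_that("windowed weighted FST equals the brute-force ratio of sums", {
  set.seed(17)
  g <- random_gmatrix(30, 30, miss_rate = 0.1, n_chrom = 1)
  pop1 <- g$sample_ids[1:15]
  pop2 <- g$sample_ids[16:30]
  win_kb <- 3000
  got <- windowed_fst(g, pop1, pop2, window_kb = win_kb, step_kb = win_kb / 2,
                      min_snps = 3L)
  for (k in seq_len(nrow(got))) {
    in_win <- which(g$markers$pos_bp >= got$start_bp[k] &
                      g$markers$pos_bp <= got$end_bp[k])
    num <- den <- 0
    n_used <- 0
    for (j in in_win) {
      x1 <- g$values[match(pop1, g$sample_ids), j]
      x2 <- g$values[match(pop2, g$sample_ids), j]
      x1 <- x1[!is.na(x1)]
      x2 <- x2[!is.na(x2)]
      if (!length(x1) || !length(x2)) next
      n_used <- n_used + 1
      comp <- oracle_wc(
        c(length(x1), length(x2)),
        c(mean(x1) / 2, mean(x2) / 2),
        c(mean(x1 == 1), mean(x2 == 1))
      )
      num <- num + comp["a"]
      den <- den + sum(comp)
    }
    expect_equal(got$n_snps[k], n_used)
    expect_equal(got$weighted_fst[k], unname(num / den), tolerance = 1e-12)
  }
  # symmetry in population order
  swapped <- windowed_fst(g, pop2, pop1, window_kb = win_kb,
                          step_kb = win_kb / 2, min_snps = 3L)
  expect_equal(got$weighted_fst, swapped$weighted_fst)
})

test_that("identical cohorts show no differentiation and never SELECTION", {
  set.seed(23)
  g <- random_gmatrix(20, 40, n_chrom = 1)
  ids <- g$sample_ids
  win <- windowed_fst(g, ids[1:20], ids[1:20], window_kb = 3000,
                      step_kb = 1500, min_snps = 3L)
  expect_true(all(win$weighted_fst <= 1e-12))
  rel <- relevant_windows(win)
  cls <- classify_selection_vs_drift(rel, g, ids, ids[1:20], ids[1:20])
  expect_false(any(cls$classification == "SELECTION"))
})

test_that("percentile relevance matches a sort-and-slice oracle", {
  set.seed(5)
  win <- data.frame(
    chrom = "chr1", start_bp = seq_len(1000), end_bp = seq_len(1000),
    n_snps = 10L, weighted_fst = stats::rnorm(1000)
  )
  got <- relevant_windows(win, 0.999)
  thr <- stats::quantile(win$weighted_fst, 0.999, type = 7, names = FALSE)
  want <- win[win$weighted_fst >= thr, ]
  expect_equal(got$weighted_fst, want$weighted_fst)
  # ties at the threshold are kept ("equal or above")
  all_equal <- transform(win, weighted_fst = 0.25)
  expect_equal(nrow(relevant_windows(all_equal, 0.999)), 1000L)
  # a single window is returned
  expect_equal(nrow(relevant_windows(win[1, ], 0.999)), 1L)
})

# build a genotype matrix whose three cohorts have prescribed per-SNP
# composition, to exercise the MAF change rule with known frequencies
freq_fixture <- function(base_comp, high_comp, low_comp, n_snps = 5) {
  cols_base <- replicate(n_snps, do.call(dosage_column, as.list(base_comp)))
  cols_high <- replicate(n_snps, do.call(dosage_column, as.list(high_comp)))
  cols_low <- replicate(n_snps, do.call(dosage_column, as.list(low_comp)))
  vals <- rbind(cols_base, cols_high, cols_low)
  n_b <- sum(base_comp)
  n_h <- sum(high_comp)
  n_l <- sum(low_comp)
  ids <- c(sprintf("B%02d", seq_len(n_b)), sprintf("H%02d", seq_len(n_h)),
           sprintf("L%02d", seq_len(n_l)))
  mm <- marker_map(sprintf("m%02d", seq_len(n_snps)), "chr1",
                   seq_len(n_snps) * 1000L, "A", "C")
  list(
    g = genotype_matrix(vals, ids, mm),
    base = ids[seq_len(n_b)],
    high = ids[n_b + seq_len(n_h)],
    low = ids[n_b + n_h + seq_len(n_l)]
  )
}

test_that("MAF change rule separates selection from drift", {
  win <- data.frame(chrom = "chr1", start_bp = 1L, end_bp = 10000L)
  # base 0.3, high 0.45, low 0.15: opposite shifts -> SELECTION
  fx <- freq_fixture(c(8, 12, 0), c(6, 10, 4), c(14, 6, 0))
  cls <- classify_selection_vs_drift(win, fx$g, fx$base, fx$high, fx$low)
  expect_equal(cls$maf_base, 0.3)
  expect_equal(cls$maf_high, 0.45)
  expect_equal(cls$maf_low, 0.15)
  expect_equal(cls$classification, "SELECTION")
  # both lines shift the same way -> DRIFT
  fx2 <- freq_fixture(c(8, 12, 0), c(6, 10, 4), c(6, 10, 4))
  cls2 <- classify_selection_vs_drift(win, fx2$g, fx2$base, fx2$high, fx2$low)
  expect_equal(cls2$classification, "DRIFT")
  # one line unchanged within epsilon -> DRIFT
  fx3 <- freq_fixture(c(8, 12, 0), c(8, 12, 0), c(14, 6, 0))
  cls3 <- classify_selection_vs_drift(win, fx3$g, fx3$base, fx3$high, fx3$low,
                                      epsilon = 0.01)
  expect_equal(cls3$classification, "DRIFT")
  # no polymorphic base SNP -> UNCLASSIFIED
  fx4 <- freq_fixture(c(20, 0, 0), c(6, 10, 4), c(14, 6, 0))
  cls4 <- classify_selection_vs_drift(win, fx4$g, fx4$base, fx4$high, fx4$low)
  expect_equal(cls4$classification, "UNCLASSIFIED")
})

test_that("the tracked allele is anchored to the base-population minor allele", {
  win <- data.frame(chrom = "chr1", start_bp = 1L, end_bp = 10000L)
  # alt is the base MAJOR allele (freq 0.7): tracking must flip to the
  # minor allele, so alt 0.55 -> tracked 0.45, alt 0.85 -> tracked 0.15
  fx <- freq_fixture(c(0, 12, 8), c(2, 14, 4), c(0, 6, 14))
  cls <- classify_selection_vs_drift(win, fx$g, fx$base, fx$high, fx$low)
  expect_equal(cls$maf_base, 0.3)
  expect_equal(cls$maf_high, 0.45)
  expect_equal(cls$maf_low, 0.15)
  expect_equal(cls$classification, "SELECTION")
})
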