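even_markers <- function(n, spacing_bp = 10e3, chrom = "chr1") {
  marker_map(sprintf("m%04d", seq_len(n)), chrom,
             as.integer(seq_len(n)) * as.integer(spacing_bp), "A", "C")
}

test_that("a fully homozygous chromosome yields one ROH spanning all SNPs", {
  mm <- even_markers(200)
  segs <- call_roh(rep(0L, 200), mm)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 200L)
  expect_equal(segs$start_bp, mm$pos_bp[1])
  expect_equal(segs$end_bp, mm$pos_bp[200])
})

test_that("alternating heterozygotes yield no ROH", {
  mm <- even_markers(200)
  dosage <- rep(c(0L, 1L), 100)
  expect_equal(nrow(call_roh(dosage, mm)), 0L)
})

test_that("chromosomes shorter than one window yield no windows and no ROH", {
  mm <- even_markers(20)
  expect_equal(nrow(call_roh(rep(0L, 20), mm)), 0L)
})

test_that("call_roh equals the exhaustive four-step brute force", {
  set.seed(42)
  params <- roh_params()
  for (rep in 1:8) {
    n <- 250
    pos <- sort(sample.int(6e6, n))
    # heterozygous background with a planted homozygous tract
    dosage <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                     prob = c(0.3, 0.4, 0.3))
    tract_start <- sample.int(n - 80, 1)
    tract <- tract_start:(tract_start + sample(55:75, 1))
    dosage[tract] <- sample(c(0L, 2L), length(tract), replace = TRUE)
    if (rep %% 2 == 0) dosage[sample.int(n, 3)] <- NA  # sprinkle missing
    mm <- marker_map(sprintf("m%04d", 1:n), "chr1", pos, "A", "C")
    got <- call_roh(dosage, mm, params)
    want <- oracle_roh(dosage, pos, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("ROH calls are invariant to ref/alt relabeling", {
  set.seed(8)
  n <- 300
  pos <- sort(sample.int(5e6, n))
  dosage <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.4, 0.2, 0.4))
  dosage[100:180] <- 2L
  mm <- marker_map(sprintf("m%04d", 1:n), "chr1", pos, "A", "C")
  a <- call_roh(dosage, mm)
  b <- call_roh(2L - dosage, mm)
  expect_equal(a, b)
})

test_that("every reported segment satisfies the ROH invariants", {
  set.seed(55)
  params <- roh_params()
  sim <- simulate_experiment(sim_config(
    n_chrom = 1L, chrom_len_bp = 6e6, snps_per_chrom = 500L,
    pop_size_per_line = 25L, generations_sampled = c(0L, 4L),
    cohort_sizes = list(base = 10L, high = 10L, low = 10L), seed = 19
  ))
  segs <- call_roh_all(sim$genotypes, params)
  if (nrow(segs)) {
    expect_true(all(segs$start_bp <= segs$end_bp))
    expect_true(all(segs$n_snps >= params$min_snps_in_roh))
    expect_true(all(
      (segs$end_bp - segs$start_bp) / 1000 / segs$n_snps <= params$max_kb_per_snp
    ))
  }
})

test_that("consensus counting equals brute-force per-SNP coverage", {
  set.seed(91)
  mm <- even_markers(150)
  pos <- mm$pos_bp
  segs <- do.call(rbind, lapply(1:12, function(i) {
    s <- sample.int(120, 1)
    e <- s + sample.int(25, 1)
    data.frame(sample_id = sprintf("S%02d", i), chrom = "chr1",
               start_bp = pos[s], end_bp = pos[min(e, 150)],
               n_snps = NA_integer_, stringsAsFactors = FALSE)
  }))
  for (mc in c(2L, 4L)) {
    got <- consensus_roh(segs, mm, min_count = mc)
    want <- oracle_consensus(segs, pos, mc)
    expect_equal(got$start_bp, want$start_bp)
    expect_equal(got$end_bp, want$end_bp)
  }
})

test_that("single-individual segments never form a min_count-2 consensus", {
  mm <- even_markers(100)
  segs <- data.frame(sample_id = "only", chrom = "chr1",
                     start_bp = mm$pos_bp[10], end_bp = mm$pos_bp[60],
                     n_snps = 51L)
  expect_equal(nrow(consensus_roh(segs, mm, min_count = 2L)), 0L)
  # two identical segment sets overlay to the segment itself
  segs2 <- rbind(segs, transform(segs, sample_id = "twin"))
  cons <- consensus_roh(segs2, mm, min_count = 2L)
  expect_equal(cons$start_bp, segs$start_bp)
  expect_equal(cons$end_bp, segs$end_bp)
})

test_that("the two-line signature rule matches direct predicate evaluation", {
  set.seed(3)
  n_high <- 140
  n_low <- 130
  cons <- data.frame(
    chrom = "chr1",
    start_bp = seq(1e5, by = 2e5, length.out = 30),
    end_bp = seq(1.5e5, by = 2e5, length.out = 30),
    n_snps = 10L,
    count = 0L,
    count_high = sample(0:140, 30, replace = TRUE),
    count_low = sample(0:130, 30, replace = TRUE)
  )
  cons$count <- cons$count_high + cons$count_low
  # explicit absolute thresholds
  got <- roh_signatures(cons, n_high, n_low, thresholds = c(70, 65))
  want <- cons[cons$count_high >= 70 & cons$count_low >= 65, ]
  expect_equal(got$start_bp, want$start_bp)
  # boundary: counts exactly at thresholds qualify; one failing line excludes
  one <- cons[1, ]
  one$count_high <- 70L; one$count_low <- 65L
  expect_equal(nrow(roh_signatures(one, n_high, n_low, thresholds = c(70, 65))), 1L)
  one$count_low <- 0L
  expect_equal(nrow(roh_signatures(one, n_high, n_low, thresholds = c(70, 65))), 0L)
  # fraction mode
  got_f <- roh_signatures(cons, n_high, n_low, fraction = 0.5)
  want_f <- cons[cons$count_high >= ceiling(0.5 * n_high) &
                   cons$count_low >= ceiling(0.5 * n_low), ]
  expect_equal(got_f$start_bp, want_f$start_bp)
  expect_warning(
    out <- roh_signatures(cons, 10, 10, thresholds = c(70, 65)),
    "exceed"
  )
  expect_equal(nrow(out), 0L)
})

test_that("a selection-fixed haplotype region is recovered as a shared signature", {
  # two single-origin standing variants in the same region, each favored in
  # one line, fix local haplotypes in both lines: the consensus rule should
  # recover an interval overlapping the planted region
  cfg <- sim_config(
    n_chrom = 1L, snps_per_chrom = 1500L, chrom_len_bp = 1e7, seed = 7,
    selected_loci = list(
      list(chrom = "chr1", pos_bp = 5e6, s = 0.5, favored_line = "HIGH",
           p0 = 0.5, mode = "one_line"),
      list(chrom = "chr1", pos_bp = 5.2e6, s = 0.5, favored_line = "LOW",
           p0 = 0.5, mode = "one_line")
    )
  )
  sim <- simulate_experiment(cfg)
  s_h <- cohort_samples(sim$cohorts, "HIGH", 11)
  s_l <- cohort_samples(sim$cohorts, "LOW", 11)
  segs <- call_roh_all(sim$genotypes, samples = c(s_h, s_l))
  lines <- stats::setNames(
    c(rep("HIGH", length(s_h)), rep("LOW", length(s_l))), c(s_h, s_l)
  )
  cons <- consensus_roh(segs, sim$genotypes$markers, min_count = 2L,
                        lines = lines)
  sig <- roh_signatures(cons, length(s_h), length(s_l), fraction = 0.5)
  expect_gt(nrow(sig), 0L)
  expect_true(any(sig$start_bp <= 5.2e6 & sig$end_bp >= 5e6))
})
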