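small_cfg <- function(seed, ...) {
  sim_config(
    n_chrom = 1L, chrom_len_bp = 5e6, snps_per_chrom = 200L,
    pop_size_per_line = 30L, generations_sampled = c(0L, 3L),
    cohort_sizes = list(base = 20L, high = 15L, low = 15L),
    seed = seed, ...
  )
}

test_that("simulation output is deterministic given the seed", {
  a <- simulate_experiment(small_cfg(5))
  b <- simulate_experiment(small_cfg(5))
  expect_same_gmatrix(a$genotypes, b$genotypes)
  expect_equal(a$truth$trajectories, b$truth$trajectories)
  d <- simulate_experiment(small_cfg(6))
  expect_false(identical(a$genotypes$values, d$genotypes$values))
})

test_that("simulated genotypes are valid dosage matrices on sorted markers", {
  sim <- simulate_experiment(small_cfg(9))
  v <- sim$genotypes$values
  expect_true(all(v %in% 0:2))
  m <- sim$genotypes$markers
  expect_true(all(tapply(m$pos_bp, m$chrom, function(p) all(diff(p) > 0))))
  expect_setequal(sim$cohorts$sample_id, sim$genotypes$sample_ids)
})

test_that("LD between SNP pairs decays with distance", {
  # mean r2 in increasing distance bins, averaged over replicates of the
  # base population
  set.seed(31)
  bins <- c(0, 2e5, 1e6, 5e6)
  acc <- matrix(0, nrow = 12, ncol = length(bins) - 1)
  for (rep in 1:12) {
    cfg <- sim_config(
      n_chrom = 1L, chrom_len_bp = 5e6, snps_per_chrom = 120L,
      pop_size_per_line = 40L, generations_sampled = 0L:0L,
      seed = 300 + rep
    )
    base <- simulate_base(cfg)
    g <- base$genotypes
    keep <- apply(g$values, 2, stats::var) > 0
    vals <- g$values[, keep]
    pos <- g$markers$pos_bp[keep]
    r2 <- suppressWarnings(stats::cor(vals))^2
    dist <- abs(outer(pos, pos, "-"))
    up <- upper.tri(r2)
    for (b in seq_len(length(bins) - 1)) {
      sel <- up & dist > bins[b] & dist <= bins[b + 1]
      acc[rep, b] <- mean(r2[sel], na.rm = TRUE)
    }
  }
  trend <- colMeans(acc)
  expect_true(all(diff(trend) <= 0))
})

test_that("neutral allele-frequency change matches the drift closed form", {
  # Var(p_t) ~ p0 (1 - p0) (1 - (1 - 1/(2N))^t) under pure drift
  set.seed(77)
  n_rep <- 50
  t_gen <- 5L
  n_pop <- 30L
  ratios <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    cfg <- sim_config(
      n_chrom = 1L, chrom_len_bp = 2e6, snps_per_chrom = 60L,
      pop_size_per_line = n_pop, generations_sampled = c(0L, t_gen),
      seed = 500 + rep
    )
    base <- simulate_base(cfg)
    ev <- evolve_line(base, cfg, "HIGH", t_gen)
    h0 <- ev$haps_by_gen[["0"]]
    ht <- ev$haps_by_gen[[as.character(t_gen)]]
    p0 <- colMeans(h0)
    pt <- colMeans(ht)
    keep <- p0 > 0.1 & p0 < 0.9
    ratios[rep] <- mean((pt[keep] - p0[keep])^2) /
      mean(p0[keep] * (1 - p0[keep]))
  }
  expected <- 1 - (1 - 1 / (2 * n_pop))^t_gen
  obs <- mean(ratios)
  mc_se <- stats::sd(ratios) / sqrt(n_rep)
  expect_lt(abs(obs - expected), max(3 * mc_se, 0.25 * expected))
})

test_that("strong divergent selection drives the favored allele near fixation", {
  # deterministic recursion p' = p (1 + s (p + 1)) / wbar predicts > 0.9
  # by generation 11 for s = 0.5, p0 = 0.5; the stochastic model should
  # reach that in >= 90% of replicates
  set.seed(99)
  n_rep <- 50
  hit <- logical(n_rep)
  for (rep in seq_len(n_rep)) {
    cfg <- sim_config(
      n_chrom = 1L, chrom_len_bp = 2e6, snps_per_chrom = 30L,
      pop_size_per_line = 100L, generations_sampled = c(0L, 11L),
      selected_loci = list(list(
        chrom = "chr1", pos_bp = 1e6, s = 0.5, favored_line = "HIGH", p0 = 0.5
      )),
      seed = 700 + rep
    )
    base <- simulate_base(cfg)
    ev <- evolve_line(base, cfg, "HIGH", 11L)
    final <- ev$trajectories$freq[ev$trajectories$generation == 11L]
    hit[rep] <- final > 0.9
  }
  expect_gte(mean(hit), 0.9)
})

test_that("divergent mode pushes the two lines in opposite directions", {
  cfg <- sim_config(
    n_chrom = 1L, chrom_len_bp = 2e6, snps_per_chrom = 30L,
    pop_size_per_line = 80L, generations_sampled = c(0L, 11L),
    selected_loci = list(list(
      chrom = "chr1", pos_bp = 1e6, s = 0.5, favored_line = "HIGH", p0 = 0.5
    )),
    seed = 41
  )
  sim <- simulate_experiment(cfg)
  tr <- subset(sim$truth$trajectories, generation == 11)
  expect_gt(tr$freq[tr$line == "HIGH"], 0.8)
  expect_lt(tr$freq[tr$line == "LOW"], 0.2)
})

test_that("mean final frequency increases with the selection coefficient", {
  set.seed(13)
  mean_final <- sapply(c(0, 0.1, 0.3, 0.5), function(s) {
    finals <- sapply(1:12, function(rep) {
      cfg <- sim_config(
        n_chrom = 1L, chrom_len_bp = 2e6, snps_per_chrom = 30L,
        pop_size_per_line = 50L, generations_sampled = c(0L, 8L),
        selected_loci = list(list(
          chrom = "chr1", pos_bp = 1e6, s = s, favored_line = "HIGH", p0 = 0.5
        )),
        seed = 900 + rep
      )
      base <- simulate_base(cfg)
      ev <- evolve_line(base, cfg, "HIGH", 8L)
      ev$trajectories$freq[ev$trajectories$generation == 8L]
    })
    mean(finals)
  })
  expect_true(all(diff(mean_final) > 0))
})

test_that("generation-13 cohorts descend from the generation-11 lineages", {
  cfg <- small_cfg(21)
  sim <- simulate_experiment(cfg)
  gens <- sort(unique(sim$cohorts$generation))
  expect_equal(gens, c(0L, 3L))
  # single continuous run: both sampled generations share one marker map
  expect_equal(nrow(sim$genotypes$markers), 200L)
})

test_that("annotated-variant fixture plants exactly the recoverable truth", {
  fx <- simulate_annotated_variants(20, 60, 5, seed = 3)
  hit <- fixed_divergent_functional_indels(fx$variants)
  expect_equal(
    hit[, c("chrom", "pos_bp", "ref", "alt")],
    fx$truth
  )
  # no plants -> empty
  fx0 <- simulate_annotated_variants(20, 40, 0, seed = 3)
  expect_equal(nrow(fixed_divergent_functional_indels(fx0$variants)), 0L)
  # determinism
  fx2 <- simulate_annotated_variants(20, 60, 5, seed = 3)
  expect_identical(fx$variants, fx2$variants)
})
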