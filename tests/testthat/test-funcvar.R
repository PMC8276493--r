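test_that("transcription-unit effects qualify as functional", {
  expect_true(is_functional("3'UTR"))
  expect_true(is_functional("3ʹUTR"))  # unicode prime tolerated
  expect_false(is_functional("intergenic"))
  expect_true(is_functional(c("intron", "missense")))  # any-match
  expect_false(is_functional("stop gained"))
  expect_true(is_functional("stop gained", extended = TRUE))
  expect_error(is_functional("nonsense_class"), "unknown effect class")
})

test_that("effect tabulation counts (variant, gene, effect) combinations", {
  v <- data.frame(
    chrom = c("c1", "c1", "c1"), pos_bp = c(10L, 10L, 50L),
    ref = "A", alt = "T", vtype = "SNV",
    gene_id = c("G1", "G2", "G1"),
    effect = c("missense", "upstream", "intron"),
    gt_low = "0/0", gt_high = "0/0"
  )
  tab <- tabulate_effects(v)
  expect_equal(tab$n_variants, 2L)     # one variant affects two genes
  expect_equal(tab$total_effects, 3L)
  expect_equal(tab$counts[["missense"]], 1L)
  expect_gte(tab$total_effects, tab$n_variants)
  empty <- tabulate_effects(v[0, ])
  expect_equal(empty$total_effects, 0L)
  expect_true(all(empty$counts == 0L))
})

test_that("effect tabulation equals a brute-force counter on random input", {
  set.seed(27)
  cls <- effect_classes()
  v <- data.frame(
    chrom = "c1",
    pos_bp = sample.int(50, 120, replace = TRUE),
    ref = "A", alt = "T", vtype = "SNV",
    gene_id = sample(sprintf("G%d", 1:6), 120, replace = TRUE),
    effect = sample(cls, 120, replace = TRUE),
    gt_low = "0/0", gt_high = "0/0"
  )
  tab <- tabulate_effects(v)
  key <- paste(v$chrom, v$pos_bp, v$ref, v$alt, v$gene_id, v$effect)
  uv <- v[!duplicated(key), ]
  for (cl in cls) {
    expect_equal(tab$counts[[cl]], sum(uv$effect == cl))
  }
  expect_equal(tab$total_effects, nrow(uv))
})

test_that("fixed-divergent detection requires disjoint homozygous genotypes", {
  expect_true(fixed_divergent("1/1", "2/2"))   # novel-allele fixation
  expect_true(fixed_divergent("0/0", "1/1"))
  expect_false(fixed_divergent("0/1", "1/1"))  # heterozygous
  expect_false(fixed_divergent("1/1", "1/1"))  # shared allele
  expect_false(fixed_divergent("1/1", "1/2"))
  expect_warning(out <- fixed_divergent("./.", "1/1"), "missing")
  expect_false(out)
  # symmetric in line order
  set.seed(81)
  gts <- c("0/0", "0/1", "1/1", "1/2", "2/2")
  for (i in 1:20) {
    a <- sample(gts, 1)
    b <- sample(gts, 1)
    expect_equal(fixed_divergent(a, b), fixed_divergent(b, a))
  }
})

test_that("candidate genes equal the brute-force interval join", {
  set.seed(14)
  fx <- simulate_annotated_variants(15, 80, 4, seed = 9)
  sig <- data.frame(chrom = "chr1",
                    start_bp = c(1e4, 2e5), end_bp = c(1.2e5, 3.5e5))
  got <- candidate_genes(fx$variants, sig)
  # brute force: functional variants inside any signature, per gene
  eff_fun <- fx$variants$effect %in% c("3'UTR", "5'UTR", "missense",
                                       "frameshift", "splicing")
  inside <- mapply(function(p) {
    any(p >= sig$start_bp & p <= sig$end_bp)
  }, fx$variants$pos_bp)
  keep <- eff_fun & inside & !is.na(fx$variants$gene_id)
  want_genes <- sort(unique(fx$variants$gene_id[keep]))
  expect_equal(got$gene_id, want_genes)
  if (nrow(got)) {
    expect_true(all(got$functional_variant_count >= 1L))
  }
  # variant outside all signatures never surfaces its gene
  far <- fx$variants[1, ]
  far$pos_bp <- 9e6L
  far$effect <- "missense"
  far$gene_id <- "FARGENE"
  expect_false("FARGENE" %in% candidate_genes(rbind(fx$variants, far), sig)$gene_id)
})

test_that("GO pathway percentages follow the keyword-dictionary rule", {
  # no keywords: everything in Other Processes
  pct <- go_pathway_percentages(letters[1:5], list())
  expect_equal(unname(pct[["Other Processes"]]), 100)
  # worked example: one immune keyword over two descriptions
  pct2 <- go_pathway_percentages(
    c("cytokine production", "nucleus"),
    list(immune = "cytokine")
  )
  expect_equal(unname(pct2[["immune"]]), 50)
  expect_equal(unname(pct2[["Other Processes"]]), 50)
  expect_error(go_pathway_percentages(character(0), list()), "N = 0")
})

test_that("first-match assignment sums to 100 and matches a brute matcher", {
  set.seed(6)
  dict <- list(
    immune = c("cytokine", "immune"),
    stress = c("stress", "cortisol"),
    metabolism = c("lipid", "glucose")
  )
  words <- c("cytokine storm", "immune tolerance", "stress response",
             "lipid transport", "glucose and stress", "dna repair",
             "cortisol signalling", "histone binding")
  desc <- sample(words, 60, replace = TRUE)
  pct <- go_pathway_percentages(desc, dict)
  expect_equal(sum(pct), 100)
  brute <- c(immune = 0, stress = 0, metabolism = 0, `Other Processes` = 0)
  for (d in tolower(desc)) {
    hit <- NA
    for (pw in names(dict)) {
      if (any(sapply(dict[[pw]], grepl, x = d, fixed = TRUE))) {
        hit <- pw
        break
      }
    }
    if (is.na(hit)) hit <- "Other Processes"
    brute[hit] <- brute[hit] + 1
  }
  expect_equal(as.numeric(pct), as.numeric(brute / length(desc) * 100))
  # multi-assignment can exceed 100 and is flagged
  pct_multi <- go_pathway_percentages(desc, dict, multi = TRUE)
  expect_gte(sum(pct_multi), 100)
  expect_true(attr(pct_multi, "multi_assignment"))
})

test_that("decoy records each fail exactly one filter criterion", {
  d <- decoy_variants()
  expect_gte(nrow(d), 8L)
  expect_equal(suppressWarnings(nrow(fixed_divergent_functional_indels(d))), 0L)
  # each decoy passes the other two criteria
  for (i in seq_len(nrow(d))) {
    fails <- c(
      indel = d$vtype[i] != "INDEL",
      functional = !is_functional(d$effect[i]),
      divergent = !suppressWarnings(fixed_divergent(d$gt_low[i], d$gt_high[i]))
    )
    expect_equal(sum(fails), 1L, info = paste("decoy", i))
  }
})
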