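# Wright-Fisher forward simulator of a divergent selection experiment.
#
# Founder haplotypes carry Beta-distributed allele frequencies; individual
# haplotypes are founder mosaics with Poisson crossovers (Haldane model), so
# LD decays with physical distance. Two lines evolve from a shared base
# population under multiplicative selection at planted loci and are sampled
# at configurable generations, mirroring a base / generation-11 /
# generation-13 cohort design.

#' Configure a divergent selection simulation
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len_bp chromosome length in base pairs.
#' @param snps_per_chrom SNPs per chromosome (positions uniform, deduplicated).
#' @param n_founder_haplotypes founder haplotypes the base mosaics are built
#'   from.
#' @param pop_size_per_line diploid population size of each selected line
#'   (the base population has twice this size so the lines can split from
#'   disjoint halves).
#' @param generations_sampled generations at which cohorts are drawn; must be
#'   sorted ascending and start at 0.
#' @param selected_loci list of loci, each a list with `chrom`, `pos_bp`,
#'   `s` (selection coefficient, >= 0), `favored_line` ("HIGH" or "LOW"),
#'   optional `p0` (founder alt-allele frequency to force) and optional
#'   `mode`: `"divergent"` (default; alt allele favored with coefficient `s`
#'   in `favored_line`, ref allele favored with the same coefficient in the
#'   other line, emulating two-sided divergent selection) or `"one_line"`
#'   (selection only in `favored_line`).
#' @param recomb_rate_cM_per_Mb recombination rate (centimorgan per megabase).
#' @param allele_freq_prior Beta shape pair for founder allele frequencies.
#' @param sweep_origin_age_gens when a selected locus forces a founder
#'   frequency `p0`, the favored allele is modelled as a standing variant of
#'   single mutational origin: every alt-carrying founder haplotype shares
#'   the donor haplotype around the locus over an identity-by-descent tract
#'   whose one-sided length is exponential with mean `1 / (age * r)` (the
#'   standard ancestral-haplotype decay after `age` generations at
#'   recombination rate `r`). Selection then refixes one local haplotype and
#'   leaves the homozygosity / differentiation / LD signature the scan
#'   methods target, sharpest at the focal SNP. Set to 0 to place the
#'   favored allele on unrelated founder backgrounds instead.
#' @param cohort_sizes named list: number of individuals sampled per cohort,
#'   `base` plus `high`/`low` vectors aligned with the selected generations in
#'   `generations_sampled`.
#' @param seed RNG seed; every simulation is deterministic given the config.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L,
                       chrom_len_bp = 5e7,
                       snps_per_chrom = 2000L,
                       n_founder_haplotypes = 40L,
                       pop_size_per_line = 100L,
                       generations_sampled = c(0L, 11L, 13L),
                       selected_loci = list(),
                       recomb_rate_cM_per_Mb = 1.0,
                       allele_freq_prior = c(0.5, 0.5),
                       sweep_origin_age_gens = 100,
                       cohort_sizes = NULL,
                       seed = 1L) {
  generations_sampled <- as.integer(sort(unique(generations_sampled)))
  if (generations_sampled[1] != 0L) {
    stop("sim_config: generations_sampled must start at 0")
  }
  if (snps_per_chrom < 2L) stop("sim_config: snps_per_chrom must be >= 2")
  if (pop_size_per_line < 2L) stop("sim_config: pop_size_per_line must be >= 2")
  for (loc in selected_loci) {
    if (is.null(loc$s) || loc$s < 0) stop("sim_config: selection coefficient s must be >= 0")
    if (!loc$favored_line %in% c("HIGH", "LOW")) {
      stop("sim_config: favored_line must be HIGH or LOW")
    }
  }
  sel_gens <- setdiff(generations_sampled, 0L)
  if (is.null(cohort_sizes)) {
    n <- pop_size_per_line
    cohort_sizes <- list(
      base = min(60L, 2L * n),
      high = pmin(n, rep(c(70L, 46L), length.out = length(sel_gens))),
      low = pmin(n, rep(c(65L, 49L), length.out = length(sel_gens)))
    )
  }
  structure(list(
    n_chrom = as.integer(n_chrom),
    chrom_len_bp = as.numeric(chrom_len_bp),
    snps_per_chrom = as.integer(snps_per_chrom),
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    pop_size_per_line = as.integer(pop_size_per_line),
    generations_sampled = generations_sampled,
    selected_loci = selected_loci,
    recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
    allele_freq_prior = allele_freq_prior,
    sweep_origin_age_gens = sweep_origin_age_gens,
    cohort_sizes = cohort_sizes,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# chromosome layout helpers -------------------------------------------------

chrom_index <- function(markers) {
  split(seq_len(nrow(markers)), markers$chrom)
}

# one recombinant gamete from a parent's two haplotypes; crossovers Poisson
# with the configured cM/Mb rate (Haldane: no interference)
make_gamete <- function(h1, h2, markers_by_chrom, pos_by_chrom, len_morgan) {
  out <- integer(length(h1))
  for (k in seq_along(markers_by_chrom)) {
    idx <- markers_by_chrom[[k]]
    n_xo <- stats::rpois(1, len_morgan[k])
    phase0 <- sample.int(2L, 1L) - 1L
    if (n_xo == 0L) {
      out[idx] <- if (phase0 == 0L) h1[idx] else h2[idx]
    } else {
      xo <- sort(stats::runif(n_xo, 0, 1))
      phase <- (phase0 + findInterval(pos_by_chrom[[k]], xo)) %% 2L
      out[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
    }
  }
  out
}

#' Simulate the base population
#'
#' SNP positions are drawn uniformly per chromosome, sorted and deduplicated.
#' Founder allele frequencies come from the configured Beta prior,
#' conditioned to be polymorphic among the founder haplotypes; base
#' individuals are founder mosaics so LD decays with distance. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `haplotypes` (2N_base x SNPs 0/1 matrix), `markers`
#'   (a [marker_map()]), `sel_idx` (marker column of each selected locus) and
#'   `genotypes` (the generation-0 [genotype_matrix()] of all base
#'   individuals).
#' @export
simulate_base <- function(config) {
  with_seed(config$seed, simulate_base_impl(config))
}

simulate_base_impl <- function(config) {
  n_chrom <- config$n_chrom
  m <- config$snps_per_chrom
  if (m > config$chrom_len_bp) {
    stop("simulate_base: more SNPs than distinct positions")
  }
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  pos_list <- lapply(seq_len(n_chrom), function(k) {
    p <- sort(unique(round(stats::runif(m * 1.2, 1, config$chrom_len_bp))))
    while (length(p) < m) {
      p <- sort(unique(c(p, round(stats::runif(m, 1, config$chrom_len_bp)))))
    }
    as.integer(sort(sample(p, m)))
  })
  markers <- marker_map(
    snp_id = unlist(lapply(seq_len(n_chrom), function(k) {
      sprintf("%s_snp%05d", chroms[k], seq_len(m))
    })),
    chrom = rep(chroms, each = m),
    pos_bp = unlist(pos_list),
    ref_allele = "A",
    alt_allele = "C"
  )
  n_snp <- nrow(markers)
  nf <- config$n_founder_haplotypes

  # founder allele frequencies, conditioned polymorphic among founders
  founders <- matrix(0L, nrow = nf, ncol = n_snp)
  sh <- config$allele_freq_prior
  for (j in seq_len(n_snp)) {
    repeat {
      p <- stats::rbeta(1, sh[1], sh[2])
      col <- stats::rbinom(nf, 1L, p)
      cs <- sum(col)
      if (cs > 0L && cs < nf) break
    }
    founders[, j] <- col
  }

  # force founder frequency at planted loci (snapped to the nearest SNP)
  sel_idx <- integer(0)
  if (length(config$selected_loci)) {
    sel_idx <- vapply(config$selected_loci, function(loc) {
      on_chrom <- which(markers$chrom == loc$chrom)
      if (!length(on_chrom)) stop("sim_config: selected locus on unknown chromosome")
      on_chrom[which.min(abs(markers$pos_bp[on_chrom] - loc$pos_bp))]
    }, integer(1))
    for (i in seq_along(sel_idx)) {
      p0 <- config$selected_loci[[i]]$p0
      if (!is.null(p0)) {
        k <- max(1L, min(nf - 1L, round(p0 * nf)))
        carriers <- sample.int(nf, k)
        age <- config$sweep_origin_age_gens %||% 0
        if (age > 0) {
          # single mutational origin: each carrier shares the donor's local
          # haplotype over an exponentially decaying IBD tract
          j <- sel_idx[i]
          r_per_bp <- config$recomb_rate_cM_per_Mb / 100 / 1e6
          mean_tract <- 1 / (age * r_per_bp)
          on_chrom <- which(markers$chrom == markers$chrom[j])
          donor <- carriers[1]
          for (cr in setdiff(carriers, donor)) {
            lo <- markers$pos_bp[j] - stats::rexp(1, 1 / mean_tract)
            hi <- markers$pos_bp[j] + stats::rexp(1, 1 / mean_tract)
            near <- on_chrom[markers$pos_bp[on_chrom] >= lo &
                               markers$pos_bp[on_chrom] <= hi]
            founders[cr, near] <- founders[donor, near]
          }
        }
        founders[, sel_idx[i]] <- 0L
        founders[carriers, sel_idx[i]] <- 1L
      }
    }
  }

  n_base <- 2L * config$pop_size_per_line
  mb <- chrom_index(markers)
  pos_rel <- lapply(seq_len(n_chrom), function(k) pos_list[[k]] / config$chrom_len_bp)
  len_morgan <- rep(
    config$chrom_len_bp / 1e6 * config$recomb_rate_cM_per_Mb / 100,
    n_chrom
  )
  haps <- matrix(0L, nrow = 2L * n_base, ncol = n_snp)
  for (h in seq_len(2L * n_base)) {
    i1 <- sample.int(nf, 1L)
    i2 <- sample.int(nf, 1L)
    haps[h, ] <- make_gamete(founders[i1, ], founders[i2, ], mb, pos_rel, len_morgan)
  }
  geno <- haps[seq(1L, 2L * n_base, by = 2L), , drop = FALSE] +
    haps[seq(2L, 2L * n_base, by = 2L), , drop = FALSE]
  g0 <- genotype_matrix(
    geno, sprintf("BASE_G0_%03d", seq_len(n_base)), markers
  )
  list(
    haplotypes = haps, markers = markers, sel_idx = sel_idx, genotypes = g0,
    pos_rel = pos_rel, len_morgan = len_morgan, markers_by_chrom = mb
  )
}

# fitness of each diploid individual in one line: multiplicative over loci,
# genotype dosage of the favored allele maps to (1, 1+s, 1+2s)
line_fitness <- function(haps, sel_idx, loci, line) {
  n_ind <- nrow(haps) / 2L
  w <- rep(1, n_ind)
  if (!length(sel_idx)) return(w)
  d1 <- haps[seq(1L, nrow(haps), by = 2L), sel_idx, drop = FALSE]
  d2 <- haps[seq(2L, nrow(haps), by = 2L), sel_idx, drop = FALSE]
  dos <- d1 + d2
  for (i in seq_along(loci)) {
    loc <- loci[[i]]
    mode <- loc$mode %||% "divergent"
    if (loc$favored_line == line) {
      fav_dos <- dos[, i]                  # alt allele favored
    } else if (mode == "divergent") {
      fav_dos <- 2L - dos[, i]             # ref allele favored in the other line
    } else {
      next                                 # one_line: neutral here
    }
    w <- w * (1 + loc$s * fav_dos)
  }
  w
}

#' Evolve one line forward under Wright-Fisher reproduction with selection
#'
#' Discrete non-overlapping generations at constant size; each offspring
#' draws two distinct parents with probability proportional to fitness and
#' receives one recombinant gamete from each. Allele-frequency trajectories
#' at the planted loci are recorded every generation. Fixation of all
#' fitness variation is allowed.
#'
#' @param pool result of [simulate_base()].
#' @param config a [sim_config()].
#' @param line `"HIGH"` or `"LOW"`.
#' @param n_generations number of generations to run.
#' @param start_haps optional haplotype matrix to start from (defaults to a
#'   disjoint half of the base population: HIGH takes the first half, LOW
#'   the second).
#' @return list with `haps_by_gen` (list: generation number as character ->
#'   2N x SNPs haplotype matrix) and `trajectories` (data frame: locus,
#'   line, generation, alt-allele frequency).
#' @export
evolve_line <- function(pool, config, line, n_generations,
                        start_haps = NULL) {
  n <- config$pop_size_per_line
  if (is.null(start_haps)) {
    ind <- if (line == "HIGH") seq_len(n) else n + seq_len(n)
    hap_rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    haps <- pool$haplotypes[hap_rows, , drop = FALSE]
  } else {
    haps <- start_haps
  }
  loci <- config$selected_loci
  sel_idx <- pool$sel_idx
  traj <- list()
  record <- function(h, gen) {
    if (!length(sel_idx)) return(NULL)
    data.frame(
      locus = seq_along(sel_idx), line = line, generation = gen,
      freq = colMeans(h[, sel_idx, drop = FALSE]),
      stringsAsFactors = FALSE
    )
  }
  traj[[1]] <- record(haps, 0L)
  haps_by_gen <- list("0" = haps)
  for (t in seq_len(n_generations)) {
    w <- line_fitness(haps, sel_idx, loci, line)
    prob <- if (sum(w) > 0) w / sum(w) else rep(1 / n, n)
    newh <- matrix(0L, nrow = 2L * n, ncol = ncol(haps))
    for (i in seq_len(n)) {
      par <- sample.int(n, 2L, replace = FALSE, prob = prob)
      for (k in 1:2) {
        p <- par[k]
        newh[2L * i - 2L + k, ] <- make_gamete(
          haps[2L * p - 1L, ], haps[2L * p, ],
          pool$markers_by_chrom, pool$pos_rel, pool$len_morgan
        )
      }
    }
    haps <- newh
    traj[[t + 1L]] <- record(haps, t)
    haps_by_gen[[as.character(t)]] <- haps
  }
  list(
    haps_by_gen = haps_by_gen,
    trajectories = if (length(sel_idx)) do.call(rbind, traj) else
      data.frame(locus = integer(0), line = character(0),
                 generation = integer(0), freq = numeric(0))
  )
}

haps_to_genotypes <- function(haps, ids, markers) {
  n <- nrow(haps) / 2L
  geno <- haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(geno, ids, markers)
}

#' Simulate a full divergent selection experiment
#'
#' Builds the base population, splits it into two disjoint lines, evolves
#' both through all sampled generations in a single continuous run (so
#' later cohorts descend from the same lineages as earlier ones), and draws
#' cohorts without replacement at each configured generation.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_result` with `genotypes` (combined
#'   [genotype_matrix()] of all cohorts), `cohorts` (a [cohort_table()]),
#'   `truth` (selected-locus definitions, their marker columns and realized
#'   trajectories) and `markers`.
#' @export
simulate_experiment <- function(config) {
  with_seed(config$seed, {
    pool <- simulate_base_impl(config)
    n_gen <- max(config$generations_sampled)
    high <- evolve_line(pool, config, "HIGH", n_gen)
    low <- evolve_line(pool, config, "LOW", n_gen)

    cs <- config$cohort_sizes
    sel_gens <- setdiff(config$generations_sampled, 0L)
    n_base_pop <- 2L * config$pop_size_per_line

    take <- function(haps, n_take, prefix) {
      n_ind <- nrow(haps) / 2L
      ind <- sort(sample.int(n_ind, min(n_take, n_ind)))
      rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
      haps_to_genotypes(
        haps[rows, , drop = FALSE],
        sprintf("%s_%03d", prefix, seq_along(ind)), pool$markers
      )
    }
    gmats <- list()
    coh <- list()
    gb <- take(pool$haplotypes, cs$base, "BASE_G0")
    gmats[[1]] <- gb
    coh[[1]] <- data.frame(
      sample_id = gb$sample_ids, line = "BASE", generation = 0L,
      stringsAsFactors = FALSE
    )
    for (i in seq_along(sel_gens)) {
      gen <- sel_gens[i]
      gh <- take(high$haps_by_gen[[as.character(gen)]], cs$high[i],
                 sprintf("HIGH_G%d", gen))
      gl <- take(low$haps_by_gen[[as.character(gen)]], cs$low[i],
                 sprintf("LOW_G%d", gen))
      gmats <- c(gmats, list(gh, gl))
      coh <- c(coh, list(
        data.frame(sample_id = gh$sample_ids, line = "HIGH", generation = gen,
                   stringsAsFactors = FALSE),
        data.frame(sample_id = gl$sample_ids, line = "LOW", generation = gen,
                   stringsAsFactors = FALSE)
      ))
    }
    all_vals <- do.call(rbind, lapply(gmats, function(g) g$values))
    all_ids <- unlist(lapply(gmats, function(g) g$sample_ids))
    cohdf <- do.call(rbind, coh)
    truth <- list(
      selected_loci = config$selected_loci,
      sel_idx = pool$sel_idx,
      sel_markers = pool$markers[pool$sel_idx, , drop = FALSE],
      trajectories = rbind(high$trajectories, low$trajectories)
    )
    structure(list(
      genotypes = genotype_matrix(all_vals, all_ids, pool$markers),
      cohorts = cohort_table(cohdf$sample_id, cohdf$line, cohdf$generation),
      truth = truth,
      markers = pool$markers
    ), class = "sim_result")
  })
}

# annotated-variant fixture -------------------------------------------------

#' Effect-class vocabulary for annotated variants
#'
#' The 14 recognized effect classes for transcription-effect annotation.
#'
#' @return character vector.
#' @export
effect_classes <- function() {
  c(
    "upstream", "downstream", "intergenic", "3'UTR", "5'UTR", "intron",
    "splicing", "synonymous", "missense", "frameshift", "inframe",
    "ncRNA exon", "stop gained", "start lost"
  )
}

#' Simulate an annotated variant table with planted fixed-divergent INDELs
#'
#' Emits a variant table (one row per variant-gene-effect), a gene interval
#' table, and a truth list naming exactly `n_planted_fixed_divergent`
#' variants that are INDELs with a transcription-unit effect (UTR, missense,
#' frameshift or splicing) and disjoint homozygous genotypes between the two
#' lines. All other variants are decoys drawn over the full effect-class
#' vocabulary and genotype space, excluded from the planted criteria.
#'
#' @param n_genes number of genes.
#' @param n_variants number of variants.
#' @param n_planted_fixed_divergent number of planted fixed-divergent
#'   functional INDELs (must be <= `n_variants`).
#' @param seed RNG seed.
#' @param chrom chromosome name for the fixture.
#' @return list with `variants` (annotated variant data frame), `genes`
#'   (gene interval data frame: gene_id, chrom, start_bp, end_bp) and
#'   `truth` (data frame of planted variant keys).
#' @export
simulate_annotated_variants <- function(n_genes, n_variants,
                                        n_planted_fixed_divergent,
                                        seed = 1L, chrom = "chr1") {
  if (n_planted_fixed_divergent > n_variants) {
    stop("simulate_annotated_variants: more planted variants than variants")
  }
  with_seed(seed, {
    gene_len <- 2e4
    gaps <- 1e4
    starts <- as.integer(round(seq(1, by = gene_len + gaps, length.out = n_genes)))
    genes <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(n_genes)),
      chrom = chrom,
      start_bp = starts,
      end_bp = as.integer(starts + gene_len - 1L),
      stringsAsFactors = FALSE
    )
    span <- max(genes$end_bp) + gaps
    pos <- sort(sample.int(span, n_variants))
    planted <- sort(sample.int(n_variants, n_planted_fixed_divergent))
    functional <- c("3'UTR", "5'UTR", "missense", "frameshift", "splicing")
    hom_pairs <- list(c("0/0", "1/1"), c("1/1", "0/0"), c("1/1", "2/2"), c("2/2", "1/1"))
    rows <- vector("list", n_variants)
    truth <- vector("list", n_planted_fixed_divergent)
    ti <- 0L
    for (i in seq_len(n_variants)) {
      is_planted <- i %in% planted
      if (is_planted) {
        gi <- sample.int(n_genes, 1L)
        p <- as.integer(sample(genes$start_bp[gi]:genes$end_bp[gi], 1L))
        eff <- sample(setdiff(functional, "missense"), 1L)  # INDEL-compatible
        gp <- hom_pairs[[sample.int(length(hom_pairs), 1L)]]
        vtype <- "INDEL"
        ref <- "AT"
        altv <- "A"
      } else {
        p <- pos[i]
        gi <- which(genes$start_bp <= p & genes$end_bp >= p)
        vtype <- sample(c("SNV", "INDEL"), 1L, prob = c(0.85, 0.15))
        if (length(gi) == 0L) {
          gi <- NA_integer_
          eff <- "intergenic"
        } else {
          gi <- gi[1]
          eff <- sample(setdiff(effect_classes(), "intergenic"), 1L)
        }
        # decoys never satisfy all three planted criteria at once: if the
        # effect is functional and the type INDEL, force a non-divergent
        # genotype pair
        divergent_ok <- !(eff %in% functional && vtype == "INDEL")
        gts <- c("0/0", "0/1", "1/1", "1/2", "2/2")
        repeat {
          gp <- sample(gts, 2L, replace = TRUE)
          if (divergent_ok || !is_fixed_divergent_pair(gp[1], gp[2])) break
        }
        ref <- if (vtype == "SNV") "A" else "AT"
        altv <- if (vtype == "SNV") "G" else "A"
      }
      gene_id <- if (is.na(gi)) NA_character_ else genes$gene_id[gi]
      rows[[i]] <- data.frame(
        chrom = chrom, pos_bp = as.integer(p), ref = ref, alt = altv,
        vtype = vtype, gene_id = gene_id, effect = eff,
        gt_low = gp[1], gt_high = gp[2], stringsAsFactors = FALSE
      )
      if (is_planted) {
        ti <- ti + 1L
        truth[[ti]] <- rows[[i]][, c("chrom", "pos_bp", "ref", "alt")]
      }
    }
    variants <- do.call(rbind, rows)
    variants <- variants[order(variants$pos_bp), , drop = FALSE]
    rownames(variants) <- NULL
    truth_df <- if (ti) do.call(rbind, truth) else
      data.frame(chrom = character(0), pos_bp = integer(0),
                 ref = character(0), alt = character(0))
    truth_df <- truth_df[order(truth_df$pos_bp), , drop = FALSE]
    rownames(truth_df) <- NULL
    list(variants = variants, genes = genes, truth = truth_df)
  })
}
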