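# Pipeline configuration and subcommand driver. The thin command-line
# wrapper at inst/cli/divsig.R dispatches onto run_subcommand().

#' Build a full pipeline configuration
#'
#' Every analysis parameter carries its standard default; any subset can be
#' overridden. The configuration round-trips through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param genotypes path to the genotype file (VCF or PLINK-text prefix).
#' @param genotype_format `"VCF"` or `"PLINK_TEXT"`.
#' @param cohorts path to the 3-column cohort TSV.
#' @param annotation path to a gene annotation (BED or GFF3).
#' @param annotation_format `"BED"` or `"GFF3"`.
#' @param variants path to an annotated variant TSV.
#' @param out_dir output directory.
#' @param seed RNG seed used by every stochastic stage.
#' @param sim named list of [sim_config()] overrides.
#' @param qc named list of [qc_params()] overrides.
#' @param roh named list of [roh_params()] overrides plus `min_count`,
#'   `fraction`, `thresholds`.
#' @param fst list: window_kb, step_kb, min_snps, percentile, epsilon.
#' @param varld list: window_snps, step_snps, percentile, run.
#' @param scan_generation,validate_generation cohort generations analysed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL,
                            genotype_format = "VCF",
                            cohorts = NULL,
                            annotation = NULL,
                            annotation_format = "BED",
                            variants = NULL,
                            out_dir = "divsig_out",
                            seed = 1L,
                            sim = list(),
                            qc = list(),
                            roh = list(),
                            fst = list(),
                            varld = list(),
                            scan_generation = 11L,
                            validate_generation = 13L) {
  cfg <- list(
    genotypes = genotypes,
    genotype_format = genotype_format,
    cohorts = cohorts,
    annotation = annotation,
    annotation_format = annotation_format,
    variants = variants,
    out_dir = out_dir,
    seed = as.integer(seed),
    sim = sim,
    qc = utils::modifyList(
      list(min_sample_call_rate = 0.97, min_maf = 0.05, max_snp_missing = 0.05),
      qc
    ),
    roh = utils::modifyList(
      list(
        window_snps = 50L, max_het_in_window = 1L, max_missing_in_window = 0L,
        min_hom_window_fraction = 0.05, max_gap_kb = 1000,
        min_snps_in_roh = 50L, max_kb_per_snp = 30,
        min_count = 2L, fraction = 0.5, thresholds = NULL
      ),
      roh
    ),
    fst = utils::modifyList(
      list(window_kb = 500, step_kb = 250, min_snps = 10L,
           percentile = 0.999, epsilon = 0.01),
      fst
    ),
    varld = utils::modifyList(
      list(window_snps = 50L, step_snps = 1L, percentile = 0.999, run = TRUE),
      varld
    ),
    scan_generation = as.integer(scan_generation),
    validate_generation = as.integer(validate_generation)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @return `path` / the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[names(raw) %in% names(formals(pipeline_config))])
}

cfg_roh_params <- function(cfg) {
  do.call(roh_params, cfg$roh[names(cfg$roh) %in% names(formals(roh_params))])
}

write_provenance <- function(config, out_dir, command) {
  inputs <- Filter(
    function(p) is.character(p) && length(p) == 1L && file.exists(p),
    list(
      genotypes = config$genotypes, cohorts = config$cohorts,
      annotation = config$annotation, variants = config$variants
    )
  )
  prov <- list(
    command = command,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("divsig")),
    r_version = as.character(getRversion()),
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
    config = unclass(config)
  )
  yaml::write_yaml(prov, file.path(out_dir, sprintf("provenance_%s.yaml", command)))
}

load_inputs <- function(config) {
  if (is.null(config$genotypes) || !file.exists(paths_first(config$genotypes, config$genotype_format))) {
    stop("usage: genotype input not found: ", config$genotypes %||% "<missing>")
  }
  if (is.null(config$cohorts) || !file.exists(config$cohorts)) {
    stop("usage: cohort table not found: ", config$cohorts %||% "<missing>")
  }
  list(
    g = read_genotypes(config$genotypes, config$genotype_format),
    cohorts = read_cohorts(config$cohorts)
  )
}

paths_first <- function(path, format) {
  if (format == "PLINK_TEXT") paste0(path, ".ped") else path
}

scan_from_config <- function(g, cohorts, config, generation) {
  run_scan(
    g, cohorts,
    generation = generation,
    qc = do.call(qc_params, config$qc),
    roh = cfg_roh_params(config),
    roh_min_count = config$roh$min_count,
    roh_fraction = config$roh$fraction,
    fst_window_kb = config$fst$window_kb,
    fst_step_kb = config$fst$step_kb,
    fst_min_snps = config$fst$min_snps,
    fst_percentile = config$fst$percentile,
    epsilon = config$fst$epsilon,
    varld_window_snps = config$varld$window_snps,
    varld_step_snps = config$varld$step_snps,
    varld_percentile = config$varld$percentile,
    run_varld = isTRUE(config$varld$run)
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_scan_outputs <- function(scan, out_dir, tag) {
  paths <- character(0)
  for (m in c("ROH", "FST", "VARLD")) {
    p <- file.path(out_dir, sprintf("%s_%s.bed", tolower(m), tag))
    write_bed(scan[[m]]$intervals, p)
    paths <- c(paths, p)
  }
  d <- scan$detail
  paths <- c(
    paths,
    write_tsv(d$roh_segments, file.path(out_dir, sprintf("roh_segments_%s.tsv", tag))),
    write_tsv(d$roh_consensus, file.path(out_dir, sprintf("roh_consensus_%s.tsv", tag))),
    write_tsv(d$fst_windows, file.path(out_dir, sprintf("fst_windows_%s.tsv", tag)))
  )
  if (nrow(d$fst_relevant)) {
    paths <- c(paths, write_tsv(
      d$fst_relevant,
      file.path(out_dir, sprintf("fst_relevant_%s.tsv", tag))
    ))
  }
  if (!is.null(d$varld)) {
    for (cmp in names(d$varld$comparisons)) {
      paths <- c(paths, write_tsv(
        d$varld$comparisons[[cmp]],
        file.path(out_dir, sprintf("varld_%s_%s.tsv", tolower(cmp), tag))
      ))
    }
  }
  paths
}

#' Run one pipeline subcommand
#'
#' Subcommands: `simulate` (write a synthetic experiment), `qc` (filter and
#' rewrite genotypes), `roh` / `fst` / `varld` (single-method scans),
#' `scan` (all three methods on the scan generation), `validate` (scan +
#' rerun on the validation generation + same-method intersection),
#' `funcvar` (fixed-divergent functional filter and candidate genes against
#' the validated signatures), `report` (merged intervals and gene overlay).
#' Every run writes a provenance YAML (config copy, seed, versions, input
#' checksums) into the output directory; outputs are deterministic given
#' config + seed.
#'
#' @param name subcommand name.
#' @param config a [pipeline_config()].
#' @return named list of output paths, invisibly.
#' @export
run_subcommand <- function(name, config) {
  name <- match.arg(name, c(
    "simulate", "qc", "roh", "fst", "varld", "scan", "validate",
    "funcvar", "report"
  ))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  divsig_log("subcommand %s: seed=%d out=%s", name, config$seed, out_dir)
  paths <- list()

  if (name == "simulate") {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    sc <- do.call(sim_config, sim_args)
    sim <- simulate_experiment(sc)
    paths$genotypes <- file.path(out_dir, "genotypes.vcf")
    write_genotypes(sim$genotypes, paths$genotypes, "VCF")
    paths$cohorts <- file.path(out_dir, "cohorts.tsv")
    write_cohorts(sim$cohorts, paths$cohorts)
    paths$truth <- write_tsv(sim$truth$trajectories,
                             file.path(out_dir, "truth_trajectories.tsv"))
    if (nrow(sim$truth$sel_markers)) {
      paths$truth_loci <- write_tsv(sim$truth$sel_markers,
                                    file.path(out_dir, "truth_loci.tsv"))
    }
  } else if (name == "qc") {
    inp <- load_inputs(config)
    res <- qc_filter(inp$g, do.call(qc_params, config$qc))
    print(res$report)
    paths$genotypes <- file.path(out_dir, "genotypes_qc.vcf")
    write_genotypes(res$genotypes, paths$genotypes, "VCF")
    paths$report <- file.path(out_dir, "qc_report.tsv")
    write_qc_report(res$report, paths$report)
  } else if (name %in% c("roh", "fst", "varld", "scan")) {
    inp <- load_inputs(config)
    cfg2 <- config
    if (name != "scan") {
      cfg2$varld$run <- name == "varld"
    }
    scan <- scan_from_config(inp$g, inp$cohorts, cfg2, config$scan_generation)
    tag <- sprintf("gen%d", config$scan_generation)
    paths$outputs <- write_scan_outputs(scan, out_dir, tag)
  } else if (name == "validate") {
    inp <- load_inputs(config)
    scan11 <- scan_from_config(inp$g, inp$cohorts, config, config$scan_generation)
    val <- validate_scan_from_config(scan11, inp$g, inp$cohorts, config)
    paths$outputs <- c(
      write_scan_outputs(scan11, out_dir, sprintf("gen%d", config$scan_generation)),
      write_scan_outputs(val$scan13, out_dir, sprintf("gen%d", config$validate_generation))
    )
    for (m in names(val$true_sets)) {
      p <- file.path(out_dir, sprintf("%s_true.bed", tolower(m)))
      write_bed(val$true_sets[[m]]$intervals, p)
      paths[[paste0("true_", tolower(m))]] <- p
    }
    rep <- merge_and_report(val$true_sets, load_annotation(config))
    paths$union <- file.path(out_dir, "true_union.bed")
    write_bed(rep$union, paths$union)
    paths$summary <- write_tsv(
      data.frame(method = names(rep$counts), n_true = as.integer(rep$counts)),
      file.path(out_dir, "true_counts.tsv")
    )
    if (length(rep$genes)) {
      paths$genes <- write_tsv(data.frame(gene_id = rep$genes),
                               file.path(out_dir, "true_signature_genes.tsv"))
    }
  } else if (name == "funcvar") {
    if (is.null(config$variants) || !file.exists(config$variants)) {
      stop("usage: annotated variant table not found: ",
           config$variants %||% "<missing>")
    }
    v <- read_annotated_variants(config$variants)
    union_bed <- file.path(out_dir, "true_union.bed")
    sig <- if (file.exists(union_bed)) read_bed(union_bed) else NULL
    fd <- fixed_divergent_functional_indels(v)
    paths$fixed_divergent <- write_tsv(
      fd, file.path(out_dir, "fixed_divergent_functional_indels.tsv")
    )
    tab <- tabulate_effects(v)
    paths$effects <- write_tsv(
      data.frame(effect = names(tab$counts), count = tab$counts,
                 row.names = NULL),
      file.path(out_dir, "effect_counts.tsv")
    )
    if (!is.null(sig)) {
      cg <- candidate_genes(v, sig)
      paths$candidates <- write_tsv(
        cg, file.path(out_dir, "candidate_genes.tsv")
      )
    } else {
      divsig_log("no true_union.bed in %s; candidate genes skipped", out_dir,
                 level = "WARN")
    }
  } else if (name == "report") {
    beds <- Filter(file.exists, stats::setNames(
      file.path(out_dir, sprintf("%s_true.bed", c("roh", "fst", "varld"))),
      c("ROH", "FST", "VARLD")
    ))
    if (!length(beds)) stop("usage: no validated signature BEDs in ", out_dir)
    sets <- lapply(names(beds), function(m) {
      signature_set(m, read_bed(beds[[m]]), config$validate_generation, "TRUE")
    })
    rep <- merge_and_report(sets, load_annotation(config))
    paths$union <- file.path(out_dir, "true_union.bed")
    write_bed(rep$union, paths$union)
    paths$summary <- write_tsv(
      data.frame(method = names(rep$counts), n_true = as.integer(rep$counts)),
      file.path(out_dir, "true_counts.tsv")
    )
    if (length(rep$genes)) {
      paths$genes <- write_tsv(data.frame(gene_id = rep$genes),
                               file.path(out_dir, "true_signature_genes.tsv"))
    }
  }
  write_provenance(config, out_dir, name)
  invisible(paths)
}

load_annotation <- function(config) {
  if (is.null(config$annotation) || !file.exists(config$annotation)) {
    return(NULL)
  }
  read_gene_annotation(config$annotation, config$annotation_format)
}

validate_scan_from_config <- function(scan11, g, cohorts, config) {
  scan13 <- scan_from_config(g, cohorts, config, config$validate_generation)
  methods <- c("ROH", "FST", "VARLD")
  true_sets <- stats::setNames(lapply(methods, function(m) {
    validate_signatures(scan11[[m]], scan13[[m]])
  }), methods)
  list(true_sets = true_sets, scan13 = scan13)
}
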