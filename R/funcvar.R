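# Prioritization of functional mutations inside true signatures: effect
# filtering, effect tabulation, fixed-divergent detection, candidate genes
# and keyword-dictionary GO pathway percentages.
#
# Line genotypes are pool consensus calls printed as a diploid-style pair
# over {0 = reference allele, 1 = alternative allele, 2 = novel allele
# absent from the reference genome}.

normalize_effect <- function(x) {
  # tolerate unicode primes and case variants of the UTR classes
  x <- gsub("ʹ|′", "'", x)
  x <- sub("^3'\\s*UTR$", "3'UTR", x, ignore.case = TRUE)
  x <- sub("^5'\\s*UTR$", "5'UTR", x, ignore.case = TRUE)
  low <- tolower(x)
  canon <- effect_classes()
  out <- canon[match(low, tolower(canon))]
  if (anyNA(out)) {
    stop("unknown effect class string(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read an annotated variant table
#'
#' Flat TSV with one row per (variant, gene, effect): columns chrom (or
#' OCU), pos_bp (or bp), ref, alt, vtype, gene_id (or Gene), effect (or
#' Region), gt_low (or Low), gt_high (or High). Effect strings must belong
#' to the recognized vocabulary (see [effect_classes()]); unknown strings
#' raise an error naming the string.
#'
#' @param path TSV path.
#' @return annotated variant data frame.
#' @export
read_annotated_variants <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  ren <- c(
    OCU = "chrom", bp = "pos_bp", Low = "gt_low", High = "gt_high",
    Region = "effect", Gene = "gene_id", Mutation = "mutation"
  )
  for (old in names(ren)) {
    if (old %in% names(df) && !(ren[[old]] %in% names(df))) {
      names(df)[names(df) == old] <- ren[[old]]
    }
  }
  need <- c("chrom", "pos_bp", "effect", "gt_low", "gt_high")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_annotated_variants: missing column(s): ", paste(miss, collapse = ", "))
  }
  df$chrom <- as.character(df$chrom)
  df$pos_bp <- as.integer(df$pos_bp)
  df$effect <- normalize_effect(df$effect)
  if (!"vtype" %in% names(df)) {
    # Table-2 style input: infer the variant type from the mutation column
    if ("mutation" %in% names(df)) {
      df$vtype <- ifelse(grepl("insertion|deletion|indel", df$mutation,
                               ignore.case = TRUE), "INDEL", "SNV")
    } else {
      stop("read_annotated_variants: need a vtype or Mutation column")
    }
  }
  df$vtype <- toupper(df$vtype)
  if (!all(df$vtype %in% c("SNV", "INDEL"))) {
    stop("read_annotated_variants: vtype must be SNV or INDEL")
  }
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  if (!"ref" %in% names(df)) df$ref <- NA_character_
  if (!"alt" %in% names(df)) df$alt <- NA_character_
  df
}

variant_key <- function(v) {
  paste(v$chrom, v$pos_bp, v$ref, v$alt, sep = ":")
}

#' Transcription-unit functional effect classes
#'
#' @param extended when TRUE, `stop gained`, `start lost` and `inframe`
#'   also qualify; the default keeps strictly the UTR / missense /
#'   frameshift / splicing criteria.
#' @return character vector of qualifying effect classes.
#' @export
functional_classes <- function(extended = FALSE) {
  base <- c("3'UTR", "5'UTR", "missense", "frameshift", "splicing")
  if (extended) c(base, "stop gained", "start lost", "inframe") else base
}

#' Is a variant's effect set functional (in a transcription unit)?
#'
#' TRUE iff any effect class is a UTR, missense, frameshift or splicing
#' annotation (optionally extended, see [functional_classes()]).
#'
#' @param effects character vector of effect classes carried by one variant.
#' @param extended see [functional_classes()].
#' @return logical scalar.
#' @export
is_functional <- function(effects, extended = FALSE) {
  any(normalize_effect(effects) %in% functional_classes(extended))
}

#' Tabulate effects per class
#'
#' Counts effects, not variants: each distinct (variant, gene, effect)
#' combination contributes once, so a variant annotated on two genes counts
#' twice in the total.
#'
#' @param variants annotated variant data frame (one row per
#'   variant-gene-effect).
#' @return list with `counts` (named integer vector over
#'   [effect_classes()]), `total_effects` and `n_variants`.
#' @export
tabulate_effects <- function(variants) {
  classes <- effect_classes()
  if (nrow(variants) == 0L) {
    return(list(
      counts = stats::setNames(integer(length(classes)), classes),
      total_effects = 0L, n_variants = 0L
    ))
  }
  eff <- normalize_effect(variants$effect)
  uniq <- !duplicated(paste(variant_key(variants), variants$gene_id, eff))
  tab <- table(factor(eff[uniq], levels = classes))
  list(
    counts = stats::setNames(as.integer(tab), classes),
    total_effects = sum(uniq),
    n_variants = length(unique(variant_key(variants)))
  )
}

is_fixed_divergent_pair <- function(gt_low, gt_high) {
  parse <- function(gt) {
    if (is.na(gt) || !nzchar(gt)) {
      return(NULL)
    }
    a <- strsplit(gt, "[/|]")[[1]]
    if (length(a) != 2L || any(a == ".")) {
      return(NULL)
    }
    a
  }
  al <- parse(gt_low)
  ah <- parse(gt_high)
  if (is.null(al) || is.null(ah)) {
    warning("fixed_divergent: missing line genotype; returning FALSE")
    return(FALSE)
  }
  hom_l <- al[1] == al[2]
  hom_h <- ah[1] == ah[2]
  hom_l && hom_h && length(intersect(al, ah)) == 0L
}

#' Is a variant fixed divergently between the two lines?
#'
#' TRUE iff both line genotypes are homozygous and share no allele: this
#' covers 1/1 vs 0/0 (alternative fixed in one line, absent in the other)
#' and 1/1 vs 2/2 (a novel allele absent from the reference fixed in one
#' line). Symmetric in line order; a missing line genotype gives FALSE with
#' a warning.
#'
#' @param gt_low,gt_high line genotype strings such as `"0/0"`, `"1/1"`,
#'   `"2/2"` (vectorized).
#' @return logical vector.
#' @export
fixed_divergent <- function(gt_low, gt_high) {
  mapply(is_fixed_divergent_pair, gt_low, gt_high, USE.NAMES = FALSE)
}

#' The fixed-divergent functional INDEL filter
#'
#' Selects variants that are (1) INDELs, (2) functional in a transcription
#' unit per [is_functional()], and (3) fixed divergently between the lines
#' per [fixed_divergent()]. This is the prioritization used to surface the
#' strongest candidate mutations.
#'
#' @param variants annotated variant data frame.
#' @param extended see [functional_classes()].
#' @return data frame of passing variants, one row per variant (key =
#'   chrom:pos:ref:alt).
#' @export
fixed_divergent_functional_indels <- function(variants, extended = FALSE) {
  if (nrow(variants) == 0L) {
    return(variants)
  }
  key <- variant_key(variants)
  func_by_key <- tapply(
    normalize_effect(variants$effect),
    key,
    function(e) any(e %in% functional_classes(extended))
  )
  first <- !duplicated(key)
  v1 <- variants[first, , drop = FALSE]
  k1 <- key[first]
  pass <- v1$vtype == "INDEL" &
    as.logical(func_by_key[k1]) &
    fixed_divergent(v1$gt_low, v1$gt_high)
  res <- v1[pass, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Decoy records for exercising the fixed-divergent functional INDEL filter
#'
#' Returns ten annotated-variant records, each violating exactly one of the
#' filter's three criteria: heterozygous or shared-allele line genotypes
#' (not fixed divergent), SNV type (not an INDEL), or an effect outside the
#' transcription unit (not functional). Useful as negative controls around
#' a worked example.
#'
#' @return annotated variant data frame.
#' @export
decoy_variants <- function() {
  data.frame(
    chrom = "d1",
    pos_bp = as.integer(seq(1000, by = 1000, length.out = 10)),
    ref = c("AT", "AT", "AT", "AT", "A", "A", "AT", "AT", "AT", "AT"),
    alt = c("A", "A", "A", "A", "G", "G", "A", "A", "A", "A"),
    vtype = c("INDEL", "INDEL", "INDEL", "INDEL", "SNV", "SNV",
              "INDEL", "INDEL", "INDEL", "INDEL"),
    gene_id = sprintf("DECOY%02d", 1:10),
    effect = c("3'UTR", "frameshift", "5'UTR", "splicing", "missense",
               "3'UTR", "intergenic", "intron", "downstream", "3'UTR"),
    gt_low = c("0/1", "1/1", "1/1", "0/0", "0/0", "1/1", "0/0", "1/1",
               "2/2", "./."),
    gt_high = c("1/1", "1/2", "1/1", "0/0", "1/1", "2/2", "1/1", "0/0",
                "1/1", "1/1"),
    stringsAsFactors = FALSE
  )
}

#' Candidate genes: functional mutations inside true signatures
#'
#' A gene is a candidate when it carries at least one functional variant
#' (per [is_functional()]) whose position lies inside a true-signature
#' interval. Counts and effect classes are aggregated per gene.
#'
#' @param variants annotated variant data frame.
#' @param true_signatures interval data frame (chrom, start_bp, end_bp) of
#'   validated signatures.
#' @param extended see [functional_classes()].
#' @return data frame with gene_id, functional_variant_count,
#'   effect_classes.
#' @export
candidate_genes <- function(variants, true_signatures, extended = FALSE) {
  empty <- data.frame(
    gene_id = character(0), functional_variant_count = integer(0),
    effect_classes = character(0), stringsAsFactors = FALSE
  )
  if (nrow(variants) == 0L || nrow(true_signatures) == 0L) {
    return(empty)
  }
  eff <- normalize_effect(variants$effect)
  func_rows <- eff %in% functional_classes(extended) & !is.na(variants$gene_id)
  v <- variants[func_rows, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(empty)
  }
  gr_v <- GenomicRanges::GRanges(
    v$chrom, IRanges::IRanges(v$pos_bp, v$pos_bp)
  )
  gr_s <- intervals_to_granges(true_signatures)
  hits <- GenomicRanges::findOverlaps(gr_v, gr_s)
  v <- v[unique(S4Vectors::queryHits(hits)), , drop = FALSE]
  if (nrow(v) == 0L) {
    return(empty)
  }
  key <- variant_key(v)
  agg <- lapply(split(seq_len(nrow(v)), v$gene_id), function(i) {
    data.frame(
      gene_id = v$gene_id[i[1]],
      functional_variant_count = length(unique(key[i])),
      effect_classes = paste(sort(unique(normalize_effect(v$effect[i]))),
                             collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keyword-dictionary GO pathway percentages
#'
#' Each GO description containing a pathway keyword (case-insensitive
#' substring match) is assigned to that pathway; descriptions matching no
#' keyword fall in "Other Processes". The percentage of pathway i is
#' X_i / N * 100 with N the total number of descriptions. In the default
#' first-match mode each description counts once and percentages sum to
#' 100; with `multi = TRUE` a description counts in every matching pathway
#' and the sum may exceed 100 (flagged via the `multi_assignment`
#' attribute).
#'
#' @param go_descriptions character vector of GO description strings.
#' @param dictionary named list: pathway -> character vector of lowercase
#'   keywords.
#' @param multi allow multi-pathway assignment.
#' @return named numeric vector of percentages (pathways in dictionary
#'   order, then "Other Processes").
#' @export
go_pathway_percentages <- function(go_descriptions, dictionary,
                                   multi = FALSE) {
  n <- length(go_descriptions)
  if (n == 0L) stop("go_pathway_percentages: no GO descriptions (N = 0)")
  desc <- tolower(go_descriptions)
  pathways <- names(dictionary)
  counts <- stats::setNames(numeric(length(pathways) + 1L),
                            c(pathways, "Other Processes"))
  for (d in desc) {
    matched <- FALSE
    for (pw in pathways) {
      if (any(vapply(tolower(dictionary[[pw]]),
                     function(k) grepl(k, d, fixed = TRUE), logical(1)))) {
        counts[pw] <- counts[pw] + 1
        matched <- TRUE
        if (!multi) break
      }
    }
    if (!matched) counts["Other Processes"] <- counts["Other Processes"] + 1
  }
  pct <- counts / n * 100
  attr(pct, "multi_assignment") <- multi
  pct
}
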