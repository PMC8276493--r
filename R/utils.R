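# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

divsig_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[divsig:%s] %s", level, sprintf(fmt, ...)))
}

#' Convert an interval data frame to a GRanges object
#'
#' Intervals are held internally as 1-based inclusive `(chrom, start_bp,
#' end_bp)` data frames (VCF convention); BED export shifts to 0-based
#' half-open.
#'
#' @param df data frame with columns `chrom`, `start_bp`, `end_bp`.
#' @return a `GRanges`.
#' @keywords internal
intervals_to_granges <- function(df) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start_bp, end = df$end_bp)
  )
}

granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write intervals as a BED file (0-based half-open)
#'
#' @param df interval data frame (1-based inclusive coordinates).
#' @param path output path.
#' @param names optional character vector for the BED name column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, names = NULL) {
  out <- data.frame(
    chrom = df$chrom,
    start = df$start_bp - 1L,
    end = df$end_bp,
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) out$name <- names
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' Only the first three (or four, with names) columns are used.
#'
#' @param path BED file path.
#' @return data frame with `chrom`, `start_bp`, `end_bp` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE, comment.char = "#"
  )
  out <- data.frame(
    chrom = as.character(raw[[1]]),
    start_bp = as.integer(raw[[2]]) + 1L,
    end_bp = as.integer(raw[[3]]),
    stringsAsFactors = FALSE
  )
  if (ncol(raw) >= 4L) out$name <- as.character(raw[[4]])
  out
}

# Run code with an isolated RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards so simulation calls are reproducible
# without clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# linear-interpolation percentile (type 7), the documented convention for
# all genome-wide relevance thresholds
percentile_threshold <- function(x, percentile) {
  stats::quantile(x, probs = percentile, type = 7, names = FALSE, na.rm = TRUE)
}
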