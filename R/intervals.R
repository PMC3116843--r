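#' Genomic intervals
#'
#' Throughout the package genomic intervals are plain data frames with
#' columns `chrom`, `start`, `end` in 0-based half-open coordinates (the
#' BED convention) and an optional `strand` column. Methylation is
#' strandless, so strand defaults to `"."` everywhere it is not needed.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param ... further equal-length columns (e.g. `name`, `score`).
#' @return A data.frame with validated interval columns.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start < 0")
  if (any(df$start >= df$end)) stop("empty or inverted interval (start >= end)")
  invisible(df)
}

#' Gap distance between two genomic intervals
#'
#' The number of bases strictly between two half-open intervals: 0 if they
#' overlap or abut with no base between them, `Inf` if they lie on
#' different chromosomes. Symmetric in its arguments. This is the distance
#' used by the proximity rule "methylation within 500 bp of the annotated
#' stem-loop".
#'
#' @param a,b single-row interval data.frames (or lists) with
#'   `chrom`, `start`, `end`.
#' @return Non-negative number of intervening bases, or `Inf`.
#' @export
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' b <- genomic_intervals("chr1", 150, 300)
#' gap_distance(a, b)  # 0, overlapping
gap_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  max(0, a$start - b$end, b$start - a$end)
}

# Vectorised minimum gap from one interval to a set of regions on the same
# coordinate system. Returns list(distance, index) where index is the row of
# the nearest region (minimum gap, ties broken by lower start, then chrom).
min_gap_to_regions <- function(interval, regions) {
  if (nrow(regions) == 0) return(list(distance = Inf, index = NA_integer_))
  d <- ifelse(regions$chrom == interval$chrom,
              pmax(0, interval$start - regions$end,
                      regions$start - interval$end),
              Inf)
  ord <- order(d, regions$start, regions$chrom)
  i <- ord[1]
  list(distance = d[i], index = if (is.finite(d[i])) i else NA_integer_)
}

# Merge intervals whose gap is <= merge_gap, per chromosome. Extra columns
# are dropped except `score`, which is aggregated by max.
merge_intervals <- function(df, merge_gap = 0) {
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  has_score <- "score" %in% names(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.null(cur) || row$chrom != cur$chrom ||
        row$start - cur$end > merge_gap) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- data.frame(chrom = row$chrom, start = row$start, end = row$end,
                        score = if (has_score) row$score else NA_real_,
                        stringsAsFactors = FALSE)
    } else {
      cur$end <- max(cur$end, row$end)
      if (has_score) cur$score <- max(cur$score, row$score)
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# data.frame (0-based half-open) <-> GRanges (1-based closed)
intervals_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand)
  if ("name" %in% names(df)) names(gr) <- df$name
  if ("score" %in% names(df)) S4Vectors::mcols(gr)$score <- df$score
  gr
}

granges_to_intervals <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) df$name <- as.character(mc$name)
  if (!is.null(names(gr)) && !"name" %in% names(df)) df$name <- names(gr)
  if ("score" %in% names(mc)) df$score <- as.numeric(mc$score)
  df
}
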