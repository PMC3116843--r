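#' Count reads in non-overlapping genomic windows
#'
#' Tiles each chromosome with fixed-size windows and assigns every read to
#' exactly one window by its midpoint. A midpoint falling exactly on a
#' window boundary is assigned to the right (higher-coordinate) window, so
#' read counts are conserved.
#'
#' @param reads interval data.frame of mapped read positions
#'   (0-based half-open).
#' @param window_size window width in bp (> 0).
#' @param genome named numeric vector of chromosome sizes in bp.
#' @param sample_id identifier stored with the counts.
#' @return A `window_counts` object: list with `sample_id`, `window_size`,
#'   `counts` (data.frame chrom/start/end/count tiling the genome),
#'   `total_reads` and `genome_size`.
#' @export
count_reads_in_windows <- function(reads, window_size, genome,
                                   sample_id = "sample") {
  stopifnot(window_size > 0, length(genome) >= 1, !is.null(names(genome)))
  if (nrow(reads) > 0) {
    bad <- !(reads$chrom %in% names(genome)) |
      reads$end > genome[reads$chrom] | reads$start < 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("read outside declared chromosome bounds: %s:%d-%d",
                   reads$chrom[i], reads$start[i], reads$end[i]))
    }
  }
  tiles <- do.call(rbind, lapply(names(genome), function(ch) {
    starts <- seq(0, genome[[ch]] - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, genome[[ch]]),
               stringsAsFactors = FALSE)
  }))
  tiles$count <- 0L
  if (nrow(reads) > 0) {
    mid <- (reads$start + reads$end) / 2
    idx <- floor(mid / window_size)
    key <- paste(reads$chrom, idx)
    tab <- table(key)
    tile_key <- paste(tiles$chrom, tiles$start / window_size)
    m <- match(names(tab), tile_key)
    tiles$count[m] <- as.integer(tab)
  }
  structure(list(sample_id = sample_id,
                 window_size = window_size,
                 counts = tiles,
                 total_reads = nrow(reads),
                 genome_size = sum(genome)),
            class = "window_counts")
}

#' Minimum read count indicating significant methylation
#'
#' Models background coverage as genome-wide Poisson: reads fall uniformly,
#' so a window of `window_size` bp receives on average
#' `lambda = total_reads * window_size / genome_size` reads. The threshold
#' is the smallest count whose upper-tail probability falls below a
#' Bonferroni-adjusted per-window level `alpha / n_windows`:
#' `k* = min{ k : P(Poisson(lambda) >= k) < alpha / n_windows }`.
#'
#' With zero total reads the tail probability is 0 for any k >= 1, so a
#' single read is already significant (`k* = 1`).
#'
#' @param total_reads total mapped reads in the sample.
#' @param genome_size genome length in bp.
#' @param window_size window width in bp.
#' @param alpha genome-wide significance level (default 0.01).
#' @return list with `k_star`, `lambda`, `alpha`, `n_windows`.
#' @export
significance_threshold <- function(total_reads, genome_size, window_size,
                                   alpha = 0.01) {
  stopifnot(total_reads >= 0, alpha > 0, alpha < 1, window_size > 0)
  n_windows <- ceiling(genome_size / window_size)
  if (n_windows < 1) stop("degenerate genome: no windows")
  lambda <- total_reads * window_size / genome_size
  level <- alpha / n_windows
  k <- 1
  # P(X >= k) = ppois(k - 1, lambda, lower.tail = FALSE)
  while (stats::ppois(k - 1, lambda, lower.tail = FALSE) >= level) {
    k <- k + 1
  }
  list(k_star = k, lambda = lambda, alpha = alpha, n_windows = n_windows)
}

#' Call significant methylated regions from window counts
#'
#' Windows with count >= `k_star` are significant; significant windows
#' separated by at most `merge_gap` bp are merged into regions. Each
#' region's score is the maximum window count it contains.
#'
#' @param wc `window_counts` object from [count_reads_in_windows()].
#' @param k_star minimum significant count (>= 1), e.g. from
#'   [significance_threshold()].
#' @param merge_gap maximum gap in bp between merged significant windows
#'   (default 0: adjacent windows only).
#' @return A `methylome_profile`: list with `sample_id`, `threshold_reads`
#'   and `regions` (interval data.frame with `score` = max window count).
#' @export
call_regions <- function(wc, k_star, merge_gap = 0) {
  stopifnot(inherits(wc, "window_counts"), k_star >= 1)
  sig <- wc$counts[wc$counts$count >= k_star, , drop = FALSE]
  regions <- if (nrow(sig) == 0) {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
  } else {
    names(sig)[names(sig) == "count"] <- "score"
    merge_intervals(sig, merge_gap = merge_gap)
  }
  methylome_profile(wc$sample_id, k_star, regions)
}

#' Construct a methylome profile
#'
#' @param sample_id sample identifier.
#' @param threshold_reads the minimum significant count used.
#' @param regions interval data.frame of significant methylated regions.
#' @return A `methylome_profile` object.
#' @export
methylome_profile <- function(sample_id, threshold_reads, regions) {
  validate_intervals(regions)
  structure(list(sample_id = sample_id,
                 threshold_reads = threshold_reads,
                 regions = regions),
            class = "methylome_profile")
}

#' @export
print.methylome_profile <- function(x, ...) {
  cat(sprintf("methylome_profile '%s': %d regions (k* = %s)\n",
              x$sample_id, nrow(x$regions), format(x$threshold_reads)))
  invisible(x)
}

#' Call a methylome profile from mapped reads
#'
#' Convenience composition: window counting, threshold derivation and
#' region calling in one step.
#'
#' @inheritParams count_reads_in_windows
#' @inheritParams significance_threshold
#' @inheritParams call_regions
#' @return A `methylome_profile` with the threshold metadata attached as
#'   attribute `"threshold"`.
#' @export
call_methylome <- function(reads, genome, window_size = 500, alpha = 0.01,
                           merge_gap = 0, sample_id = "sample") {
  wc <- count_reads_in_windows(reads, window_size, genome, sample_id)
  th <- significance_threshold(wc$total_reads, wc$genome_size,
                               window_size, alpha)
  prof <- call_regions(wc, th$k_star, merge_gap)
  attr(prof, "threshold") <- th
  prof
}
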