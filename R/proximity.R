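#' Screen miRNA annotations for proximal DNA methylation
#'
#' A miRNA is a candidate when a significant methylated region in the
#' reference (methylated) line lies within `max_dist` bases of its
#' annotated stem-loop (gap distance, inclusive: a 500 bp gap qualifies
#' under the default). For each candidate the demethylated derivative's
#' profile is interrogated the same way to record whether the proximal
#' methylation is retained there. Strand is ignored; methylation is
#' strandless.
#'
#' @param mirnas data.frame of miRNA annotations: `mirna_id`, `chrom`,
#'   `start`, `end`, optional logical `known_methylation_regulated` and
#'   `imprinted_cluster` flags (default FALSE).
#' @param ref_profile `methylome_profile` of the methylated reference line.
#' @param demeth_profile `methylome_profile` of the demethylated
#'   derivative.
#' @param max_dist maximum gap in bp (default 500).
#' @return data.frame of proximity calls sorted by `mirna_id`:
#'   one row per candidate with `distance_reference`,
#'   `methylated_in_demethylated` (retention), `distance_demethylated`, and
#'   the nearest reference region's coordinates. Ties in nearest-region
#'   choice are broken by lower start coordinate.
#' @export
screen_candidates <- function(mirnas, ref_profile, demeth_profile,
                              max_dist = 500) {
  stopifnot(inherits(ref_profile, "methylome_profile"),
            inherits(demeth_profile, "methylome_profile"))
  if (nrow(mirnas) == 0 || nrow(ref_profile$regions) == 0) {
    return(empty_proximity_calls())
  }
  if (anyDuplicated(mirnas$mirna_id)) stop("duplicate mirna_id in annotation")
  region_chroms <- unique(c(ref_profile$regions$chrom,
                            demeth_profile$regions$chrom))
  unknown <- setdiff(region_chroms, unique(mirnas$chrom))
  # regions on chromosomes absent from the annotation are legitimate;
  # the converse (annotation chromosome absent from the profile genome)
  # cannot be detected here because profiles carry no genome. Mismatched
  # naming schemes, however, are caught:
  if (length(unknown) == length(region_chroms) && length(unknown) > 0) {
    stop("no chromosome shared between annotation and profiles; ",
         "offending profile chromosomes: ",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(mirnas)), function(i) {
    m <- mirnas[i, ]
    hit <- min_gap_to_regions(m, ref_profile$regions)
    if (!is.finite(hit$distance) || hit$distance > max_dist) return(NULL)
    dem <- min_gap_to_regions(m, demeth_profile$regions)
    nr <- ref_profile$regions[hit$index, ]
    data.frame(mirna_id = m$mirna_id,
               methylated_in_reference = TRUE,
               distance_reference = hit$distance,
               methylated_in_demethylated =
                 is.finite(dem$distance) && dem$distance <= max_dist,
               distance_demethylated = dem$distance,
               nearest_chrom = nr$chrom,
               nearest_start = nr$start,
               nearest_end = nr$end,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_proximity_calls())
  calls <- do.call(rbind, rows)
  calls <- calls[order(calls$mirna_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_proximity_calls <- function() {
  data.frame(mirna_id = character(),
             methylated_in_reference = logical(),
             distance_reference = numeric(),
             methylated_in_demethylated = logical(),
             distance_demethylated = numeric(),
             nearest_chrom = character(),
             nearest_start = numeric(),
             nearest_end = numeric(),
             stringsAsFactors = FALSE)
}
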