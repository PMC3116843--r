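#' Construct a transcript model
#'
#' @param gene_id gene identifier.
#' @param chrom,start,end transcript span, 0-based half-open.
#' @param strand `"+"` or `"-"` (determines the TSS end).
#' @param exons data.frame with `start`, `end` columns (0-based half-open),
#'   all within the transcript span.
#' @return A `transcript_model` list with a `tss` field at the
#'   strand-appropriate end.
#' @export
transcript_model <- function(gene_id, chrom, start, end, strand = "+",
                             exons = data.frame(start = numeric(),
                                                end = numeric())) {
  stopifnot(start < end, strand %in% c("+", "-", "."))
  if (nrow(exons) > 0 && (any(exons$start < start) || any(exons$end > end))) {
    stop("exon outside transcript span: ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand,
                 tss = if (strand == "-") end else start,
                 exons = exons[order(exons$start), , drop = FALSE]),
            class = "transcript_model")
}

#' Classify the genomic context of a miRNA stem-loop
#'
#' A stem-loop is `intronic` if it lies fully inside a transcript but
#' overlaps none of its exons, `exonic` if it overlaps any exon of a
#' containing transcript, and `intergenic` otherwise. When several
#' transcripts contain the stem-loop the smallest containing transcript is
#' reported as the host; all containing genes are listed in
#' `all_host_genes`.
#'
#' @param mirna single-row data.frame (or list) with `mirna_id`, `chrom`,
#'   `start`, `end`.
#' @param transcripts list of [transcript_model()] objects.
#' @return list with `mirna_id`, `context`, `host_gene_id`
#'   (NA for intergenic), `all_host_genes`.
#' @export
classify_context <- function(mirna, transcripts) {
  containing <- Filter(function(tx) {
    tx$chrom == mirna$chrom && tx$start <= mirna$start && mirna$end <= tx$end
  }, transcripts)
  if (length(containing) == 0) {
    return(list(mirna_id = mirna$mirna_id, context = "intergenic",
                host_gene_id = NA_character_,
                all_host_genes = character()))
  }
  sizes <- vapply(containing, function(tx) tx$end - tx$start, numeric(1))
  host <- containing[[order(sizes)[1]]]
  exonic <- any(vapply(containing, function(tx) {
    nrow(tx$exons) > 0 &&
      any(tx$exons$start < mirna$end & mirna$start < tx$exons$end)
  }, logical(1)))
  list(mirna_id = mirna$mirna_id,
       context = if (exonic) "exonic" else "intronic",
       host_gene_id = host$gene_id,
       all_host_genes = vapply(containing, `[[`, character(1), "gene_id"))
}

#' Flag significant methylation at a host-gene promoter
#'
#' The putative promoter is the window `[TSS - flank, TSS + flank)`
#' around the annotated transcription start site (default 1000 bp each
#' side). Returns TRUE iff any significant methylated region of the
#' profile overlaps that window.
#'
#' @param host [transcript_model()] of the host gene.
#' @param profile `methylome_profile`.
#' @param flank bp each side of the TSS (default 1000).
#' @return logical flag.
#' @export
promoter_methylation_flag <- function(host, profile, flank = 1000) {
  win_start <- max(0, host$tss - flank)
  win_end <- host$tss + flank
  r <- profile$regions
  any(r$chrom == host$chrom & r$start < win_end & win_start < r$end)
}

#' Derive the host gene's qualitative 5-aza-dC response
#'
#' Compares in which cell lines the host gene re-expresses significantly
#' with the lines in which its embedded miRNA does: undetectable Ct in all
#' wells of every line gives `not_expressed`; no significant line gives
#' `no_change`; significance in a strict subset of the miRNA's responding
#' lines gives `inconsistent_increase`; significance in every line where
#' the miRNA responded gives `concordant_increase`.
#'
#' @param host_results rows of [reexpression_results()] for the host gene.
#' @param mirna_results rows of [reexpression_results()] for the embedded
#'   miRNA.
#' @return One of `"not_expressed"`, `"no_change"`,
#'   `"inconsistent_increase"`, `"concordant_increase"`.
#' @export
host_response <- function(host_results, mirna_results) {
  if (nrow(host_results) == 0) return("no_change")
  if (all(!host_results$detectable)) return("not_expressed")
  host_sig <- host_results$cell_line[host_results$significant]
  mirna_sig <- mirna_results$cell_line[mirna_results$significant]
  if (length(host_sig) == 0) return("no_change")
  if (all(mirna_sig %in% host_sig)) return("concordant_increase")
  "inconsistent_increase"
}

#' Decide host-gene transcriptional independence
#'
#' Pure decision table applied to confirmed aza-responsive candidates:
#' intergenic miRNAs are independent of any host promoter; intronic
#' miRNAs are independent when the putative host does not respond to
#' demethylating treatment (`no_change`) or is not expressed at all, and
#' possibly co-regulated when the host also increases (consistently or
#' not); exonic context and missing host data are indeterminate.
#'
#' @param context `"intergenic"`, `"intronic"` or `"exonic"`.
#' @param host_response host response category from [host_response()], or
#'   NA when no host data exist.
#' @return `"independent"`, `"possibly_coregulated"` or
#'   `"indeterminate"`.
#' @export
independence_call <- function(context, host_response = NA_character_) {
  stopifnot(context %in% c("intergenic", "intronic", "exonic"))
  if (context == "intergenic") return("independent")
  if (context == "exonic") return("indeterminate")
  if (is.na(host_response)) return("indeterminate")
  switch(host_response,
         no_change = "independent",
         not_expressed = "independent",
         inconsistent_increase = "possibly_coregulated",
         concordant_increase = "possibly_coregulated",
         stop("unknown host response: ", host_response))
}
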