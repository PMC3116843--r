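#' Read a BED file of genomic features
#'
#' Thin wrapper around [rtracklayer::import.bed()] returning the package's
#' 0-based half-open interval data.frame.
#'
#' @param path BED file path.
#' @return Interval data.frame with any `name`/`score` columns present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_intervals(gr)
}

#' Write intervals to a BED file
#'
#' @param df interval data.frame (`chrom`, `start`, `end`, optional
#'   `name`, `score`, `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  gr <- intervals_to_granges(df)
  if ("score" %in% names(df)) S4Vectors::mcols(gr)$score <- df$score
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Expects `transcript` features (with `ID` and optional `gene_id`
#' attributes) and child `exon` features (`Parent`). The TSS is taken at
#' the strand-appropriate end of the transcript.
#'
#' @param path GFF3 file path.
#' @return A list of transcript models as produced by [transcript_model()].
#' @export
read_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- granges_to_intervals(gr)
  df$type <- as.character(S4Vectors::mcols(gr)$type)
  df$ID <- as.character(S4Vectors::mcols(gr)$ID)
  parent <- S4Vectors::mcols(gr)$Parent
  df$Parent <- vapply(as.list(parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  gene_id <- S4Vectors::mcols(gr)$gene_id
  df$gene_id <- if (is.null(gene_id)) df$ID else as.character(gene_id)

  tx_rows <- df[df$type %in% c("transcript", "mRNA"), , drop = FALSE]
  lapply(seq_len(nrow(tx_rows)), function(i) {
    tx <- tx_rows[i, ]
    ex <- df[df$type == "exon" & !is.na(df$Parent) & df$Parent == tx$ID, ,
             drop = FALSE]
    transcript_model(
      gene_id = if (is.na(tx$gene_id)) tx$ID else tx$gene_id,
      chrom = tx$chrom, start = tx$start, end = tx$end,
      strand = tx$strand,
      exons = ex[, c("start", "end"), drop = FALSE])
  })
}

#' Write transcript models to GFF3
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  lines <- c("##gff-version 3")
  for (tx in transcripts) {
    strand <- if (tx$strand %in% c("+", "-")) tx$strand else "."
    lines <- c(lines, paste(
      tx$chrom, "mirmeth", "transcript", tx$start + 1, tx$end, ".",
      strand, ".",
      sprintf("ID=%s;gene_id=%s", tx$gene_id, tx$gene_id), sep = "\t"))
    if (nrow(tx$exons) > 0) {
      for (j in seq_len(nrow(tx$exons))) {
        lines <- c(lines, paste(
          tx$chrom, "mirmeth", "exon",
          tx$exons$start[j] + 1, tx$exons$end[j], ".", strand, ".",
          sprintf("ID=%s.exon%d;Parent=%s", tx$gene_id, j, tx$gene_id),
          sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write simple TSV tables
#'
#' TSVs with a header row are the interchange format for expression
#' matrices, Ct tables and phenotype tables.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param df data.frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
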