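#' The ten confirmed candidate miRNAs, as a synthetic-coordinate fixture
#'
#' Encodes the screen's ten drug-confirmed candidate miRNAs with their
#' published genomic contexts, putative host genes, host-promoter
#' methylation status and qualitative host-gene response to demethylating
#' treatment: miR-1247, miR-1826 and miR-219-2 are intergenic; miR-1237
#' (RPS6KA4), miR-24-1 and miR-27b (C9orf3), miR-602 (AB058779), miR-663b
#' (ANKRD30BL) and miR-941-1/-3 (DNAJC5) are intronic. Only ANKRD30BL
#' carries promoter methylation; the C9orf3 pair shows an inconsistent
#' host increase; ANKRD30BL is not expressed before or after treatment;
#' all other hosts show no change.
#'
#' Coordinates are synthetic: features are laid out on a toy chromosome
#' preserving the containment relations (each intronic candidate inside an
#' intron of its host transcript, the intergenic ones outside all
#' transcripts), not the hg18 positions.
#'
#' @return list with `mirnas` (annotation data.frame), `transcripts`
#'   (list of [transcript_model()]), `records` (data.frame with the
#'   published context, host, promoter-methylation and host-response
#'   columns), and `reference_regions` (one methylated region spanning
#'   the ANKRD30BL TSS, as a `methylome_profile`).
#' @export
confirmed_candidates_fixture <- function() {
  ex <- tx_exons_rel()
  tx_at <- function(gene, start, strand = "+") {
    transcript_model(gene, "chrS", start, start + tx_span(), strand,
                     exons = data.frame(start = start + ex$start,
                                        end = start + ex$end))
  }
  transcripts <- list(
    RPS6KA4 = tx_at("RPS6KA4", 20000),
    C9orf3 = tx_at("C9orf3", 40000),
    AB058779 = tx_at("AB058779", 60000, "-"),
    ANKRD30BL = tx_at("ANKRD30BL", 80000),
    DNAJC5 = tx_at("DNAJC5", 100000))

  intronic <- function(id, gene, offset = 2600) {
    tx <- transcripts[[gene]]
    data.frame(mirna_id = id, chrom = "chrS", start = tx$start + offset,
               end = tx$start + offset + 80, stringsAsFactors = FALSE)
  }
  intergenic <- function(id, start) {
    data.frame(mirna_id = id, chrom = "chrS", start = start,
               end = start + 80, stringsAsFactors = FALSE)
  }
  mirnas <- rbind(
    intronic("hsa-miR-1237", "RPS6KA4"),
    intergenic("hsa-miR-1247", 5000),
    intergenic("hsa-miR-1826", 10000),
    intergenic("hsa-miR-219-2", 15000),
    intronic("hsa-miR-24-1", "C9orf3", 2600),
    intronic("hsa-miR-27b", "C9orf3", 4500),
    intronic("hsa-miR-602", "AB058779"),
    intronic("hsa-miR-663b", "ANKRD30BL"),
    intronic("hsa-miR-941-1", "DNAJC5", 2600),
    intronic("hsa-miR-941-3", "DNAJC5", 4500))

  records <- data.frame(
    mirna_id = mirnas$mirna_id,
    context = c("intronic", "intergenic", "intergenic", "intergenic",
                "intronic", "intronic", "intronic", "intronic",
                "intronic", "intronic"),
    host_gene_id = c("RPS6KA4", NA, NA, NA, "C9orf3", "C9orf3",
                     "AB058779", "ANKRD30BL", "DNAJC5", "DNAJC5"),
    host_promoter_methylated = c(FALSE, NA, NA, NA, FALSE, FALSE,
                                 FALSE, TRUE, FALSE, FALSE),
    host_response = c("no_change", NA, NA, NA,
                      "inconsistent_increase", "inconsistent_increase",
                      "no_change", "not_expressed",
                      "no_change", "no_change"),
    stringsAsFactors = FALSE)

  ank_tss <- transcripts$ANKRD30BL$tss
  reference_regions <- methylome_profile(
    "reference", 1,
    data.frame(chrom = "chrS", start = ank_tss - 300, end = ank_tss + 500,
               score = NA_real_, stringsAsFactors = FALSE))

  list(mirnas = mirnas, transcripts = transcripts, records = records,
       reference_regions = reference_regions)
}
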