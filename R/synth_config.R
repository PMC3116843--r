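#' Configuration of the synthetic two-cell-line world
#'
#' The generator emulates the design of a methylation screen in a
#' methylated cancer line and its demethylated derivative (a knockout
#' retaining only residual methylation): MBD-enrichment reads with Poisson
#' background and fold-enriched methylated regions, triplicate expression
#' arrays where planted methylation-silenced miRNAs rise upon
#' demethylation, Ct tables with a planted demethylating-drug response,
#' bisulfite clones, and phenotype assay tables.
#'
#' Planted methylated regions are blocks of `region_tiles` x `region_tile`
#' bp aligned to the `region_tile` grid: methylation domains are modeled
#' at the resolution at which MBD enrichment is scored.
#'
#' @param genome_length bp per chromosome.
#' @param n_chroms number of chromosomes.
#' @param n_mirnas number of annotated miRNA stem-loops.
#' @param n_transcripts number of transcript models.
#' @param frac_methylated_mirnas fraction of miRNAs planted as
#'   methylation-silenced (regulated).
#' @param frac_retained_in_demethylated per-region probability that a
#'   planted methylated region is retained in the demethylated derivative.
#' @param background_read_rate background coverage, reads per bp.
#' @param peak_enrichment fold enrichment of read rate inside planted
#'   regions (>= 1; 1 is the null world).
#' @param expression_silencing_factor expression fold applied in the
#'   demethylated line to regulated miRNAs whose methylation is lost.
#' @param replicate_cv coefficient of variation of multiplicative
#'   replicate noise on expression values.
#' @param bisulfite_conversion_rate probability an unmethylated C converts.
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @param n_known_regulated,n_imprinted planted already-known
#'   methylation-regulated and imprinted-cluster miRNAs (methylated, to be
#'   excluded by the funnel).
#' @param n_coregulated planted host-driven intronic miRNAs (methylated
#'   and aza-responsive, but the host responds too).
#' @param n_decoys planted miRNAs with proximal methylation but no
#'   expression response (negative controls for the concordance stage).
#' @param read_length simulated read length in bp (GAII-era default 36).
#' @param region_tile,region_tiles grid unit and number of units per
#'   planted methylated region.
#' @param qpcr_fold planted relative-expression fold after demethylating
#'   treatment for responsive targets.
#' @param qpcr_noise_sd additive SD on simulated Ct values (cycles).
#' @param per_cpg_methylation per-CpG methylation probability at planted
#'   loci in the baseline (methylated) condition.
#' @param per_cpg_methylation_treated same, after demethylating treatment.
#' @param n_background_regions planted methylated regions per chromosome
#'   away from any miRNA.
#' @return A validated `world_config` list.
#' @export
world_config <- function(genome_length = 500000,
                         n_chroms = 2,
                         n_mirnas = 50,
                         n_transcripts = 18,
                         frac_methylated_mirnas = 0.3,
                         frac_retained_in_demethylated = 0.25,
                         background_read_rate = 0.02,
                         peak_enrichment = 10,
                         expression_silencing_factor = 3,
                         replicate_cv = 0.1,
                         bisulfite_conversion_rate = 0.99,
                         seed = 1,
                         n_known_regulated = 4,
                         n_imprinted = 2,
                         n_coregulated = 2,
                         n_decoys = 3,
                         read_length = 36,
                         region_tile = 500,
                         region_tiles = 2,
                         qpcr_fold = 4,
                         qpcr_noise_sd = 0.1,
                         per_cpg_methylation = 0.9,
                         per_cpg_methylation_treated = 0.3,
                         n_background_regions = 8) {
  cfg <- as.list(environment())
  props <- c("frac_methylated_mirnas", "frac_retained_in_demethylated",
             "bisulfite_conversion_rate", "per_cpg_methylation",
             "per_cpg_methylation_treated")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$peak_enrichment < 1) stop("peak_enrichment must be >= 1")
  if (cfg$genome_length < 10 * tx_span()) {
    stop("genome_length must be >= 10x the largest feature span (",
         10 * tx_span(), " bp)")
  }
  if (cfg$replicate_cv < 0) stop("replicate_cv must be >= 0")
  if (cfg$seed != as.integer(cfg$seed)) stop("seed must be an integer")
  n_special <- with(cfg, round(frac_methylated_mirnas * n_mirnas) +
                      n_known_regulated + n_imprinted + n_coregulated +
                      n_decoys)
  if (n_special > cfg$n_mirnas) {
    stop("planted categories exceed n_mirnas (", n_special, " > ",
         cfg$n_mirnas, ")")
  }
  structure(cfg, class = "world_config")
}

#' Read a world configuration from a YAML file
#'
#' @param path YAML file with `world_config` fields.
#' @return A `world_config`.
#' @export
read_world_config <- function(path) {
  do.call(world_config, yaml::read_yaml(path))
}

# fixed transcript geometry (bp, relative to transcript start):
# three exons leaving introns [200,3800) and [4000,7800); intronic
# stem-loops sit at +2600 so a 1000 bp upstream region block cannot reach
# the +/-1000 bp promoter window of the TSS.
tx_span <- function() 8000
tx_exons_rel <- function() data.frame(start = c(0, 3800, 7800),
                                      end = c(200, 4000, 8000))
mirna_len <- function() 80
intronic_offset <- function() 2600
slot_len <- function() 12000

# independent deterministic sub-streams per generator stage
derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) %% 100000) * 1000 + k)
}
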