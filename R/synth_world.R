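#' Generate the synthetic two-cell-line world
#'
#' Lays out transcript models and miRNA stem-loops on a toy genome, plants
#' methylated regions proximal to the chosen miRNA categories, and returns
#' the ground-truth manifest the recovery tests compare against.
#'
#' Planted categories:
#' \describe{
#'   \item{regulated}{methylation-silenced miRNAs, transcriptionally
#'     independent of any host; the set the funnel should recover.}
#'   \item{coregulated}{intronic miRNAs whose host gene responds to
#'     demethylating treatment in every line the miRNA does; the funnel
#'     should route these to `possibly_coregulated`.}
#'   \item{known/imprinted}{methylated miRNAs carrying the
#'     already-reported / imprinted-cluster flags; excluded by the funnel
#'     before validation.}
#'   \item{decoys}{miRNAs with proximal methylation but no expression or
#'     drug response (like a candidate that stays silenced after
#'     demethylation); they must fall out at the concordance or
#'     re-expression stage.}
#' }
#'
#' Every planted methylated region lies within 500 bp of its miRNA
#' stem-loop (gap distance). Per-region retention in the demethylated
#' derivative is Bernoulli(`frac_retained_in_demethylated`). Additional
#' background regions are planted far (> 500 bp) from every miRNA.
#'
#' @param config a [world_config()].
#' @param out_dir optional directory; when given, annotation files
#'   (miRNA BED, transcript GFF3, amplicon FASTA, manifest JSON) are
#'   written there.
#' @return A `synth_world` list: `config`, `genome` (named chrom sizes),
#'   `mirnas` (annotation data.frame with flags), `transcripts` (list of
#'   [transcript_model()]), `amplicons`, and `manifest`.
#' @export
generate_world <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "world_config"))
  set.seed(derive_seed(config$seed, 1))
  genome <- stats::setNames(rep(config$genome_length, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))

  # slot-based placement guarantees non-overlap and cheap feasibility check
  slots <- do.call(rbind, lapply(names(genome), function(ch) {
    starts <- seq(0, genome[[ch]] - slot_len(), by = slot_len())
    data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
  }))

  n_reg <- round(config$frac_methylated_mirnas * config$n_mirnas)
  categories <- rep("unmethylated", config$n_mirnas)
  if (config$n_mirnas > 0) {
    categories[seq_len(min(config$n_mirnas,
                           n_reg + config$n_coregulated +
                             config$n_known_regulated + config$n_imprinted +
                             config$n_decoys))] <-
      rep(c("regulated", "coregulated", "known", "imprinted", "decoy"),
          times = c(n_reg, config$n_coregulated, config$n_known_regulated,
                    config$n_imprinted, config$n_decoys))
  }
  # intronic placement: all coregulated (they need a host) plus roughly
  # half of the rest, one miRNA per transcript, supply permitting
  intronic <- rep(FALSE, config$n_mirnas)
  for (i in order(categories != "coregulated")) {
    if (sum(intronic) >= config$n_transcripts) break
    if (categories[i] == "coregulated" || i %% 2 == 0) intronic[i] <- TRUE
  }
  if (any(categories == "coregulated" & !intronic)) {
    stop("infeasible placement: not enough transcripts to host the ",
         "coregulated miRNAs")
  }

  n_bg <- config$n_background_regions * config$n_chroms
  needed <- config$n_transcripts + sum(!intronic & config$n_mirnas > 0) + n_bg
  if (needed > nrow(slots)) {
    stop("infeasible placement: ", needed, " feature slots needed but only ",
         nrow(slots), " available; increase genome_length or n_chroms")
  }
  slot_order <- sample(nrow(slots))

  # transcripts
  transcripts <- list()
  take <- 0
  for (i in seq_len(config$n_transcripts)) {
    take <- take + 1
    sl <- slots[slot_order[take], ]
    strand <- if (i %% 3 == 0) "-" else "+"
    start <- sl$start + 2000
    transcripts[[i]] <- transcript_model(
      gene_id = sprintf("GENE%03d", i),
      chrom = sl$chrom, start = start, end = start + tx_span(),
      strand = strand,
      exons = data.frame(start = start + tx_exons_rel()$start,
                         end = start + tx_exons_rel()$end))
  }

  # miRNAs
  mirnas <- NULL
  if (config$n_mirnas > 0) {
    tx_pool <- sample(seq_len(config$n_transcripts))
    tx_used <- 0
    rows <- vector("list", config$n_mirnas)
    for (i in seq_len(config$n_mirnas)) {
      id <- sprintf("mir-%03d", i)
      if (intronic[i]) {
        tx_used <- tx_used + 1
        tx <- transcripts[[tx_pool[tx_used]]]
        s <- tx$start + intronic_offset()
        rows[[i]] <- data.frame(mirna_id = id, chrom = tx$chrom, start = s,
                                end = s + mirna_len(),
                                host_gene_id = tx$gene_id,
                                stringsAsFactors = FALSE)
      } else {
        take <- take + 1
        sl <- slots[slot_order[take], ]
        s <- sl$start + 5000 + sample(0:400, 1)
        rows[[i]] <- data.frame(mirna_id = id, chrom = sl$chrom, start = s,
                                end = s + mirna_len(),
                                host_gene_id = NA_character_,
                                stringsAsFactors = FALSE)
      }
    }
    mirnas <- do.call(rbind, rows)
    mirnas$strand <- "."
    mirnas$category <- categories
    mirnas$known_methylation_regulated <- categories == "known"
    mirnas$imprinted_cluster <- categories == "imprinted"
  } else {
    mirnas <- data.frame(mirna_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         host_gene_id = character(), strand = character(),
                         category = character(),
                         known_methylation_regulated = logical(),
                         imprinted_cluster = logical(),
                         stringsAsFactors = FALSE)
  }

  # planted methylated regions proximal to every methylated miRNA
  tile <- config$region_tile
  width <- tile * config$region_tiles
  meth_idx <- which(mirnas$category != "unmethylated")
  region_rows <- lapply(meth_idx, function(i) {
    s <- mirnas$start[i]
    t0 <- floor(s / tile) * tile
    upstream <- t0 >= width && stats::runif(1) < 0.5
    start <- if (upstream) t0 - width else t0
    data.frame(chrom = mirnas$chrom[i], start = start, end = start + width,
               mirna_id = mirnas$mirna_id[i], kind = "mirna",
               stringsAsFactors = FALSE)
  })
  # host-promoter methylation for coregulated miRNAs
  promoter_rows <- lapply(which(mirnas$category == "coregulated"), function(i) {
    tx <- transcripts[[match(mirnas$host_gene_id[i],
                             vapply(transcripts, `[[`, character(1),
                                    "gene_id"))]]
    g <- max(0, floor(tx$tss / tile) * tile - tile)
    data.frame(chrom = tx$chrom, start = g, end = g + width,
               mirna_id = mirnas$mirna_id[i], kind = "host_promoter",
               stringsAsFactors = FALSE)
  })
  bg_rows <- lapply(seq_len(n_bg), function(j) {
    take <<- take + 1
    sl <- slots[slot_order[take], ]
    start <- sl$start + 4000
    data.frame(chrom = sl$chrom, start = start, end = start + width,
               mirna_id = NA_character_, kind = "background",
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, c(region_rows, promoter_rows, bg_rows))
  if (is.null(regions)) {
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), mirna_id = character(),
                          kind = character(), stringsAsFactors = FALSE)
  }
  regions$retained <- stats::runif(nrow(regions)) <
    config$frac_retained_in_demethylated
  # a coregulated miRNA's promoter region shares its stem-loop region fate
  if (nrow(regions) > 0) {
    for (i in which(regions$kind == "host_promoter")) {
      j <- which(regions$kind == "mirna" &
                   regions$mirna_id == regions$mirna_id[i])
      regions$retained[i] <- regions$retained[j]
    }
  }
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL

  regulated <- mirnas$mirna_id[mirnas$category == "regulated"]
  coregulated <- mirnas$mirna_id[mirnas$category == "coregulated"]
  known_or_imprinted <- mirnas$mirna_id[mirnas$category %in%
                                          c("known", "imprinted")]
  retained_map <- stats::setNames(
    regions$retained[regions$kind == "mirna"],
    regions$mirna_id[regions$kind == "mirna"])

  bis_loci <- utils::head(regulated, 3)
  amplicons <- generate_amplicons(bis_loci)

  manifest <- list(
    methylated_regions = list(
      reference = regions[, c("chrom", "start", "end", "kind", "mirna_id",
                              "retained")],
      demethylated = regions[regions$retained,
                             c("chrom", "start", "end", "kind", "mirna_id",
                               "retained")]),
    regulated_mirnas = regulated,
    coregulated_mirnas = coregulated,
    imprinted_or_known_ids = known_or_imprinted,
    decoy_mirnas = mirnas$mirna_id[mirnas$category == "decoy"],
    retained_in_demethylated = retained_map,
    per_cpg_methylation = stats::setNames(
      rep(config$per_cpg_methylation, length(bis_loci)), bis_loci),
    independent_regulated = regulated,
    host_genes = stats::setNames(mirnas$host_gene_id, mirnas$mirna_id),
    not_expressed_host = {
      cand <- mirnas$host_gene_id[mirnas$category == "regulated" &
                                    !is.na(mirnas$host_gene_id)]
      if (length(cand)) cand[1] else NA_character_
    })

  world <- structure(list(config = config, genome = genome, mirnas = mirnas,
                          transcripts = transcripts, amplicons = amplicons,
                          manifest = manifest),
                     class = "synth_world")
  if (!is.null(out_dir)) write_world(world, out_dir)
  world
}

# random amplicon sequences: 240 bp backbone with 16 planted CpGs and a
# handful of non-CpG cytosines (conversion-efficiency readout)
generate_amplicons <- function(locus_ids, length_bp = 240, n_cpg = 16) {
  stats::setNames(lapply(locus_ids, function(id) {
    b <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE,
                prob = c(0.35, 0.15, 0.35, 0.15))
    # break accidental CpGs so planted positions are the only ones
    for (i in seq_len(length_bp - 1)) {
      if (b[i] == "C" && b[i + 1] == "G") b[i + 1] <- "A"
    }
    pos <- round(seq(10, length_bp - 10, length.out = n_cpg))
    b[pos] <- "C"; b[pos + 1] <- "G"
    for (p in pos) if (p > 1 && b[p - 1] == "C") b[p - 1] <- "A"
    amplicon(id, paste(b, collapse = ""))
  }), locus_ids)
}

#' Extract per-sample methylome profiles from the truth manifest
#'
#' The "perfect peak caller": planted regions become called regions
#' directly, for zero-noise end-to-end tests.
#'
#' @param world a `synth_world`.
#' @return list with `reference` and `demethylated` `methylome_profile`s.
#' @export
manifest_profiles <- function(world) {
  mk <- function(df, id) {
    r <- df[, c("chrom", "start", "end")]
    r$score <- rep(NA_real_, nrow(r))
    methylome_profile(id, 1, r[order(r$chrom, r$start), , drop = FALSE])
  }
  list(reference = mk(world$manifest$methylated_regions$reference,
                      "reference"),
       demethylated = mk(world$manifest$methylated_regions$demethylated,
                         "demethylated"))
}

#' Write the world's annotation files and manifest
#'
#' @param world a `synth_world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- world$mirnas
  if (nrow(m) > 0) {
    bed <- data.frame(chrom = m$chrom, start = m$start, end = m$end,
                      name = m$mirna_id, score = 0, strand = m$strand,
                      stringsAsFactors = FALSE)
    write_bed(bed, file.path(dir, "mirnas.bed"))
  } else {
    writeLines(character(), file.path(dir, "mirnas.bed"))
  }
  write_transcripts_gff3(world$transcripts,
                         file.path(dir, "transcripts.gff3"))
  if (length(world$amplicons) > 0) {
    seqs <- Biostrings::DNAStringSet(
      vapply(world$amplicons, `[[`, character(1), "reference"))
    names(seqs) <- paste0(names(world$amplicons), "|reference")
    Biostrings::writeXStringSet(seqs, file.path(dir, "amplicons.fa"))
  }
  manifest <- world$manifest
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
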