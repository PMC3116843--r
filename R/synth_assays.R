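#' Simulate MBD-enrichment read positions for one sample
#'
#' Background reads fall as a Poisson process at `background_read_rate`
#' reads/bp; inside planted methylated regions the rate is
#' `peak_enrichment`-fold. The demethylated sample keeps enrichment only
#' over retained regions. Reads are fixed-length intervals
#' (`read_length`, default 36 bp).
#'
#' @param world a `synth_world` from [generate_world()].
#' @param sample `"reference"` or `"demethylated"`.
#' @return Interval data.frame of read positions, sorted.
#' @export
generate_mbd_reads <- function(world, sample = c("reference",
                                                 "demethylated")) {
  sample <- match.arg(sample)
  config <- world$config
  set.seed(derive_seed(config$seed, if (sample == "reference") 2 else 3))
  rl <- config$read_length
  regions <- world$manifest$methylated_regions[[sample]]
  out <- lapply(names(world$genome), function(ch) {
    L <- world$genome[[ch]]
    n_bg <- stats::rpois(1, config$background_read_rate * L)
    starts <- if (n_bg > 0) {
      floor(stats::runif(n_bg, 0, L - rl))
    } else numeric()
    rg <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(rg) > 0 && config$peak_enrichment > 1) {
      extra_rate <- config$background_read_rate *
        (config$peak_enrichment - 1)
      for (i in seq_len(nrow(rg))) {
        n_e <- stats::rpois(1, extra_rate * (rg$end[i] - rg$start[i]))
        if (n_e > 0) {
          starts <- c(starts,
                      floor(stats::runif(n_e, rg$start[i],
                                         rg$end[i] - rl)))
        }
      }
    }
    if (length(starts) == 0) return(NULL)
    data.frame(chrom = ch, start = sort(starts), end = sort(starts) + rl,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate the triplicate miRNA expression matrix
#'
#' Silenced (methylated) miRNAs start at a low baseline; in the
#' demethylated line, regulated/coregulated/known/imprinted miRNAs whose
#' proximal region was lost rise by `expression_silencing_factor`, while
#' retained-methylation miRNAs stay silenced and decoys never respond.
#' Replicate noise is multiplicative log-normal with coefficient of
#' variation `replicate_cv` (mean 1).
#'
#' @param world a `synth_world`.
#' @param n_replicates replicates per cell line (default 3).
#' @return list with `values` (miRNA x sample matrix), `sample_lines`,
#'   and the line labels `ref_line`/`demeth_line`.
#' @export
generate_expression <- function(world, n_replicates = 3) {
  config <- world$config
  set.seed(derive_seed(config$seed, 4))
  m <- world$mirnas
  responsive <- m$category %in% c("regulated", "coregulated", "known",
                                  "imprinted")
  retained <- world$manifest$retained_in_demethylated[m$mirna_id]
  retained[is.na(retained)] <- FALSE
  # common baseline keeps the per-sample median anchored on the unchanged
  # majority, as global normalization of a real array assumes
  base <- rep(100, nrow(m))
  mean_ref <- base
  mean_demeth <- ifelse(responsive & !retained,
                        base * config$expression_silencing_factor, base)
  sigma <- sqrt(log(1 + config$replicate_cv^2))
  noise <- function(n) stats::rlnorm(n, meanlog = -sigma^2 / 2,
                                     sdlog = sigma)
  n <- nrow(m)
  values <- cbind(
    matrix(rep(mean_ref, n_replicates) *
             noise(n * n_replicates), nrow = n),
    matrix(rep(mean_demeth, n_replicates) *
             noise(n * n_replicates), nrow = n))
  rownames(values) <- m$mirna_id
  colnames(values) <- c(paste0("ref_", seq_len(n_replicates)),
                        paste0("demeth_", seq_len(n_replicates)))
  list(values = values,
       sample_lines = rep(c("reference", "demethylated"),
                          each = n_replicates),
       ref_line = "reference", demeth_line = "demethylated")
}

#' Simulate qRT-PCR Ct tables for the re-expression experiment
#'
#' Primary-miRNA targets for every methylated miRNA plus their putative
#' host genes, each referenced to GAPDH, in three cell lines under
#' untreated/treated (demethylating drug) conditions with `n_replicates`
#' wells per condition. Ct follows
#' `Ct = Ct_reference + dCt_base - log2(planted fold) * treated + noise`.
#' Regulated, coregulated, known and imprinted miRNAs respond with
#' `qpcr_fold` in all lines; decoys and independent hosts do not; hosts of
#' coregulated miRNAs respond like their miRNA; one host of a regulated
#' miRNA is planted undetectable (all-NA Ct) to exercise the
#' `not_expressed` path.
#'
#' @param world a `synth_world`.
#' @param cell_lines character vector of cell-line ids (first = primary).
#' @param n_replicates wells per condition (default 3).
#' @return Ct data.frame: `target`, `reference`, `cell_line`, `condition`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @export
generate_qpcr <- function(world, cell_lines = c("lineA", "lineB", "lineC"),
                          n_replicates = 3) {
  config <- world$config
  set.seed(derive_seed(config$seed, 5))
  m <- world$mirnas
  meth <- m[m$category != "unmethylated", , drop = FALSE]
  responds <- stats::setNames(
    meth$category %in% c("regulated", "coregulated", "known", "imprinted"),
    meth$mirna_id)
  hosts <- unique(stats::na.omit(meth$host_gene_id))
  coreg_hosts <- unique(stats::na.omit(
    meth$host_gene_id[meth$category == "coregulated"]))
  na_host <- world$manifest$not_expressed_host
  targets <- c(meth$mirna_id, hosts)
  planted_fold <- c(ifelse(responds, config$qpcr_fold, 1),
                    stats::setNames(
                      ifelse(hosts %in% coreg_hosts, config$qpcr_fold, 1),
                      hosts))
  rows <- list()
  for (tg in targets) {
    undetectable <- !is.na(na_host) && tg == na_host
    for (line in cell_lines) {
      for (cond in c("untreated", "treated")) {
        ct_ref <- 20 + stats::rnorm(n_replicates, 0, config$qpcr_noise_sd)
        shift <- if (cond == "treated") log2(planted_fold[[tg]]) else 0
        ct_tg <- ct_ref + 8 - shift +
          stats::rnorm(n_replicates, 0, config$qpcr_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tg, reference = "GAPDH", cell_line = line,
          condition = cond, replicate = seq_len(n_replicates),
          ct_target = if (undetectable) NA_real_ else ct_tg,
          ct_reference = ct_ref, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(target = character(), reference = character(),
                      cell_line = character(), condition = character(),
                      replicate = integer(), ct_target = numeric(),
                      ct_reference = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate bisulfite clone sequences for the planted amplicon loci
#'
#' Per condition (baseline methylated, demethylating-drug treated,
#' demethylated derivative), each clone's CpGs are drawn
#' Bernoulli(per-CpG methylation probability) and the sequence is pushed
#' through [in_silico_convert()] at the configured conversion rate.
#'
#' @param world a `synth_world`.
#' @param n_clones clones per condition (default 8).
#' @return named list per locus: `amplicon`, `clones` (list per condition
#'   of named character vectors), `truth` (per-condition methylation
#'   probability).
#' @export
generate_bisulfite <- function(world, n_clones = 8) {
  config <- world$config
  set.seed(derive_seed(config$seed, 6))
  probs <- c(baseline = config$per_cpg_methylation,
             treated = config$per_cpg_methylation_treated,
             demethylated = 0.05)
  lapply(world$amplicons, function(amp) {
    n_cpg <- length(amp$cpg_pos)
    clones <- lapply(names(probs), function(cond) {
      v <- vapply(seq_len(n_clones), function(k) {
        state <- stats::runif(n_cpg) < probs[[cond]]
        in_silico_convert(amp$reference, state,
                          config$bisulfite_conversion_rate)
      }, character(1))
      stats::setNames(v, sprintf("%s_%02d", cond, seq_len(n_clones)))
    })
    names(clones) <- names(probs)
    list(amplicon = amp, clones = clones, truth = probs)
  })
}

#' Simulate phenotype assay tables
#'
#' Wound-healing widths, BrdU/DAPI nucleus counts, transwell migrated-cell
#' counts and a growth curve for four transfection groups, with planted
#' effects: the `mimic-b` group has impaired migration and proliferation
#' (a tumor-suppressive mimic), `mimic-a` impaired migration only.
#'
#' @param config a [world_config()] (only `seed` and `replicate_cv` are
#'   used).
#' @return list of data.frames: `wound`, `brdu`, `transwell`, `growth`.
#' @export
generate_phenotype <- function(config) {
  set.seed(derive_seed(config$seed, 7))
  cv <- max(config$replicate_cv, 1e-12)
  groups <- c("mock", "negative_control", "mimic-a", "mimic-b")
  closure <- c(mock = 0.5, negative_control = 0.5,
               `mimic-a` = 0.25, `mimic-b` = 0.25)
  wound <- do.call(rbind, lapply(groups, function(g) {
    w0 <- stats::rnorm(6, 500, 500 * cv / 4)
    w16 <- pmax(0, w0 * (1 - closure[[g]]) *
                  (1 + stats::rnorm(6, 0, cv / 2)))
    data.frame(group = g, replicate = 1:6, width_0h = w0, width_16h = w16,
               stringsAsFactors = FALSE)
  }))
  brdu_pct <- c(mock = 45, negative_control = 45,
                `mimic-a` = 45, `mimic-b` = 25)
  brdu <- do.call(rbind, lapply(groups, function(g) {
    total <- stats::rpois(3, 650)
    pos <- stats::rbinom(3, total, brdu_pct[[g]] / 100)
    data.frame(group = g, replicate = 1:3, brdu_positive = pos,
               dapi_total = total, n_fields = 4, stringsAsFactors = FALSE)
  }))
  mig_mean <- c(mock = 60, negative_control = 60,
                `mimic-a` = 30, `mimic-b` = 30)
  transwell <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, field = 1:9,
               count = stats::rpois(9, mig_mean[[g]]),
               stringsAsFactors = FALSE)
  }))
  growth_base <- c(mock = 1, negative_control = 1,
                   `mimic-a` = 1, `mimic-b` = 0.6)
  growth <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(c(0, 48, 96), function(tp) {
      mean_cells <- 8e4 * (2^(tp / 24))^growth_base[[g]]
      data.frame(group = g, replicate = 1:3, timepoint = tp,
                 value = mean_cells * (1 + stats::rnorm(3, 0, cv)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(wound) <- rownames(brdu) <- rownames(transwell) <-
    rownames(growth) <- NULL
  list(wound = wound, brdu = brdu, transwell = transwell, growth = growth)
}
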