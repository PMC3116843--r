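#' Partition candidates into excluded and novel
#'
#' Candidates on the known methylation-regulated list or in an imprinted
#' cluster are excluded from further validation; a candidate on both lists
#' is excluded once, with `known_regulated` taking precedence.
#'
#' @param candidate_ids character vector of candidate miRNA ids.
#' @param known_list ids already reported as methylation-regulated.
#' @param imprinted_list ids in imprinted-domain clusters.
#' @return data.frame `mirna_id`, `excluded_reason`
#'   (`"known_regulated"`, `"imprinted"`, or `"none"`).
#' @export
apply_exclusions <- function(candidate_ids, known_list = character(),
                             imprinted_list = character()) {
  reason <- ifelse(candidate_ids %in% known_list, "known_regulated",
                   ifelse(candidate_ids %in% imprinted_list, "imprinted",
                          "none"))
  data.frame(mirna_id = candidate_ids, excluded_reason = reason,
             stringsAsFactors = FALSE)
}

#' Run the full candidate screen
#'
#' Executes the staged funnel: methylome calling (unless precomputed
#' profiles are supplied), proximity screen, known/imprinted exclusion,
#' expression concordance, demethylating-drug re-expression with
#' cross-line confirmation, and genomic-context / host-independence
#' classification. Candidates failing a stage keep a `final_class` naming
#' that stage; nothing is silently dropped.
#'
#' @param inputs list with elements:
#'   \describe{
#'     \item{mirnas}{annotation data.frame (`mirna_id`, `chrom`, `start`,
#'       `end`).}
#'     \item{transcripts}{list of [transcript_model()].}
#'     \item{profiles}{optional list with `reference` and `demethylated`
#'       `methylome_profile`s; if absent, `reads` (list of read
#'       data.frames per sample) and `genome` are required.}
#'     \item{expression}{list as returned by [generate_expression()]:
#'       `values`, `sample_lines`, `ref_line`, `demeth_line`.}
#'     \item{ct_table}{Ct data.frame for [reexpression_results()].}
#'     \item{known_ids, imprinted_ids}{exclusion lists.}
#'   }
#' @param params list of stage parameters; defaults:
#'   `window_size` 500, `alpha` 0.01, `merge_gap` 0, `max_dist` 500,
#'   `fold_threshold` 1.5, `q_threshold` 0.05, `reexpression_alpha` 0.05,
#'   `primary_line`/`validation_lines` (first / remaining cell lines in
#'   `ct_table`), `rescue_inconsistent` FALSE (route inconsistent
#'   candidates to qPCR anyway), `promoter_flank` 1000.
#' @return list with `records` (one row per stage-1 candidate) and
#'   `report` (see [funnel_report()]).
#' @export
run_screen <- function(inputs, params = list()) {
  p <- utils::modifyList(list(window_size = 500, alpha = 0.01,
                              merge_gap = 0, max_dist = 500,
                              fold_threshold = 1.5, q_threshold = 0.05,
                              reexpression_alpha = 0.05,
                              primary_line = NULL, validation_lines = NULL,
                              rescue_inconsistent = FALSE,
                              promoter_flank = 1000),
                         params)

  profiles <- inputs$profiles
  if (is.null(profiles)) {
    if (is.null(inputs$reads) || is.null(inputs$genome)) {
      stop("stage methylome: need either profiles or reads + genome")
    }
    profiles <- lapply(names(inputs$reads), function(s) {
      call_methylome(inputs$reads[[s]], inputs$genome,
                     window_size = p$window_size, alpha = p$alpha,
                     merge_gap = p$merge_gap, sample_id = s)
    })
    names(profiles) <- names(inputs$reads)
  }

  calls <- screen_candidates(inputs$mirnas, profiles$reference,
                             profiles$demethylated, max_dist = p$max_dist)
  excl <- apply_exclusions(calls$mirna_id,
                           inputs$known_ids %||% character(),
                           inputs$imprinted_ids %||% character())
  records <- merge(calls, excl, by = "mirna_id", sort = TRUE)

  expr <- inputs$expression
  de <- differential_expression(expr$values, expr$sample_lines,
                                expr$ref_line, expr$demeth_line)
  records <- classify_concordance(records, de,
                                  fold_threshold = p$fold_threshold,
                                  q_threshold = p$q_threshold)

  # candidates forwarded to drug re-expression testing
  forward <- records$excluded_reason == "none" &
    (records$concordance %in% c("consistent_upregulated",
                                "consistent_retained_silenced") |
       (p$rescue_inconsistent & records$concordance == "inconsistent"))

  qres <- reexpression_results(inputs$ct_table,
                               alpha = p$reexpression_alpha)
  lines <- unique(inputs$ct_table$cell_line)
  primary <- p$primary_line %||% (if (length(lines)) lines[1] else NA)
  validation <- p$validation_lines %||% setdiff(lines, primary)
  conf <- confirm_across_lines(
    qres[qres$target %in% records$mirna_id[forward], , drop = FALSE],
    primary, validation)

  records$tested_reexpression <- forward &
    records$mirna_id %in% qres$target
  records$significant_primary <- records$mirna_id %in%
    qres$target[qres$cell_line == primary & qres$significant]
  records$confirmed <- records$mirna_id %in% conf$confirmed

  # context and independence for confirmed candidates
  records$context <- rep(NA_character_, nrow(records))
  records$host_gene_id <- rep(NA_character_, nrow(records))
  records$host_promoter_methylated <- rep(NA, nrow(records))
  records$host_response <- rep(NA_character_, nrow(records))
  records$independence <- rep(NA_character_, nrow(records))
  gene_ids <- vapply(inputs$transcripts, `[[`, character(1), "gene_id")
  for (i in which(records$confirmed)) {
    m <- inputs$mirnas[inputs$mirnas$mirna_id == records$mirna_id[i], ]
    cc <- classify_context(m, inputs$transcripts)
    records$context[i] <- cc$context
    records$host_gene_id[i] <- cc$host_gene_id
    hr <- NA_character_
    if (!is.na(cc$host_gene_id)) {
      host_tx <- inputs$transcripts[[match(cc$host_gene_id, gene_ids)]]
      records$host_promoter_methylated[i] <-
        promoter_methylation_flag(host_tx, profiles$reference,
                                  flank = p$promoter_flank)
      hr <- host_response(
        qres[qres$target == cc$host_gene_id, , drop = FALSE],
        qres[qres$target == records$mirna_id[i], , drop = FALSE])
      records$host_response[i] <- hr
    }
    records$independence[i] <- independence_call(cc$context, hr)
  }

  records$final_class <- funnel_final_class(records)
  report <- funnel_report(records)
  list(records = records, report = report)
}

funnel_final_class <- function(r) {
  ifelse(r$excluded_reason != "none", "excluded",
  ifelse(r$concordance == "untested", "failed_concordance_untested",
  ifelse(!(r$concordance %in% c("consistent_upregulated",
                                "consistent_retained_silenced")) &
           !r$tested_reexpression, "failed_concordance",
  ifelse(!r$tested_reexpression, "failed_reexpression_untested",
  ifelse(!r$significant_primary, "failed_primary_reexpression",
  ifelse(!r$confirmed, "failed_validation",
  ifelse(r$independence == "independent", "novel_meth_regulated",
         "failed_independence")))))))
}

#' Per-stage funnel report
#'
#' Counts and id lists for every stage of the screen, with the
#' monotonicity invariant (novel >= consistent >= up-regulated >=
#' confirmed >= final; exclusions accounted separately) enforced — an
#' inconsistent record set is an internal error, never silently corrected.
#'
#' @param records candidate records from [run_screen()].
#' @return list of per-stage id vectors and a `counts` named vector.
#' @export
funnel_report <- function(records) {
  ids <- function(sel) sort(records$mirna_id[sel])
  proximal <- ids(rep(TRUE, nrow(records)))
  excluded <- ids(records$excluded_reason != "none")
  novel <- ids(records$excluded_reason == "none")
  consistent <- ids(records$excluded_reason == "none" &
                      records$concordance %in%
                        c("consistent_upregulated",
                          "consistent_retained_silenced"))
  upregulated <- ids(records$excluded_reason == "none" &
                       records$tested_reexpression &
                       records$significant_primary)
  confirmed <- ids(records$confirmed)
  final <- ids(!is.na(records$final_class) &
                 records$final_class == "novel_meth_regulated")
  counts <- c(proximal = length(proximal),
              known_or_imprinted_excluded = length(excluded),
              novel_candidates = length(novel),
              expression_consistent = length(consistent),
              aza_upregulated_primary = length(upregulated),
              confirmed_all_lines = length(confirmed),
              independent_final = length(final))
  mono <- c(counts["novel_candidates"], counts["aza_upregulated_primary"],
            counts["confirmed_all_lines"], counts["independent_final"])
  if (any(diff(mono) > 0) ||
      counts["proximal"] != counts["novel_candidates"] +
        counts["known_or_imprinted_excluded"] ||
      !all(final %in% confirmed) || !all(confirmed %in% upregulated)) {
    stop("internal error: funnel counts are not monotone")
  }
  list(proximal = proximal, known_or_imprinted_excluded = excluded,
       novel_candidates = novel, expression_consistent = consistent,
       aza_upregulated_primary = upregulated,
       confirmed_all_lines = confirmed, independent_final = final,
       counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the screen end-to-end on a synthetic world
#'
#' Convenience wrapper generating all assay data from the world's
#' manifest and invoking [run_screen()].
#'
#' @param world a `synth_world`.
#' @param perfect_peaks use the manifest's planted regions directly as
#'   called regions (zero-noise mode) instead of simulating reads and
#'   calling peaks.
#' @param params passed to [run_screen()].
#' @return [run_screen()] result.
#' @export
screen_synthetic_world <- function(world, perfect_peaks = FALSE,
                                   params = list()) {
  inputs <- list(
    mirnas = world$mirnas,
    transcripts = world$transcripts,
    expression = generate_expression(world),
    ct_table = generate_qpcr(world),
    known_ids = world$mirnas$mirna_id[
      world$mirnas$known_methylation_regulated],
    imprinted_ids = world$mirnas$mirna_id[world$mirnas$imprinted_cluster])
  if (perfect_peaks) {
    inputs$profiles <- manifest_profiles(world)
  } else {
    inputs$reads <- list(reference = generate_mbd_reads(world, "reference"),
                         demethylated = generate_mbd_reads(world,
                                                           "demethylated"))
    inputs$genome <- world$genome
  }
  run_screen(inputs, params)
}
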