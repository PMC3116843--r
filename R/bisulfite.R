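#' In-silico bisulfite conversion of a reference sequence
#'
#' Models the conversion chemistry: unmethylated cytosines deaminate to
#' uracil and read as T, with efficiency `conversion_rate`; methylated
#' CpG cytosines are protected. Cytosines outside a CpG context are
#' treated as unmethylated. Only the converted top strand is modeled.
#'
#' @param reference DNA string (A/C/G/T).
#' @param methylation_state logical vector, one flag per CpG position of
#'   the reference (TRUE = methylated, protected).
#' @param conversion_rate probability an unmethylated C converts
#'   (default 1).
#' @return Converted DNA string.
#' @export
in_silico_convert <- function(reference, methylation_state,
                              conversion_rate = 1) {
  stopifnot(conversion_rate >= 0, conversion_rate <= 1)
  bases <- strsplit(toupper(reference), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) stop("invalid DNA alphabet")
  cpg <- cpg_positions(reference)
  stopifnot(length(methylation_state) == length(cpg))
  protected <- rep(FALSE, length(bases))
  protected[cpg[methylation_state]] <- TRUE
  c_idx <- which(bases == "C" & !protected)
  convert <- c_idx[stats::runif(length(c_idx)) < conversion_rate]
  bases[convert] <- "T"
  paste(bases, collapse = "")
}

#' CpG dinucleotide positions in a reference sequence
#'
#' @param reference DNA string.
#' @return Integer vector of 1-based positions of the C of each CpG.
#' @export
cpg_positions <- function(reference) {
  ref <- toupper(reference)
  unlist(gregexpr("CG", ref, fixed = TRUE)[[1]]) |> (\(p) p[p > 0])()
}

#' Construct an amplicon record
#'
#' @param locus_id locus identifier.
#' @param reference genomic (unconverted) reference sequence of the
#'   amplicon.
#' @return list with `locus_id`, `reference`, `cpg_pos` (1-based C
#'   positions of each CpG).
#' @export
amplicon <- function(locus_id, reference) {
  pos <- cpg_positions(reference)
  if (length(pos) == 0) stop("amplicon contains no CpG: ", locus_id)
  list(locus_id = locus_id, reference = toupper(reference), cpg_pos = pos)
}

#' Score one bisulfite clone against its amplicon
#'
#' The clone must be in the same coordinate frame as the reference (equal
#' length; clones are fixture-generated, not aligned). At each CpG
#' position: C reads as methylated, T as unmethylated, anything else as
#' ambiguous.
#'
#' @param amp amplicon from [amplicon()].
#' @param clone clone DNA string, same length as the reference.
#' @param clone_id identifier.
#' @return list with `locus_id`, `clone_id`, `calls` (character vector
#'   `"methylated"`/`"unmethylated"`/`"ambiguous"`, one per CpG).
#' @export
call_clone <- function(amp, clone, clone_id = "clone") {
  clone <- toupper(clone)
  if (nchar(clone) != nchar(amp$reference)) {
    stop(sprintf("clone/reference length mismatch at %s: %d vs %d",
                 amp$locus_id, nchar(clone), nchar(amp$reference)))
  }
  b <- substring(clone, amp$cpg_pos, amp$cpg_pos)
  calls <- ifelse(b == "C", "methylated",
                  ifelse(b == "T", "unmethylated", "ambiguous"))
  list(locus_id = amp$locus_id, clone_id = clone_id, calls = calls)
}

#' Summarize clone calls for one locus
#'
#' Per-CpG methylated fractions (ambiguous calls excluded from the
#' denominator), the overall percent methylation, and a plain-text
#' lollipop grid, one row per clone, with filled circles for methylated
#' and open circles for unmethylated CpGs. Fewer than `min_clones` clones
#' triggers a warning (standard practice sequences at least eight), never
#' a failure.
#'
#' @param clones list of clone calls from [call_clone()], same locus.
#' @param min_clones minimum clone count before warning (default 8).
#' @return list with `locus_id`, `n_clones`, `per_cpg_fraction`,
#'   `overall_percent`, `lollipop` (character vector of grid rows),
#'   `below_minimum`.
#' @export
locus_summary <- function(clones, min_clones = 8) {
  stopifnot(length(clones) >= 1)
  ids <- unique(vapply(clones, `[[`, character(1), "locus_id"))
  if (length(ids) != 1) stop("inconsistent locus ids: ",
                             paste(ids, collapse = ", "))
  mat <- do.call(rbind, lapply(clones, `[[`, "calls"))
  meth <- colSums(mat == "methylated")
  unmeth <- colSums(mat == "unmethylated")
  frac <- ifelse(meth + unmeth > 0, meth / (meth + unmeth), NA_real_)
  below <- length(clones) < min_clones
  if (below) {
    warning(sprintf("locus %s: only %d clones (< %d)",
                    ids, length(clones), min_clones))
  }
  glyph <- c(methylated = "\u25CF", unmethylated = "\u25CB",
             ambiguous = "?")
  lollipop <- apply(mat, 1, function(r) paste(glyph[r], collapse = " "))
  list(locus_id = ids, n_clones = length(clones),
       per_cpg_fraction = unname(frac),
       overall_percent = 100 * mean(frac, na.rm = TRUE),
       lollipop = unname(lollipop),
       below_minimum = below)
}

#' Compare methylation between baseline and treated summaries
#'
#' Per-CpG and overall change in methylated fraction; negative deltas mean
#' demethylation (as after 5-aza-dC treatment).
#'
#' @param baseline,treated summaries from [locus_summary()] for the same
#'   amplicon.
#' @return list with `per_cpg_delta`, `overall_delta`.
#' @export
demethylation_compare <- function(baseline, treated) {
  if (length(baseline$per_cpg_fraction) != length(treated$per_cpg_fraction)) {
    stop("CpG count mismatch between summaries")
  }
  delta <- treated$per_cpg_fraction - baseline$per_cpg_fraction
  list(per_cpg_delta = delta, overall_delta = mean(delta, na.rm = TRUE))
}

#' Read amplicon reference and clones from FASTA
#'
#' Sequence ids follow the convention `locus|clone`; the record named
#' `locus|reference` is the unconverted genomic reference.
#'
#' @param path FASTA file.
#' @return named list per locus: `amplicon` and character vector `clones`
#'   (named by clone id).
#' @export
read_bisulfite_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  locus <- vapply(parts, `[`, character(1), 1)
  member <- vapply(parts, `[`, character(1), 2)
  out <- list()
  for (lc in unique(locus)) {
    sel <- locus == lc
    refs <- which(sel & member == "reference")
    if (length(refs) != 1) stop("locus ", lc, " needs exactly one reference")
    clones <- as.character(seqs[sel & member != "reference"])
    names(clones) <- member[sel & member != "reference"]
    out[[lc]] <- list(amplicon = amplicon(lc, as.character(seqs[[refs]])),
                      clones = clones)
  }
  out
}

#' Score all clones of one locus
#'
#' @param locus element of [read_bisulfite_fasta()] output (or a list with
#'   `amplicon` and named `clones`).
#' @param min_clones passed to [locus_summary()].
#' @return the [locus_summary()] of all clones.
#' @export
score_locus <- function(locus, min_clones = 8) {
  calls <- lapply(names(locus$clones), function(cid) {
    call_clone(locus$amplicon, locus$clones[[cid]], cid)
  })
  locus_summary(calls, min_clones)
}
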