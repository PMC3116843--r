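#' Relative quantification by the 2^-ddCt method
#'
#' Computes per-replicate dCt = Ct_target - Ct_reference within each
#' condition, ddCt = mean(dCt treated) - mean(dCt untreated), and the
#' relative fold 2^(-ddCt), so the untreated condition is normalized to 1.
#' Mature miRNAs are conventionally referenced to U6 snoRNA, primary
#' miRNAs and host genes to GAPDH; the function is agnostic and pairs
#' whatever reference wells are supplied.
#'
#' @param ct data.frame with columns `target`, `reference`, `condition`
#'   (`"untreated"`/`"treated"`), `replicate`, `ct_target`, `ct_reference`.
#' @return list with `fold`, `ddct`, `dct_treated`, `dct_untreated`
#'   (per-replicate dCt vectors). Targets undetectable in every well
#'   (all-NA Ct) return `fold = NA` with `detectable = FALSE`.
#' @export
delta_delta_ct <- function(ct) {
  need <- c("condition", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  if (any(is.na(ct$ct_reference))) {
    stop("reference wells missing for target ",
         paste(unique(ct$target), collapse = ","))
  }
  if (all(is.na(ct$ct_target))) {
    return(list(fold = NA_real_, ddct = NA_real_,
                dct_treated = numeric(), dct_untreated = numeric(),
                detectable = FALSE))
  }
  dct <- ct$ct_target - ct$ct_reference
  dct_t <- dct[ct$condition == "treated"]
  dct_u <- dct[ct$condition == "untreated"]
  if (!length(dct_t) || !length(dct_u)) stop("both conditions required")
  ddct <- mean(dct_t) - mean(dct_u)
  list(fold = 2^(-ddct), ddct = ddct,
       dct_treated = dct_t, dct_untreated = dct_u,
       detectable = TRUE)
}

#' Test re-expression after demethylating treatment
#'
#' Student's (equal-variance) two-sided t test on the replicate dCt values
#' of the two conditions; replicates are unpaired. Because re-expression
#' is a directional claim, the significance flag additionally requires
#' fold > 1. Zero-variance corner cases follow the [welch_test()]
#' conventions.
#'
#' @param dd result of [delta_delta_ct()].
#' @param alpha significance level (default 0.05).
#' @return list with `fold`, `p_value`, `significant`, `detectable`.
#' @export
reexpression_test <- function(dd, alpha = 0.05) {
  if (!isTRUE(dd$detectable)) {
    return(list(fold = NA_real_, p_value = NA_real_,
                significant = FALSE, detectable = FALSE))
  }
  x <- dd$dct_treated; y <- dd$dct_untreated
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  } else {
    p <- stats::t.test(x, y, var.equal = TRUE)$p.value
  }
  list(fold = dd$fold, p_value = p,
       significant = (p < alpha) && (dd$fold > 1),
       detectable = TRUE)
}

#' Quantify aza re-expression for every target and cell line in a Ct table
#'
#' @param ct_table data.frame with columns `target`, `reference`,
#'   `cell_line`, `condition`, `replicate`, `ct_target`, `ct_reference`.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `target`, `cell_line`, `fold`, `p_value`,
#'   `significant`, `detectable`.
#' @export
reexpression_results <- function(ct_table, alpha = 0.05) {
  if (nrow(ct_table) == 0) {
    return(data.frame(target = character(), cell_line = character(),
                      fold = numeric(), p_value = numeric(),
                      significant = logical(), detectable = logical(),
                      stringsAsFactors = FALSE))
  }
  keys <- unique(ct_table[, c("target", "cell_line")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ct_table[ct_table$target == keys$target[i] &
                    ct_table$cell_line == keys$cell_line[i], ]
    rr <- reexpression_test(delta_delta_ct(sub), alpha)
    data.frame(target = keys$target[i], cell_line = keys$cell_line[i],
               fold = rr$fold, p_value = rr$p_value,
               significant = rr$significant, detectable = rr$detectable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confirm re-expression across independent cell lines
#'
#' A target is confirmed when it is significantly re-expressed in the
#' primary line and in every validation line in which it was tested;
#' targets significant in the primary line but not in all validation
#' lines are reported as partial, never silently dropped.
#'
#' @param results data.frame from [reexpression_results()].
#' @param primary_line primary cell-line id.
#' @param validation_lines character vector of validation cell-line ids.
#' @return list with `confirmed`, `partial` (target id vectors) and the
#'   per-line significance table `detail`.
#' @export
confirm_across_lines <- function(results, primary_line, validation_lines) {
  if (nrow(results) == 0) {
    return(list(confirmed = character(), partial = character(),
                detail = results))
  }
  if (!primary_line %in% results$cell_line) {
    stop("primary line absent from results: ", primary_line)
  }
  targets <- unique(results$target)
  sig_in <- function(tg, line) {
    r <- results[results$target == tg & results$cell_line == line, ]
    nrow(r) > 0 && isTRUE(r$significant[1])
  }
  confirmed <- character(); partial <- character()
  for (tg in targets) {
    if (!sig_in(tg, primary_line)) next
    tested <- validation_lines[validation_lines %in%
                                 results$cell_line[results$target == tg]]
    if (all(vapply(tested, function(l) sig_in(tg, l), logical(1)))) {
      confirmed <- c(confirmed, tg)
    } else {
      partial <- c(partial, tg)
    }
  }
  list(confirmed = sort(confirmed), partial = sort(partial),
       detail = results)
}
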