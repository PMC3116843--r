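#' Median-scale normalize an expression matrix
#'
#' Scales every sample (column) so its median equals the grand median of
#' all sample medians. Monotone within each sample, and a fixed point when
#' sample medians already agree.
#'
#' @param values numeric matrix, miRNAs x samples, non-negative.
#' @return Matrix of the same shape with attribute
#'   `"normalization" = "median-scaling"`.
#' @export
normalize_matrix <- function(values) {
  stopifnot(is.matrix(values), ncol(values) >= 1)
  med <- apply(values, 2, stats::median)
  if (any(med == 0)) {
    stop("all-zero (zero-median) sample cannot be normalized: ",
         paste(colnames(values)[med == 0], collapse = ", "))
  }
  target <- stats::median(med)
  out <- sweep(values, 2, target / med, `*`)
  attr(out, "normalization") <- "median-scaling"
  out
}

#' Welch's two-sample t test with degenerate-input conventions
#'
#' Delegates to [stats::t.test()] (unequal variances, Welch–Satterthwaite
#' df, two-sided) but defines the zero-variance corner cases the screen
#' can produce with noise-free replicates: if both groups have zero
#' variance and equal means, p = 1; if both have zero variance and
#' different means, p = 0 and the result is flagged degenerate.
#'
#' @param x,y numeric replicate vectors (length >= 2 each).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
welch_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control via [stats::p.adjust()]; q values
#' are returned in the original order.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return q values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Differential expression between reference and demethylated lines
#'
#' For each miRNA, computes group means on the normalized linear scale,
#' the fold change demethylated/reference, Welch's t test across
#' replicates, and BH-adjusted q values across all tested miRNAs.
#'
#' @param values numeric matrix, miRNAs x samples (rownames = miRNA ids).
#' @param sample_lines character vector, one entry per column, naming the
#'   cell line of each replicate.
#' @param ref_line,demeth_line cell-line labels of the methylated
#'   reference and the demethylated derivative.
#' @param normalize logical; median-scale first (default TRUE).
#' @param log_scale test on log2 intensities (default TRUE). Array
#'   replicate noise is multiplicative, so log intensity is the
#'   approximately homoscedastic normal scale; fold changes are always
#'   reported on linear group means.
#' @return data.frame: `mirna_id`, `mean_ref`, `mean_demeth`,
#'   `fold_change`, `t_stat`, `df`, `p_value`, `q_value`.
#' @export
differential_expression <- function(values, sample_lines,
                                    ref_line, demeth_line,
                                    normalize = TRUE, log_scale = TRUE) {
  stopifnot(ncol(values) == length(sample_lines))
  if (sum(sample_lines == ref_line) < 2 ||
      sum(sample_lines == demeth_line) < 2) {
    stop("need >= 2 replicates per cell line")
  }
  if (normalize) values <- normalize_matrix(values)
  if (log_scale && any(values <= 0)) {
    stop("log-scale testing requires positive intensities")
  }
  xi <- sample_lines == ref_line
  yi <- sample_lines == demeth_line
  res <- lapply(rownames(values), function(id) {
    x <- values[id, xi]; y <- values[id, yi]
    wt <- if (log_scale) welch_test(log2(y), log2(x))
          else welch_test(y, x)   # demethylated vs reference
    data.frame(mirna_id = id,
               mean_ref = mean(x), mean_demeth = mean(y),
               fold_change = mean(y) / mean(x),
               t_stat = wt$t, df = wt$df, p_value = wt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- fdr_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Classify expression concordance with methylation status
#'
#' Applies the concordance rule of the screen: a candidate whose proximal
#' methylation is lost in the demethylated line and whose expression rises
#' at least `fold_threshold` (significantly at `q_threshold`) is
#' `consistent_upregulated`; one that retains methylation and stays below
#' the fold threshold is `consistent_retained_silenced`; anything else is
#' `inconsistent`. A candidate missing from the expression results is
#' marked `untested`, never dropped. The fold gate is inclusive
#' (fold == 1.5 passes).
#'
#' @param calls proximity-call data.frame from [screen_candidates()].
#' @param de differential-expression data.frame from
#'   [differential_expression()].
#' @param fold_threshold fold-change gate (default 1.5).
#' @param q_threshold FDR gate (default 0.05).
#' @return `calls` with columns `fold_change`, `q_value`, `concordance`.
#' @export
classify_concordance <- function(calls, de, fold_threshold = 1.5,
                                 q_threshold = 0.05) {
  m <- match(calls$mirna_id, de$mirna_id)
  fold <- de$fold_change[m]
  q <- de$q_value[m]
  cls <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (is.na(m[i])) {
      cls[i] <- "untested"
    } else if (!calls$methylated_in_demethylated[i] &&
               fold[i] >= fold_threshold && q[i] < q_threshold) {
      cls[i] <- "consistent_upregulated"
    } else if (calls$methylated_in_demethylated[i] &&
               fold[i] < fold_threshold) {
      cls[i] <- "consistent_retained_silenced"
    } else {
      cls[i] <- "inconsistent"
    }
  }
  calls$fold_change <- fold
  calls$q_value <- q
  calls$concordance <- cls
  calls
}
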