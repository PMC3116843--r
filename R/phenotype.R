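#' Wound-healing closure fraction
#'
#' Fraction of the wound width closed between 0 h and the endpoint:
#' `(width_0h - width_16h) / width_0h`. Negative values (the wound
#' widened) are reported as-is.
#'
#' @param width_0h wound width immediately after wounding (µm, > 0).
#' @param width_16h wound width at the endpoint (µm, >= 0).
#' @return Closed fraction (vectorised).
#' @export
wound_closure <- function(width_0h, width_16h) {
  if (any(width_0h <= 0)) stop("width_0h must be positive")
  if (any(width_16h < 0)) stop("width_16h must be non-negative")
  (width_0h - width_16h) / width_0h
}

#' Normalize group values to the mock-transfection mean
#'
#' @param values numeric vector of per-replicate group values.
#' @param mock_values numeric vector of mock-group values.
#' @return `values / mean(mock_values)`.
#' @export
normalize_to_mock <- function(values, mock_values) {
  m <- mean(mock_values)
  if (m == 0) stop("mock group mean is zero")
  values / m
}

#' BrdU incorporation percentage with counting QC
#'
#' @param brdu_positive BrdU-positive nucleus count.
#' @param dapi_total total DAPI-stained nucleus count (>= positive, > 0).
#' @param n_fields number of microscope fields counted.
#' @param min_nuclei,min_fields QC thresholds (defaults 600 nuclei,
#'   4 fields).
#' @return list with `percent` and character vector `flags`
#'   (`"undercount"`, `"few_fields"`).
#' @export
brdu_fraction <- function(brdu_positive, dapi_total, n_fields,
                          min_nuclei = 600, min_fields = 4) {
  if (dapi_total == 0) stop("no DAPI-stained nuclei counted")
  stopifnot(dapi_total >= brdu_positive, brdu_positive >= 0)
  flags <- character()
  if (dapi_total < min_nuclei) flags <- c(flags, "undercount")
  if (n_fields < min_fields) flags <- c(flags, "few_fields")
  list(percent = 100 * brdu_positive / dapi_total, flags = flags)
}

#' Transwell migration change relative to mock
#'
#' Mean migrated-cell count of the group divided by the mock group mean,
#' with a QC flag when fewer than `min_fields` microscope fields were
#' counted.
#'
#' @param group_counts per-field migrated-cell counts for the group.
#' @param mock_counts per-field counts for mock-transfected cells.
#' @param min_fields QC threshold (default 9 fields per membrane).
#' @return list with `ratio` and `flags`.
#' @export
migration_change <- function(group_counts, mock_counts, min_fields = 9) {
  stopifnot(length(group_counts) >= 1, length(mock_counts) >= 1)
  if (mean(mock_counts) == 0) stop("mock group mean is zero")
  flags <- character()
  if (length(group_counts) < min_fields || length(mock_counts) < min_fields) {
    flags <- c(flags, "few_fields")
  }
  list(ratio = mean(group_counts) / mean(mock_counts), flags = flags)
}

#' Student's t comparison of two replicate groups
#'
#' Pooled-variance two-sided t test with a significance flag at
#' `alpha` and the degenerate-input conventions of [welch_test()].
#'
#' @param a,b numeric replicate vectors (length >= 2).
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `p`, `significant`.
#' @export
group_compare <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, p = 1, significant = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                significant = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha)
}

#' Summarize a phenotype assay table
#'
#' Per-group summaries with mock normalization and pairwise Student's t
#' comparison of every group against mock. Wound tables need columns
#' `group`, `replicate`, `width_0h`, `width_16h`; BrdU tables `group`,
#' `replicate`, `brdu_positive`, `dapi_total`, `n_fields`; transwell
#' tables `group`, `field`, `count`; growth/MTT tables `group`,
#' `replicate`, `timepoint`, `value` (summarized as per-timepoint means
#' and SD, no curve fitting).
#'
#' @param table assay data.frame.
#' @param assay one of `"wound"`, `"brdu"`, `"transwell"`, `"growth"`.
#' @param mock_group label of the mock group (default `"mock"`).
#' @return data.frame of per-group summaries with `p_value` vs mock.
#' @export
summarize_assay <- function(table, assay = c("wound", "brdu", "transwell",
                                             "growth"),
                            mock_group = "mock") {
  assay <- match.arg(assay)
  groups <- unique(table$group)
  if (!mock_group %in% groups) stop("mock group absent: ", mock_group)
  per_rep <- switch(assay,
    wound = {
      v <- wound_closure(table$width_0h, table$width_16h)
      split(v, table$group)
    },
    brdu = {
      v <- 100 * table$brdu_positive / table$dapi_total
      split(v, table$group)
    },
    transwell = split(table$count, table$group),
    growth = {
      # per-timepoint group means compared at the final timepoint
      tp <- max(table$timepoint)
      split(table$value[table$timepoint == tp],
            table$group[table$timepoint == tp])
    })
  mock_vals <- per_rep[[mock_group]]
  rows <- lapply(groups, function(g) {
    v <- per_rep[[g]]
    cmp <- if (g == mock_group) list(t = 0, p = 1, significant = FALSE)
           else group_compare(v, mock_vals)
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = stats::sd(v),
               normalized = mean(v) / mean(mock_vals),
               p_value = cmp$p, significant = cmp$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
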