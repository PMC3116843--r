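test_that("the ten confirmed candidates classify as 7 intronic + 3 intergenic", {
  fx <- confirmed_candidates_fixture()
  ctx <- vapply(seq_len(nrow(fx$mirnas)), function(i) {
    classify_context(fx$mirnas[i, ], fx$transcripts)$context
  }, character(1))
  expect_equal(sum(ctx == "intronic"), 7)
  expect_equal(sum(ctx == "intergenic"), 3)
  # classification matches the published per-miRNA contexts
  expect_equal(ctx, fx$records$context)
  hosts <- vapply(seq_len(nrow(fx$mirnas)), function(i) {
    classify_context(fx$mirnas[i, ], fx$transcripts)$host_gene_id
  }, character(1))
  expect_equal(hosts, fx$records$host_gene_id)
})

test_that("a miRNA overlapping no transcript is intergenic", {
  cc <- classify_context(
    data.frame(mirna_id = "m", chrom = "chr9", start = 100, end = 180),
    list())
  expect_equal(cc$context, "intergenic")
  expect_true(is.na(cc$host_gene_id))
})

test_that("nested transcripts: smallest containing host, all reported", {
  outer <- transcript_model("OUTER", "chr1", 0, 50000,
                            exons = data.frame(start = 0, end = 100))
  inner <- transcript_model("INNER", "chr1", 10000, 20000,
                            exons = data.frame(start = 10000, end = 10100))
  m <- data.frame(mirna_id = "m", chrom = "chr1", start = 15000, end = 15080)
  cc <- classify_context(m, list(outer, inner))
  expect_equal(cc$host_gene_id, "INNER")
  expect_setequal(cc$all_host_genes, c("OUTER", "INNER"))
  # exhaustive containment oracle
  for (tx in list(outer, inner)) {
    expect_true(tx$start <= m$start && m$end <= tx$end)
  }
})

test_that("exon overlap makes a contained miRNA exonic", {
  tx <- transcript_model("G", "chr1", 0, 10000,
                         exons = data.frame(start = c(0, 5000),
                                            end = c(200, 5200)))
  inside_exon <- data.frame(mirna_id = "m", chrom = "chr1",
                            start = 5100, end = 5180)
  expect_equal(classify_context(inside_exon, list(tx))$context, "exonic")
  straddling <- data.frame(mirna_id = "m", chrom = "chr1",
                           start = 4950, end = 5030)
  expect_equal(classify_context(straddling, list(tx))$context, "exonic")
})

test_that("promoter methylation uses a half-open +/-1000 bp TSS window", {
  tx <- transcript_model("G", "chr1", 5000, 13000)
  prof_at <- function(start, end) {
    methylome_profile("p", 1, data.frame(chrom = "chr1", start = start,
                                         end = end, score = 1))
  }
  # region exactly abutting TSS+1000 does not overlap the half-open window
  expect_false(promoter_methylation_flag(tx, prof_at(6000, 7000)))
  expect_true(promoter_methylation_flag(tx, prof_at(5999, 7000)))
  expect_true(promoter_methylation_flag(tx, prof_at(4500, 5100)))
  expect_false(promoter_methylation_flag(
    tx, methylome_profile("p", 1,
                          data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), score = numeric()))))
  # minus-strand transcript: TSS at the high-coordinate end
  txm <- transcript_model("G", "chr1", 5000, 13000, strand = "-")
  expect_true(promoter_methylation_flag(txm, prof_at(13500, 13600)))
  expect_false(promoter_methylation_flag(txm, prof_at(5000, 5100)))
})

test_that("the ANKRD30BL-like fixture promoter is flagged methylated", {
  fx <- confirmed_candidates_fixture()
  flags <- vapply(fx$records$host_gene_id, function(g) {
    if (is.na(g)) return(NA)
    promoter_methylation_flag(fx$transcripts[[g]], fx$reference_regions)
  }, logical(1))
  expect_equal(unname(flags), fx$records$host_promoter_methylated)
  expect_true(flags[["ANKRD30BL"]])
})

test_that("the independence decision table matches a hand-written truth table", {
  truth <- list(
    list("intergenic", NA, "independent"),
    list("intergenic", "concordant_increase", "independent"),
    list("intronic", "no_change", "independent"),
    list("intronic", "not_expressed", "independent"),
    list("intronic", "inconsistent_increase", "possibly_coregulated"),
    list("intronic", "concordant_increase", "possibly_coregulated"),
    list("intronic", NA, "indeterminate"),
    list("exonic", "no_change", "indeterminate"),
    list("exonic", NA, "indeterminate"))
  for (case in truth) {
    expect_equal(independence_call(case[[1]], case[[2]]), case[[3]])
  }
  expect_error(independence_call("intronic", "bogus"), "unknown")
  expect_error(independence_call("upstream"), "intergenic")
})

test_that("the published ten-candidate table yields 8 independent calls", {
  fx <- confirmed_candidates_fixture()
  calls <- vapply(seq_len(nrow(fx$records)), function(i) {
    independence_call(fx$records$context[i], fx$records$host_response[i])
  }, character(1))
  expect_equal(sum(calls == "independent"), 8)
  expect_setequal(fx$records$mirna_id[calls == "possibly_coregulated"],
                  c("hsa-miR-24-1", "hsa-miR-27b"))
})

test_that("host response derives from cross-line significance patterns", {
  res <- function(lines, sig, detect = TRUE) {
    data.frame(target = "x", cell_line = lines, fold = 2, p_value = 0.01,
               significant = sig, detectable = detect,
               stringsAsFactors = FALSE)
  }
  mirna <- res(c("L1", "L2", "L3"), c(TRUE, TRUE, TRUE))
  expect_equal(host_response(res(c("L1", "L2", "L3"), rep(FALSE, 3)),
                             mirna), "no_change")
  expect_equal(host_response(res(c("L1", "L2", "L3"),
                                 c(TRUE, FALSE, FALSE)), mirna),
               "inconsistent_increase")
  expect_equal(host_response(res(c("L1", "L2", "L3"), rep(TRUE, 3)),
                             mirna), "concordant_increase")
  expect_equal(host_response(res(c("L1", "L2", "L3"), rep(FALSE, 3),
                                 detect = FALSE), mirna), "not_expressed")
})
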