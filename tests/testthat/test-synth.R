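test_that("configuration invariants are enforced", {
  expect_error(world_config(frac_methylated_mirnas = 1.2), "\\[0, 1\\]")
  expect_error(world_config(peak_enrichment = 0.5), "peak_enrichment")
  expect_error(world_config(genome_length = 1000), "largest feature")
  expect_error(world_config(n_mirnas = 5, n_known_regulated = 10),
               "exceed")
})

test_that("a world without miRNAs is empty but well-formed", {
  w <- generate_world(world_config(n_mirnas = 0, seed = 2,
                                   n_known_regulated = 0, n_imprinted = 0,
                                   n_coregulated = 0, n_decoys = 0))
  expect_equal(nrow(w$mirnas), 0)
  expect_length(w$manifest$regulated_mirnas, 0)
  d <- tempfile(); write_world(w, d)
  expect_true(file.exists(file.path(d, "mirnas.bed")))
  expect_length(readLines(file.path(d, "mirnas.bed")), 0)
  expect_true(file.exists(file.path(d, "transcripts.gff3")))
})

test_that("the same seed reproduces byte-identical world files", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_world(world_config(seed = 5), out_dir = d1)
  generate_world(world_config(seed = 5), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # and a different seed does not
  d3 <- tempfile()
  generate_world(world_config(seed = 6), out_dir = d3)
  expect_false(identical(tools::md5sum(file.path(d1, "manifest.json"))[[1]],
                         tools::md5sum(file.path(d3, "manifest.json"))[[1]]))
})

test_that("all generators are deterministic under the config seed", {
  w <- generate_world(world_config(seed = 41))
  w2 <- generate_world(world_config(seed = 41))
  expect_identical(generate_mbd_reads(w, "reference"),
                   generate_mbd_reads(w2, "reference"))
  expect_identical(generate_expression(w), generate_expression(w2))
  expect_identical(generate_qpcr(w), generate_qpcr(w2))
  expect_identical(generate_bisulfite(w), generate_bisulfite(w2))
  expect_identical(generate_phenotype(w$config),
                   generate_phenotype(w2$config))
})

test_that("planted regulated miRNAs sit within 500 bp of planted regions", {
  w <- cached_world(seed = 29, frac_methylated_mirnas = 0.3, n_mirnas = 50,
                    key = "prox30")
  reg <- w$manifest$regulated_mirnas
  expect_length(reg, 15)
  regions <- w$manifest$methylated_regions$reference
  for (id in reg) {
    m <- w$mirnas[w$mirnas$mirna_id == id, ]
    gaps <- vapply(seq_len(nrow(regions)), function(i) {
      gap_distance(m, regions[i, ])
    }, numeric(1))
    expect_lte(min(gaps), 500)
  }
  # regulated and coregulated sets are disjoint
  expect_length(intersect(w$manifest$regulated_mirnas,
                          w$manifest$coregulated_mirnas), 0)
})

test_that("background window counts fit a Poisson distribution", {
  # pure-background world large enough for ~10,000 windows
  w <- cached_world(seed = 3, peak_enrichment = 1, genome_length = 2500000,
                    n_background_regions = 0, key = "gof")
  reads <- generate_mbd_reads(w, "reference")
  wc <- count_reads_in_windows(reads, 500, w$genome)
  counts <- wc$counts$count
  expect_gte(length(counts), 10000)
  lambda <- mean(counts)
  # chi-square GOF with pooled tail bins (expected >= 5)
  ks <- 0:max(counts)
  expected <- dpois(ks, lambda) * length(counts)
  expected[length(expected)] <- expected[length(expected)] +
    ppois(max(counts), lambda, lower.tail = FALSE) * length(counts)
  observed <- tabulate(counts + 1, nbins = length(ks))
  keep <- expected >= 5
  obs <- c(sum(observed[!keep]), observed[keep])
  exp <- c(sum(expected[!keep]), expected[keep])
  stat <- sum((obs - exp)^2 / exp)
  p <- pchisq(stat, df = length(obs) - 2, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("with no background rate every read supports a planted region", {
  w <- cached_world(seed = 47, background_read_rate = 0, key = "nobg")
  reads <- generate_mbd_reads(w, "reference")
  regions <- w$manifest$methylated_regions$reference
  if (nrow(reads) > 0) {
    inside <- vapply(seq_len(nrow(reads)), function(i) {
      any(regions$chrom == reads$chrom[i] &
            regions$start <= reads$start[i] & reads$end[i] <= regions$end)
    }, logical(1))
    expect_true(all(inside))
  }
  expect_equal(nrow(reads), 0)  # enrichment scales the background rate
})

test_that("expression generator hits its planted moments", {
  # many intergenic regulated miRNAs for a tight Monte-Carlo bound
  w <- cached_world(seed = 61, n_mirnas = 1000, n_transcripts = 0,
                    n_coregulated = 0, n_known_regulated = 0,
                    n_imprinted = 0, n_decoys = 0,
                    frac_methylated_mirnas = 0.5,
                    frac_retained_in_demethylated = 0,
                    genome_length = 6500000, key = "moments")
  expr <- generate_expression(w)
  reg <- w$manifest$regulated_mirnas
  folds <- vapply(reg, function(id) {
    mean(expr$values[id, 4:6]) / mean(expr$values[id, 1:3])
  }, numeric(1))
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 3), 3 * se + 0.02)
  # replicates identical at zero noise
  w0 <- zero_noise_world()
  e0 <- generate_expression(w0)
  expect_true(all(e0$values[, 1] == e0$values[, 2]))
  # silencing factor 1 plants no differential expression
  w1 <- cached_world(seed = 61, expression_silencing_factor = 1,
                     replicate_cv = 0, key = "nofold")
  e1 <- generate_expression(w1)
  expect_true(all(abs(e1$values[, 4] / e1$values[, 1] - 1) < 1e-12))
})

test_that("qPCR tables carry the planted drug response structure", {
  w <- zero_noise_world()
  ct <- generate_qpcr(w)
  expect_setequal(unique(ct$cell_line), c("lineA", "lineB", "lineC"))
  expect_true(all(table(ct$target, ct$cell_line) == 6))  # 2 cond x 3 reps
  # the planted undetectable host is NA in every well
  na_host <- w$manifest$not_expressed_host
  expect_true(all(is.na(ct$ct_target[ct$target == na_host])))
  # independent hosts of regulated miRNAs show no response
  reg_hosts <- setdiff(na.omit(
    w$manifest$host_genes[w$manifest$regulated_mirnas]), na_host)
  if (length(reg_hosts) > 0) {
    sub <- ct[ct$target == reg_hosts[1] & ct$cell_line == "lineA", ]
    expect_equal(delta_delta_ct(sub)$fold, 1.0)
  }
})

test_that("per-CpG truth: full methylation and conversion read fully methylated", {
  w <- cached_world(seed = 53, per_cpg_methylation = 1,
                    bisulfite_conversion_rate = 1, key = "bis1")
  bis <- generate_bisulfite(w, n_clones = 4)
  loc <- bis[[1]]
  s <- suppressWarnings(score_locus(list(amplicon = loc$amplicon,
                                         clones = loc$clones$baseline)))
  expect_equal(s$overall_percent, 100)
})
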