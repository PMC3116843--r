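ref_seq <- "ACGTACGTCCACGTTACGACCGTA"
# CpGs at positions 2, 6, 12, 17, 21 (1-based C of each CG)

test_that("CpG positions are located correctly", {
  expect_equal(cpg_positions(ref_seq), c(2, 6, 12, 17, 21))
  expect_length(cpg_positions("AAAA"), 0)
})

test_that("full conversion spares only methylated CpG cytosines", {
  n_cpg <- length(cpg_positions(ref_seq))
  all_meth <- in_silico_convert(ref_seq, rep(TRUE, n_cpg), 1)
  # CpG Cs intact, every other C gone
  expect_equal(cpg_positions(all_meth), cpg_positions(ref_seq))
  non_cpg_c <- setdiff(which(strsplit(all_meth, "")[[1]] == "C"),
                       cpg_positions(ref_seq))
  expect_length(non_cpg_c, 0)
  no_meth <- in_silico_convert(ref_seq, rep(FALSE, n_cpg), 1)
  expect_false(grepl("C", no_meth))
})

test_that("incomplete conversion retains the expected non-CpG C fraction", {
  set.seed(31)
  # sequence with many non-CpG cytosines
  seq <- paste(rep("CAT", 400), collapse = "")
  n_c <- 400
  retained <- vapply(1:50, function(i) {
    conv <- in_silico_convert(seq, logical(0), 0.99)
    sum(strsplit(conv, "")[[1]] == "C")
  }, numeric(1))
  total <- 50 * n_c
  # binomial 99.9% interval around retention probability 0.01
  bounds <- qbinom(c(0.0005, 0.9995), total, 0.01)
  expect_gte(sum(retained), bounds[1])
  expect_lte(sum(retained), bounds[2])
})

test_that("clone scoring inverts in-silico conversion at full efficiency", {
  set.seed(17)
  amp <- amplicon("locus1", ref_seq)
  for (i in 1:20) {
    state <- runif(length(amp$cpg_pos)) < 0.5
    clone <- in_silico_convert(ref_seq, state, 1)
    calls <- call_clone(amp, clone)$calls
    expect_equal(calls == "methylated", state)
  }
})

test_that("fully converted and fully protected clones give pure call vectors", {
  amp <- amplicon("locus1", ref_seq)
  n <- length(amp$cpg_pos)
  conv <- in_silico_convert(ref_seq, rep(FALSE, n), 1)
  expect_true(all(call_clone(amp, conv)$calls == "unmethylated"))
  prot <- in_silico_convert(ref_seq, rep(TRUE, n), 1)
  expect_true(all(call_clone(amp, prot)$calls == "methylated"))
  expect_error(call_clone(amp, substr(conv, 1, 10)), "length mismatch")
})

test_that("locus summaries count by hand and render the lollipop grid", {
  amp <- amplicon("locusX", "AACGTTCGAACGTT")  # CpGs at 3, 7, 11
  clones <- list(
    call_clone(amp, "AACGTTTGAACGTT", "c1"),  # M, U, M
    call_clone(amp, "AATGTTCGAATGTT", "c2"),  # U, M, U
    call_clone(amp, "AACGTTCGAACGTT", "c3"))  # M, M, M
  expect_warning(s <- locus_summary(clones, min_clones = 8), "only 3")
  expect_equal(s$per_cpg_fraction, c(2 / 3, 2 / 3, 2 / 3))
  expect_equal(s$overall_percent, 100 * 2 / 3)
  expect_true(s$below_minimum)
  expect_equal(s$lollipop[1],
               paste("\u25CF", "\u25CB", "\u25CF"))
  # ambiguous bases drop out of the denominator
  cl4 <- call_clone(amp, "AANGTTCGAACGTT", "c4")
  expect_equal(cl4$calls[1], "ambiguous")
  s2 <- suppressWarnings(locus_summary(list(clones[[3]], cl4)))
  expect_equal(s2$per_cpg_fraction[1], 1)
})

test_that("eight fully methylated clones give 100%, no warning", {
  amp <- amplicon("locusX", "AACGTTCGAACGTT")
  clones <- lapply(1:8, function(i)
    call_clone(amp, "AACGTTCGAACGTT", paste0("c", i)))
  expect_no_warning(s <- locus_summary(clones))
  expect_equal(s$overall_percent, 100)
})

test_that("demethylation deltas compare per-CpG fractions", {
  amp <- amplicon("locusX", "AACGTTCGAACGTT")
  full <- lapply(1:8, function(i) call_clone(amp, "AACGTTCGAACGTT", i))
  none <- lapply(1:8, function(i) call_clone(amp, "AATGTTTGAATGTT", i))
  s_full <- locus_summary(full); s_none <- locus_summary(none)
  same <- demethylation_compare(s_full, s_full)
  expect_true(all(same$per_cpg_delta == 0))
  d <- demethylation_compare(s_full, s_none)
  expect_equal(d$overall_delta, -1)
  bad <- s_none; bad$per_cpg_fraction <- bad$per_cpg_fraction[-1]
  expect_error(demethylation_compare(s_full, bad), "mismatch")
})

test_that("generated clones recover the planted methylation level", {
  w <- cached_world(seed = 19, per_cpg_methylation = 0.5, key = "bis05")
  bis <- generate_bisulfite(w, n_clones = 8)
  loc <- bis[[1]]
  s <- score_locus(list(amplicon = loc$amplicon,
                        clones = loc$clones$baseline))
  n_calls <- 8 * length(loc$amplicon$cpg_pos)
  # conversion failures can only inflate the count, never deflate it
  p_eff <- 0.5 + (1 - 0.5) * (1 - w$config$bisulfite_conversion_rate)
  bounds <- qbinom(c(0.005, 0.995), n_calls, p_eff) / n_calls
  frac <- s$overall_percent / 100
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("a planted aza demethylation effect is recovered within CI", {
  w <- default_world()
  bis <- generate_bisulfite(w, n_clones = 8)
  loc <- bis[[1]]
  s_base <- score_locus(list(amplicon = loc$amplicon,
                             clones = loc$clones$baseline))
  s_aza <- score_locus(list(amplicon = loc$amplicon,
                            clones = loc$clones$treated))
  d <- demethylation_compare(s_base, s_aza)
  expect_lt(d$overall_delta, 0)
  # planted 0.9 -> 0.3: allow binomial spread at n = 8 x 16 calls
  expect_lt(abs(d$overall_delta - (0.3 - 0.9)), 0.15)
})

test_that("bisulfite FASTA round-trips through the locus|clone convention", {
  w <- default_world()
  bis <- generate_bisulfite(w, n_clones = 3)
  path <- tempfile(fileext = ".fa")
  lines <- character()
  for (lc in names(bis)) {
    lines <- c(lines, paste0(">", lc, "|reference"),
               bis[[lc]]$amplicon$reference)
    for (cond in names(bis[[lc]]$clones)) {
      cl <- bis[[lc]]$clones[[cond]]
      lines <- c(lines, rbind(paste0(">", lc, "|", names(cl)), cl))
    }
  }
  writeLines(lines, path)
  loci <- read_bisulfite_fasta(path)
  expect_setequal(names(loci), names(bis))
  lc1 <- names(bis)[1]
  expect_equal(loci[[lc1]]$amplicon$reference, bis[[lc1]]$amplicon$reference)
  expect_equal(length(loci[[lc1]]$clones), 9)  # 3 conditions x 3 clones
  s <- suppressWarnings(score_locus(loci[[lc1]]))
  expect_true(all(s$per_cpg_fraction >= 0 & s$per_cpg_fraction <= 1))
})
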