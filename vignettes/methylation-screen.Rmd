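---
title: "Screening for DNA-methylation-regulated microRNAs with mirmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for DNA-methylation-regulated microRNAs with mirmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmeth)
```

## The problem

Promoter DNA methylation can silence microRNA transcription, and such
epigenetic silencing contributes to cancer. Expression-based discovery
(compare tumor to normal, or baseline to demethylated cells, and keep the
miRNAs that move) is biased: it misses miRNAs that are equivalently
methylated in both conditions, miRNAs held silent by residual methylation
in "demethylated" cells, and miRNAs whose expression change falls below
conventional fold cutoffs. `mirmeth` implements the complementary,
methylation-first design: start from genome-wide methylation maps, take
every miRNA with methylation near its annotated stem-loop as a candidate,
and only then use expression and drug-response data as supporting
evidence.

The screen is a funnel with five stages, each implemented as an
independently testable module:

1. **Methylome calling.** MBD (methyl-CpG binding domain) pulldown
   sequencing reads are counted in fixed windows; windows whose count
   clears a Poisson background threshold are merged into significant
   methylated regions, per sample.
2. **Proximity screen.** A miRNA is a candidate if a significant region
   lies within 500 bp (gap distance, inclusive) of its stem-loop in the
   methylated reference line. Whether the demethylated derivative retains
   a region within the same distance is recorded as the retention flag.
3. **Exclusion and expression concordance.** Candidates already reported
   as methylation-regulated, or sitting in imprinted-domain clusters, are
   set aside. The rest must have expression concordant with methylation:
   up at least 1.5-fold (Welch's t test, Benjamini–Hochberg FDR < 0.05)
   in the demethylated line when methylation is lost, or still silenced
   when methylation is retained.
4. **Drug re-expression.** Each surviving candidate's primary transcript
   is quantified by qRT-PCR before and after 5-aza-2′-deoxycytidine
   (a demethylating agent) via the 2^−ΔΔCt method; re-expression must be
   significant (Student's t on replicate ΔCt, p < 0.05, fold > 1) in the
   primary cell line and every tested validation line.
5. **Genomic context and independence.** Intergenic candidates are
   independently regulated by construction. Intronic candidates are
   accepted only if their putative host gene does not itself respond to
   the demethylating drug (or is not expressed at all); a host that
   responds makes co-transcription impossible to rule out.

Bisulfite clone scoring (per-CpG methylated/unmethylated calls against an
amplicon reference, lollipop summaries, before/after-treatment deltas)
and the phenotype-assay calculators (wound closure, BrdU incorporation,
transwell migration, growth summaries) support the validation experiments
around the funnel.

## The statistical model of the peak caller

If a sample has $N$ mapped reads on a genome of $G$ bp, uniform
background coverage puts $\lambda = N \cdot w / G$ reads in a window of
$w$ bp. The minimum significant count is

$$k^* = \min\{k : P(\mathrm{Poisson}(\lambda) \ge k) < \alpha / n_w\},$$

with $n_w$ the number of windows — a Bonferroni-adjusted genome-wide
level. The published analyses this design follows defer their exact
threshold rule to earlier work; this package fixes the rule above as its
own definition because it is conservative, matches the "minimum number of
reads" framing, and is exactly testable (the suite checks it against a
brute-force tail summation and verifies monotonicity in $N$). Reads are
assigned to windows by midpoint, with boundary midpoints going to the
higher-coordinate window so counts are conserved. Defaults: $w = 500$ bp
(the same scale as the proximity rule), $\alpha = 0.01$, adjacent-only
merging (`merge_gap = 0`). All are arguments of `call_methylome()`.

Estimating $\lambda$ from total reads slightly overstates the background
in enriched samples (enriched reads inflate $N$), which makes the
threshold conservative; at the scales used here the effect is under one
count.

## Expression testing scale

Fold changes are reported on normalized linear-scale group means, and the
1.5-fold concordance gate applies to that linear fold. The Welch test,
however, is computed on log2 intensities by default
(`differential_expression(..., log_scale = TRUE)`): replicate noise on
intensity data is multiplicative, so log intensity is the approximately
homoscedastic normal scale. On the linear scale a 3-fold shift also
inflates the variance 9-fold, and at $n = 3$ per line the
Welch–Satterthwaite degrees of freedom collapse toward 2, costing real
power. Median scaling (each sample's median moved to the grand median) is
the default normalization; the cited array-processing method is not
restated in the source material, and median scaling is simple, monotone,
and auditable, and is recorded in the output's `normalization` attribute.

Two corner conventions matter with noise-free fixtures: two groups with
zero variance and equal means give $p = 1$; zero variance and different
means give $p = 0$, flagged degenerate.

A related small-sample fact is asserted honestly in the tests: at
$n = 3$ vs 3 the Welch test is *conservative* (empirical size ≈ 0.034 at
nominal 0.05) — that is a property of the Welch–Satterthwaite
approximation itself, not of this implementation, and the suite checks
nominal size (±0.01) at $n = 10$ while asserting only the conservative
bound at $n = 3$. Student's pooled t, used for qPCR ΔCt and phenotype
comparisons, holds exact size at $n = 3$.

## Decisions where the design was open

* **Candidacy requires reference-line methylation only.** Whether the
  original design required methylation in both lines is ambiguous; the
  proximity module records both flags (`methylated_in_reference`,
  `methylated_in_demethylated`) and the funnel treats reference-line
  methylation as sufficient, with retention feeding the concordance rule.
* **"Within 500 bp" is inclusive**, measured as gap distance from the
  stem-loop boundary, strand-ignored (methylation is strandless). A gap
  of exactly 500 qualifies; 501 does not. Nearest-region ties break to
  the lower start coordinate.
* **Both concordance gates are applied** (fold ≥ 1.5 *and* q < 0.05),
  each configurable, since the methods name both the fold rule and the
  FDR-corrected test. Both consistent classes — re-expressed after
  demethylation, and retained-methylation/still-silenced — are forwarded
  to drug validation: the re-expression assay is exactly the right test
  for a candidate the demethylated line never released. Inconsistent
  candidates can be rescued into validation with `rescue_inconsistent`,
  off by default.
* **The qPCR test statistic** is Student's equal-variance t on replicate
  ΔCt values (the approximately normal scale), two-sided, unpaired, with
  the significance flag additionally requiring fold > 1 because
  re-expression is a directional claim.
* **Host response** is operationalized as a comparison of per-line
  significance sets: a host significant nowhere is `no_change`;
  undetectable in every well is `not_expressed`; significant in every
  line where its miRNA responded is `concordant_increase`; anything else
  is `inconsistent_increase`. Only `no_change`/`not_expressed` hosts
  leave the embedded miRNA classified independent. Exonic contexts (none
  occur in the motivating data) route to `indeterminate`.
* **Ambiguous bisulfite bases** (neither C nor T at a CpG) are excluded
  from the per-CpG denominator rather than guessed. Incomplete conversion
  reads as methylation at truly unmethylated CpGs and is reported
  uncorrected, matching direct-reading presentation of clone data.

## The synthetic world

`generate_world()` builds a deterministic two-cell-line world emulating a
methylated colorectal line and a demethylated knockout derivative, with a
manifest of every planted effect for recovery testing. Defaults (all
exposed in `world_config()`):

* 2 chromosomes × 500 kb; 50 miRNA stem-loops (80 bp), 18 transcript
  models (8 kb, three exons); placement is slot-based so features never
  overlap, and an infeasible configuration fails with the constraint
  named.
* Planted categories: 15 regulated (methylation-silenced, independent),
  2 coregulated (host-driven), 4 known + 2 imprinted (excluded by the
  funnel), 3 decoys (methylated but unresponsive — the pattern of a
  candidate that stays silenced after demethylation), the rest
  unmethylated.
* Methylated regions are 1000 bp blocks aligned to the 500 bp analysis
  grid — methylation domains are modeled at the resolution at which MBD
  enrichment is scored — each within 500 bp of its miRNA; per-region
  retention in the demethylated line is Bernoulli(0.25), echoing the
  observation that most, but not all, proximal methylation disappears
  there while some regions persist.
* Reads: Poisson background at 0.02 reads/bp (λ = 10 per 500 bp window)
  with 10-fold enrichment inside regions — the order of enrichment an MBD
  pulldown achieves over methylated CpG islands — as 36 bp single-end
  placements.
* Expression: triplicates per line, multiplicative log-normal noise at
  CV 0.1, 3-fold reversal for regulated miRNAs whose region was lost. All
  miRNAs share a common baseline so the unchanged majority anchors the
  per-sample medians, as global normalization of a real array assumes.
* qPCR: planted 4-fold drug response (Ct noise SD 0.1 cycles) for
  regulated/coregulated/known/imprinted targets in all three simulated
  cell lines; independent hosts are planted flat, coregulated hosts
  respond, and one host is planted undetectable to exercise the
  `not_expressed` path.
* Bisulfite: per-CpG methylation 0.9 at baseline, 0.3 after treatment,
  0.05 in the demethylated line, at conversion rate 0.99.

The original assay protocols state no noise model, so every distribution
above is this package's own stipulation. The generator does **not**
emulate realistic sequence composition, read quality, alignment error,
CpG-island structure, probe-level array artifacts, or amplification
efficiency differences — so passing recovery tests demonstrates the
pipeline's logic and calibration, not robustness to those real-data
complications.

With noise switched off (`replicate_cv = 0`, `qpcr_noise_sd = 0`) and the
manifest's regions used as perfect peak calls, the funnel recovers the
planted independent regulated set *exactly*; at default noise, precision
and recall stay above 0.8 over repeated seeds (both are asserted in the
test suite; problem sizes as above, 20 seeds).

## A worked run

```{r}
world <- generate_world(world_config(seed = 1))
result <- screen_synthetic_world(world)
result$report$counts
```

```{r}
setdiff(world$manifest$independent_regulated,
        result$report$independent_final)
```

Per-candidate evidence accumulates in `result$records`, one row per
stage-1 candidate with its distance to methylation, retention flag,
exclusion reason, concordance class, confirmation status, context, host
response and final class — nothing is silently dropped.

The ten-candidate fixture distributed with the package
(`confirmed_candidates_fixture()`) encodes the confirmed candidates of
the motivating screen with synthetic coordinates that preserve the
containment relations; on it the context classifier returns 7 intronic
and 3 intergenic calls and the independence rule returns 8 independent
candidates, the two exceptions being the C9orf3-hosted pair:

```{r}
fx <- confirmed_candidates_fixture()
table(vapply(seq_len(nrow(fx$mirnas)), function(i)
  classify_context(fx$mirnas[i, ], fx$transcripts)$context, character(1)))
vapply(seq_len(nrow(fx$records)), function(i)
  independence_call(fx$records$context[i], fx$records$host_response[i]),
  character(1)) |> table()
```

## Known limitations

* The proximity rule anchors on annotated stem-loops; methylation at a
  distal primary-transcript promoter (tens of kb upstream) is invisible
  to it. This is an acknowledged limitation of stem-loop-anchored
  screens, not an implementation gap.
* Bisulfite clones are scored in the reference coordinate frame; clones
  with indels need an aligner upstream, which is out of scope.
* Peak calling is replicate-unaware and applies no CpG-density or
  mappability correction.
* The funnel consumes the known/imprinted exclusion lists as inputs; it
  does not curate them.
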