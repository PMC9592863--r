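---
title: "TriadScreen: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TriadScreen: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TriadScreen)
```

TriadScreen screens direction-constrained lncRNA–miRNA–mRNA (ceRNA)
regulatory modules from three-layer expression data collected over a
2-genotype × 2-condition × 3-replicate design. This vignette documents the
statistical model, every tunable threshold, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the procedure was genuinely open.

## The count model and the differential test

Counts for every layer are modelled as negative binomial with mean μ and
variance μ + αμ², α being the dispersion. `nbTest()` tests drought vs
control within one genotype:

1. **Normalization.** Median-of-ratios size factors over the genotype's
   six samples: for features with a nonzero geometric mean across samples,
   the per-sample factor is the median ratio to the geometric-mean
   reference, with the median taken on the log scale (an even number of
   usable features averages the two central ratios geometrically). This is
   the conventional estimator; features containing any zero are excluded
   from the reference, the standard practice the test-suite oracle also
   follows.
2. **Effect estimate.** log₂FC = log₂((m_T + c)/(m_CK + c)) on normalized
   means, with pseudocount c = 0.5 normalized counts so that fold changes
   of low-count features stay finite and shrink mildly toward zero.
3. **Dispersion.** Per feature, by the method of moments from the pooled
   within-condition variance: α̂ = max((s² − m̄)/m̄², 10⁻⁸). The floor
   keeps under-dispersed features (s² < m̄) at an effectively Poisson
   variance instead of a negative α. No shrinkage across features is
   applied; the screens consume only (log₂FC, p, direction), and a
   transparent, auditable estimator is preferred over a moderated one.
4. **Wald test.** z = log₂FC / SE(log₂FC) with the delta-method standard
   error from Var(m̂) = (m + αm²)/n per condition. The two-sided p-value
   is taken from a **t distribution with n₁ + n₂ − 2 degrees of freedom**,
   not a normal. This choice came from a calibration study at the design's
   replicate number: with 3 vs 3 samples, μ = 500 and α = 0.05, the normal
   reference rejects a true null at rate ≈ 0.13 at nominal 0.05 (the
   method-of-moments dispersion is itself noisy at n = 3), while the t₄
   reference sits at ≈ 0.05 with power ≈ 0.99 against a four-fold change.
   The acceptance suite re-measures both rates on every run.

A feature is *called* when p < `de_p` (default 0.05) and |log₂FC| >
`de_lfc` (default 1), both strict inequalities. The p-threshold is applied
to the raw p-value by default: the screening rule is read as a plain
significance criterion, not a multiplicity-corrected one; a
Benjamini–Hochberg gate is available behind `use_adjusted_p`.

## Thresholds

All numeric rules live in one `thresholdConfig()` object:

| parameter | default | meaning |
|---|---|---|
| `de_p`, `de_lfc` | 0.05, 1 | differential call: p < 0.05, \|log₂FC\| > 1 |
| `dt_specific_lfc` | 2 | DT-specific drought classes need \|log₂FC(DT)\| > 2 |
| `lfc_ratio` | 3 | shared-direction classes need log₂FC(DT)/log₂FC(DS) > 3 |
| `trans_r`, `trans_p` | 0.9, 0.01 | trans target: \|r\| > 0.9 and p < 0.01 |
| `cis_window` | 100000 bp | cis target: boundary gap ≤ 100 kb, inclusive |
| `min_lnc_length` | 200 nt | lncRNA candidates strictly longer than 200 nt |
| `min_lnc_exons` | 2 | at least 2 exons (see below) |
| `mirna_len_min/max` | 18, 30 nt | retained mature small-RNA lengths |
| `mir_score_max` | 4 | complementarity penalty ceiling for an edge |

**Exon rule.** The published filter wording ("exon number greater than
two") conflicts with the near-universal ≥ 2-exon convention for assembled
lncRNA candidates; the default here is ≥ 2, with `strict_exon_gt = TRUE`
restoring the literal strict reading.

**Cis window.** "Within 100 kb upstream and downstream" is measured as
the boundary-to-boundary gap (0 for overlapping features), inclusive at
exactly 100,000 bp, on either side and regardless of strand — the most
permissive literal reading. `GenomicRanges::distance()` implements the
same gap, which the brute-force oracle exploits.

**Trans rule.** Correlation is computed across all 12 samples on FPKM, as
the procedure states "in the samples" with no subsetting; no multiplicity
correction is applied to trans p-values (the rule is a plain p < 0.01).
At n = 12 the |r| > 0.9 condition dominates: r = 0.9 already gives
p ≈ 6·10⁻⁵.

**Positional classes.** Precedence is: no gene-body overlap → lincRNA;
any opposite-strand overlap → antisense; containment in a same-strand
intron → intronic; remaining same-strand overlap → sense. Antisense
outranks intron containment because strand disagreement is the stronger
signal; gene overlap means ≥ 1 bp intersection of gene bodies.

**Venn summaries** are computed on direction-pooled feature ids (a gene
up in one genotype and down in the other counts once in "common") — the
id-level reading of the published common/specific counts.

**Module retention.** The mutual-targeting rule ("DELs and DEGs having a
targeting relationship with each other were retained") is applied
per member: a candidate DEL or DEG survives only if it participates in at
least one linked (DEL, DEG) pair. `require_pair_link = FALSE` switches to
the looser per-module reading (all opposite-direction candidates kept once
any pair is linked). One module is emitted per DEM — modules are
DEM-centred stars, not maximal bicliques — and genotypes are screened
independently.

## The synthetic-data generator

`simulateExperiment()` emulates the *post-quantification* state of a
three-layer experiment: NB counts for mRNA/lncRNA/miRNA over the
12-sample design, genomic coordinates on a synthetic genome (7 chromosomes
× 50 Mb by default), a coding-potential verdict table, declared miRNA
target edges, and planted triads recorded in a `PlantedTruth` object.

Defaults are the conditions the recovery guarantees are stated at:
baseline NB mean 500, dispersion α = 0.05, planted |log₂FC| = 2, three
replicates, three triads per genotype (1 lncRNA + 2 mRNAs each, module
types alternating so both directions are exercised), 5% background DE
among remaining features, 60 decoy miRNA edges, and library-size factors
drawn log-uniformly within ±20% of nominal so size-factor estimation is
non-trivial. A single α is shared across features — sufficient for
testing screen logic; per-feature dispersion would only blur the planted
effect sizes.

**Cis vs trans realization of planted pairs.** Planted lncRNA–mRNA pairs
are realized as genomic neighbours (same chromosome, gap uniform in
[0, 100 kb)) with probability `cis_fraction`, default **1.0**. The default
is deliberate and follows from a variance budget. For the trans rule to
fire, the pair must correlate at |r| > 0.9 across 12 samples, i.e. shared
variance at least 9× the independent variance. At α = 0.05 and μ = 500 the
independent per-sample noise is CV ≈ 23%; a condition effect of log₂FC = 2
confined to 3 of 12 samples contributes only ≈ 2.6× the noise variance
(population r ≈ 0.73), and any *within-condition* shared factor large
enough to close the gap inflates the within-group CV past the point where
the 3-replicate Wald test retains power — the two requirements are
mutually exclusive at these settings. Rather than silently weaken either,
default planted pairs are cis; trans realization (`cis_fraction < 1`)
places pairs on different chromosomes (or > 100 kb apart) and co-expresses
them through a shared per-sample lognormal factor
(`trans_coexpr_sd`, default 0.5 log-units), which recovers reliably at
lower dispersions (the suite demonstrates 8/8 planted trans edges at
α = 0.005).

**What the generator does not emulate:** read-level artefacts (mapping
bias, multi-mapping, positional coverage), per-feature dispersion trends,
correlated background co-expression structure, genotype baseline
differences, and sequence-driven miRNA binding sites (edges are declared,
not derived from sequence, unless `scanMirTargets()` is invoked
explicitly). Passing recovery tests therefore demonstrates correctness of
the screening logic and calibration of the tests under the NB model — not
robustness to real-data artefacts upstream of quantification.

## Numerical and degenerate-input choices

* Identical seeds give bit-identical output; all randomness flows from
  the single `seed` field.
* All-zero count matrices, zero column totals, and features with no
  nonzero geometric mean raise errors naming the condition; constant
  features are skipped (with a message) by trans correlation rather than
  propagating NaN.
* `pearsonP()` returns p = 0 at |r| = 1 (the t statistic is infinite) and
  refuses constant vectors and n < 3.
* Coordinates are 1-based inclusive in all user-facing tables and in the
  GTF writer/reader; interval arithmetic uses IRanges conventions
  internally.
* Ct values for `ddct()` must lie in (0, 50), the plausible qPCR range.

## Problem sizes used by the test and acceptance suites

Unit tests run on instances of 1–300 features. The acceptance suite uses
3000 null features for type-I calibration (binomial SE ≈ 0.004), 20,000
trials for the Pearson null rate at n = 12 (SE ≈ 0.0007), 25 random
instances per brute-force oracle comparison (125 total across five
operations), and 20 generator seeds at default settings (120 planted
triads, ≈ 950 planted DE calls) for sensitivity and module
precision/recall. These sizes put the Monte-Carlo error well inside the
asserted bands while keeping a full run in about a minute.

## Known limitations

* The NB test is a two-group Wald test; multi-factor designs, batch
  effects and shrinkage estimators are out of scope.
* The complementarity scorer evaluates ungapped antiparallel alignments
  only — it is a stand-in for full plant target-prediction tools, not a
  re-implementation (no bulges, no gapped search, no free-energy model).
* Published class fractions that depend on a real genome (e.g. the
  lincRNA share among accepted lncRNAs) are not reproducible on a
  synthetic genome and are not targeted; on the sparse default genome
  nearly all simulated lncRNAs are intergenic.
* GO/KEGG annotation, degradome validation and tissue-specificity
  checks are deliberately out of scope.
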