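# TriadScreen

Direction-constrained screening of lncRNA–miRNA–mRNA (ceRNA) regulatory
modules from three-layer expression data.

## The problem

Whole-transcriptome studies of stress response in crops profile three RNA
layers — mRNAs, long noncoding RNAs (lncRNAs) and miRNAs — across a
2-genotype × 2-condition design (e.g., a drought-tolerant and a
drought-sensitive wheat variety, each under control and drought, with
three replicates). The downstream inference chains together several small,
rule-based analyses:

1. **Differential expression per genotype.** For each layer, drought vs
   control counts are compared with a negative-binomial Wald test; a
   feature is called when *p* < 0.05 and |log₂FC| > 1. Per-genotype call
   sets feed Venn summaries (common / genotype-specific / union).
2. **lncRNA identification.** Candidates must be > 200 nt with ≥ 2 exons
   and be voted noncoding by all four coding-potential tools (CPC, CNCI,
   CPAT, Pfam — consumed here as a verdict table); accepted lncRNAs are
   classified positionally as lincRNA, antisense, intronic or sense.
3. **Target assignment.** A lncRNA's *cis* targets are genes within 100 kb
   (boundary gap, either side); *trans* targets are genes whose expression
   correlates with the lncRNA at |r| > 0.9 and *p* < 0.01 across the 12
   samples. miRNA targets come from a precomputed table or from a plant
   complementarity penalty scorer (mismatch 1, G:U wobble 0.5, doubled at
   miRNA positions 2–13; edge at score ≤ 4).
4. **Drought-resistance DEG screen.** Genes fall into three screened
   types: DT-specific calls with |log₂FC(DT)| > 2 (classes A/B), shared
   same-sign calls with log₂FC(DT)/log₂FC(DS) > 3 (C/D), and
   opposite-direction calls (E/F).
5. **Module screen.** For each differentially expressed miRNA (DEM), the
   lncRNAs (DELs) and genes (DEGs) it targets *in the opposite direction*
   are collected, and members are retained only when a (DEL, DEG) pair is
   itself linked by a cis or trans edge. Modules are
   DEL-down/DEM-up/DEG-down (type 1) or the mirror pattern (type 2).

TriadScreen implements this chain as tested, reusable functions, together
with a synthetic-data generator that plants known effects, edges and
triads so every stage — and the pipeline end to end — can be validated
against ground truth without any sequencing data.

## Core model

Counts are modelled as negative binomial with variance μ + αμ².
Per-genotype testing normalizes by median-of-ratios size factors,
estimates a per-feature dispersion by the method of moments from the
pooled within-condition variance (floored at 10⁻⁸), and tests
log₂FC = log₂((m_drought + ½)/(m_CK + ½)) with a Wald statistic referred
to a t distribution on n₁ + n₂ − 2 degrees of freedom. Trans-target
p-values use the exact t transform of the Pearson correlation,
t = r√((n−2)/(1−r²)).

## Worked example

```r
library(TriadScreen)
cfg <- simulationConfig(seed = 42)   # 300 mRNA / 120 lncRNA / 60 miRNA,
                                     # 3 planted triads per genotype
res <- runPipeline(cfg, verbose = TRUE)
#> simulate: 300 mRNA, 120 lncRNA, 60 miRNA features x 12 samples
#> diffexpr: DT 14/5/3 called; DS 16/5/3 called
#> lncannot: 120/120 candidates accepted
#> targeting: 27 cis, 42 trans, 78 miRNA edges
#> screens: 5 modules (precision 1.00, recall 0.83)
res$modules[[1]]
#> TriadModule (type 1, DT): mir_0001
#>   DELs: lnc_0001
#>   DEGs: gene_0001, gene_0002
```

The log lines report, per stage: features simulated; differential calls
per genotype (mRNA/lncRNA/miRNA); lncRNA candidates surviving the
consensus filter; target edges by class; and emitted modules with their
precision/recall against the planted truth (here 5 of 6 planted triads
are recovered exactly — one member of the sixth lands just outside the
call threshold, the expected statistical attrition at three replicates).
`res$summary` holds the same numbers as a machine-readable list, and
`runPipeline(cfg, out_dir = "out")` writes every stage table (counts and
design TSVs, annotation GTF, edge TSV, truth and summary JSON).

Published summary tables can be checked directly with the set-arithmetic
helpers, e.g.

```r
vennFromSizes(15909, 11233, 6680)
#> $common [1] 6680  $ds_specific [1] 9229  $dt_specific [1] 4553  $union [1] 20462
```

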