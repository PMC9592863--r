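make_verdicts <- function(ids, noncoding = TRUE) {
    v <- as.integer(noncoding)
    data.frame(transcript_id = ids, cpc = v, cnci = v, cpat = v, pfam = v,
               stringsAsFactors = FALSE)
}

test_that("the consensus filter applies all four rules jointly", {
    tx <- data.frame(
        transcript_id = c("short", "ok", "coding1", "known", "oneexon"),
        biotype = c("unknown", "unknown", "unknown", "mRNA", "unknown"),
        length = c(150, 300, 300, 300, 300),
        n_exons = c(3, 3, 3, 3, 1), stringsAsFactors = FALSE)
    vd <- make_verdicts(tx$transcript_id)
    vd$cpat[vd$transcript_id == "coding1"] <- 0L  # one tool votes coding
    expect_identical(consensusFilter(tx, vd), "ok")
    # boundary: exactly 200 nt is rejected (rule is strictly longer)
    tx200 <- data.frame(transcript_id = "t", biotype = "unknown",
                        length = 200, n_exons = 2)
    expect_identical(consensusFilter(tx200, make_verdicts("t")), character(0))
    # strict exon reading: 2 exons no longer qualify
    tx2 <- data.frame(transcript_id = "t", biotype = "unknown",
                      length = 300, n_exons = 2)
    expect_identical(consensusFilter(tx2, make_verdicts("t")), "t")
    expect_identical(
        consensusFilter(tx2, make_verdicts("t"),
                        thresholdConfig(strict_exon_gt = TRUE)),
        character(0))
})

test_that("the consensus filter names transcripts lacking verdicts", {
    tx <- data.frame(transcript_id = c("a", "b"), biotype = "unknown",
                     length = 300, n_exons = 3)
    expect_error(consensusFilter(tx, make_verdicts("a")), "b")
})

test_that("the consensus filter equals brute-force row filtering", {
    for (seed in 1:20) {
        set.seed(seed)
        n <- 30
        tx <- data.frame(
            transcript_id = paste0("t", 1:n),
            biotype = sample(c("unknown", "mRNA"), n, replace = TRUE),
            length = sample(100:500, n, replace = TRUE),
            n_exons = sample(1:4, n, replace = TRUE),
            stringsAsFactors = FALSE)
        vd <- data.frame(transcript_id = tx$transcript_id,
                         cpc = rbinom(n, 1, 0.8), cnci = rbinom(n, 1, 0.8),
                         cpat = rbinom(n, 1, 0.8), pfam = rbinom(n, 1, 0.8))
        keep <- character()
        for (i in 1:n) {
            ok <- tx$biotype[i] == "unknown" && tx$length[i] > 200 &&
                tx$n_exons[i] >= 2 &&
                all(vd[i, c("cpc", "cnci", "cpat", "pfam")] == 1)
            if (ok) keep <- c(keep, tx$transcript_id[i])
        }
        expect_setequal(consensusFilter(tx, vd), keep)
    }
})

# one + strand gene on chr1 at [10000, 20000] with exons at the ends and an
# intron [12001, 17999]
ref_genes <- data.frame(transcript_id = "g1", chrom = "chr1", start = 10000,
                        end = 20000, strand = "+", stringsAsFactors = FALSE)
ref_exons <- data.frame(transcript_id = "g1", chrom = "chr1",
                        start = c(10000, 18000), end = c(12000, 20000),
                        strand = "+", stringsAsFactors = FALSE)

test_that("positional classes follow the precedence rules", {
    lnc <- data.frame(
        transcript_id = c("far", "anti", "intr", "sense_exon", "anti_intr"),
        chrom = "chr1",
        start = c(1e6, 11000, 13000, 11500, 13000),
        end = c(1e6 + 500, 11800, 14000, 18500, 14000),
        strand = c("+", "-", "+", "+", "-"), stringsAsFactors = FALSE)
    got <- classifyLnc(lnc, ref_genes, ref_exons)
    expect_identical(setNames(got$class, got$transcript_id),
                     c(far = "lincRNA", anti = "antisense",
                       intr = "intronic", sense_exon = "sense",
                       # opposite strand outranks intron containment
                       anti_intr = "antisense"))
})

test_that("lncRNAs off the annotated chromosomes warn and fall back", {
    lnc <- data.frame(transcript_id = "L1", chrom = "chrUn", start = 100,
                      end = 600, strand = "+")
    expect_warning(got <- classifyLnc(lnc, ref_genes, ref_exons), "L1")
    expect_identical(got$class, "lincRNA")
})

test_that("classification is total and single-valued on random placements", {
    for (seed in 1:15) {
        pl <- random_placement(seed, n_lnc = 10, n_gene = 6)
        genes <- pl$genes
        # two exons per gene leaving a central intron
        exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
            g <- genes[i, ]
            third <- floor((g$end - g$start) / 3)
            data.frame(transcript_id = g$transcript_id, chrom = g$chrom,
                       start = c(g$start, g$end - third),
                       end = c(g$start + third, g$end), strand = g$strand)
        }))
        got <- classifyLnc(pl$lncs, genes, exons)
        expect_identical(nrow(got), nrow(pl$lncs))
        expect_true(all(got$class %in% c("lincRNA", "antisense", "intronic",
                                         "sense")))
        # lincRNA iff no gene-body overlap (brute force)
        for (i in seq_len(nrow(pl$lncs))) {
            l <- pl$lncs[i, ]
            ov <- any(genes$chrom == l$chrom & genes$start <= l$end &
                      genes$end >= l$start)
            expect_identical(got$class[i] == "lincRNA", !ov)
        }
    }
})
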