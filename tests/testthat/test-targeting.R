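test_that("cis windows are gap-based and inclusive at 100 kb", {
    lnc <- data.frame(transcript_id = "L1", chrom = "chr1",
                      start = 1000000, end = 1001000)
    gene_in <- data.frame(transcript_id = "g1", chrom = "chr1",
                          start = 1050000, end = 1051000)
    e <- cisTargets(lnc, gene_in)
    expect_identical(nrow(e), 1L)
    expect_identical(e$distance, 48999)
    # boundary: gap exactly 100000 still qualifies
    gene_edge <- data.frame(transcript_id = "g2", chrom = "chr1",
                            start = 1101001, end = 1102000)
    e2 <- cisTargets(lnc, gene_edge)
    expect_identical(e2$distance, 100000)
    gene_out <- data.frame(transcript_id = "g3", chrom = "chr1",
                           start = 1101002, end = 1102000)
    expect_identical(nrow(cisTargets(lnc, gene_out)), 0L)
    # other chromosome never qualifies; overlap has distance 0
    gene_chr2 <- data.frame(transcript_id = "g4", chrom = "chr2",
                            start = 1000000, end = 1001000)
    expect_identical(nrow(cisTargets(lnc, gene_chr2)), 0L)
    gene_ov <- data.frame(transcript_id = "g5", chrom = "chr1",
                          start = 1000500, end = 1002000)
    expect_identical(cisTargets(lnc, gene_ov)$distance, 0)
})

test_that("cis targets equal a brute-force scan and are symmetric", {
    for (seed in 1:15) {
        pl <- random_placement(seed)
        got <- cisTargets(pl$lncs, pl$genes)
        want <- bf_cis(pl$lncs, pl$genes)
        key <- function(s, t) sort(paste(s, t))
        if (is.null(want)) {
            expect_identical(nrow(got), 0L)
        } else {
            expect_identical(key(got$source, got$target),
                             key(want$source, want$target))
            m <- merge(got, want, by = c("source", "target"))
            expect_equal(m$distance.x, m$distance.y)
        }
        # symmetry: scanning genes against lncRNAs gives the mirrored edges
        rev <- cisTargets(pl$genes, pl$lncs)
        expect_identical(key(got$source, got$target),
                         key(rev$target, rev$source))
    }
})

test_that("pearsonP matches the reference implementation to 1e-10", {
    set.seed(51)
    for (i in 1:25) {
        n <- sample(5:30, 1)
        x <- rnorm(n); y <- rnorm(n) + 0.5 * x
        got <- pearsonP(x, y)
        ref <- cor.test(x, y, method = "pearson")
        expect_equal(got$r, unname(ref$estimate), tolerance = 1e-10)
        expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    }
})

test_that("pearsonP handles perfect and degenerate input", {
    x <- 1:10
    got <- pearsonP(x, 2 * x + 1)
    expect_equal(got$r, 1)
    expect_equal(got$p, 0)
    expect_error(pearsonP(x, rep(3, 10)), "constant")
    expect_error(pearsonP(x, 1:9), "equal length")
    expect_error(pearsonP(1:2, 1:2), "at least 3")
})

test_that("trans targets equal all-pairs brute force with cor.test", {
    for (seed in 1:12) {
        set.seed(seed)
        lm <- matrix(rnorm(4 * 12, 10), 4, 12,
                     dimnames = list(paste0("L", 1:4), paste0("s", 1:12)))
        gm <- matrix(rnorm(5 * 12, 10), 5, 12,
                     dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
        # force a couple of strong pairs
        gm[1, ] <- lm[1, ] + rnorm(12, 0, 0.05)
        gm[2, ] <- -lm[2, ] + rnorm(12, 0, 0.05)
        got <- transTargets(lm, gm)
        want <- bf_trans(lm, gm)
        if (is.null(want)) {
            expect_identical(nrow(got), 0L)
        } else {
            expect_setequal(paste(got$source, got$target),
                            paste(want$source, want$target))
        }
    }
})

test_that("trans edges are invariant to a shared sample permutation", {
    set.seed(52)
    lm <- matrix(rnorm(36, 10), 3, 12,
                 dimnames = list(paste0("L", 1:3), paste0("s", 1:12)))
    gm <- rbind(g1 = lm[2, ] + rnorm(12, 0, 0.05),
                g2 = rnorm(12))
    colnames(gm) <- colnames(lm)
    got <- transTargets(lm, gm)
    perm <- sample(12)
    got_p <- transTargets(lm[, perm], gm[, perm])
    ord <- function(e) e[order(e$source, e$target), c("source", "target")]
    expect_identical(ord(got), ord(got_p))
    expect_identical(nrow(got), 1L)
    expect_identical(got$source[1], "L2")
})

test_that("trans targets validate samples and skip constant features", {
    lm <- matrix(rnorm(12), 1, 12,
                 dimnames = list("L1", paste0("s", 1:12)))
    gm <- matrix(rnorm(12), 1, 12,
                 dimnames = list("g1", paste0("x", 1:12)))
    expect_error(transTargets(lm, gm), "sample mismatch")
    gm2 <- matrix(5, 1, 12, dimnames = list("g1", colnames(lm)))
    expect_message(got <- transTargets(lm, gm2), "g1")
    expect_identical(nrow(got), 0L)
    # a duplicated row is a guaranteed r = 1 edge
    gm3 <- rbind(L1copy = lm[1, ])
    colnames(gm3) <- colnames(lm)
    got3 <- transTargets(lm, gm3)
    expect_identical(nrow(got3), 1L)
    expect_equal(got3$r, 1)
})

test_that("planted co-expressed pairs are recovered as trans edges", {
    # low dispersion so the shared co-expression factor dominates the noise
    cfg <- simulationConfig(n_genes = 80, n_lncRNAs = 30, n_miRNAs = 12,
                            n_planted_triads_per_genotype = 2,
                            cis_fraction = 0, dispersion = 0.005, seed = 5)
    sim <- simulateExperiment(cfg)
    lengths <- setNames(sim$annotation$length, sim$annotation$transcript_id)
    tr <- transTargets(fpkm(sim$layers$lncrna, lengths),
                       fpkm(sim$layers$mrna, lengths))
    pe <- plantedEdges(sim$truth)
    pt <- pe[pe$type == "lnc_trans", ]
    expect_gt(nrow(pt), 0)
    for (i in seq_len(nrow(pt)))
        expect_true(any(tr$source == pt$source[i] &
                        tr$target == pt$target[i]))
})

test_that("the complementarity penalty follows the plant rubric", {
    mir <- "UGACAGAAGAGAGUGAGCACA"  # 21 nt
    site <- rna_revcomp(mir)
    expect_equal(mirTargetScore(mir, site), 0)

    # single G:U wobble at miRNA position 15 (non-core): 0.5
    # miRNA pos 15 pairs site pos 21 - 15 + 1 = 7
    stopifnot(substr(mir, 15, 15) == "G")
    site_w <- site
    substr(site_w, 7, 7) <- "U"   # G:U instead of G:C
    expect_equal(mirTargetScore(mir, site_w), 0.5)

    # single mismatch at miRNA position 5 (core): doubled to 2
    site_m <- site
    pos <- 21 - 5 + 1
    stopifnot(substr(mir, 5, 5) == "A")
    substr(site_m, pos, pos) <- "C"  # A:C cannot pair
    expect_equal(mirTargetScore(mir, site_m), 2)

    # wobble inside the core doubles to 1
    stopifnot(substr(mir, 3, 3) == "A")
    site_cw <- site
    substr(site_cw, 21 - 3 + 1, 21 - 3 + 1) <- "G"  # A:G mismatch
    expect_equal(mirTargetScore(mir, site_cw), 2)
    stopifnot(substr(mir, 4, 4) == "C")
    site_gu <- site
    # put a U:G wobble at core position 2 (miRNA G pairs site U)
    stopifnot(substr(mir, 2, 2) == "G")
    substr(site_gu, 21 - 2 + 1, 21 - 2 + 1) <- "U"
    expect_equal(mirTargetScore(mir, site_gu), 1)

    expect_error(mirTargetScore("UGGT", "ACCA"), "invalid base")
    expect_error(mirTargetScore(mir, "ACGU"), "same length")
})

test_that("scanning finds planted sites and honours the score ceiling", {
    mir <- c(m1 = "UGACAGAAGAGAGUGAGCACA")
    hit_site <- rna_revcomp(mir[[1]])
    targets <- c(t_hit = paste0("AAAAA", hit_site, "GGGGG"),
                 t_miss = paste0(rep("A", 40), collapse = ""))
    got <- scanMirTargets(mir, targets, type = "mir2lnc")
    expect_identical(got$target, "t_hit")
    expect_identical(got$type, "mir2lnc")
    expect_equal(got$score, 0)
})
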