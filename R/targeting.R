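.empty_edges <- function() {
    data.frame(source = character(), target = character(),
               type = character(), r = numeric(), p = numeric(),
               distance = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
}

#' Cis-target assignment by genomic window
#'
#' Emits an edge \code{(lncRNA, gene, lnc_cis)} for every same-chromosome
#' pair whose boundary-to-boundary gap is at most \code{cis_window}
#' (inclusive at exactly the window size; overlapping features have gap 0).
#' Strand is ignored.
#'
#' @param lncs,genes data.frames with columns \code{transcript_id},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive).
#' @param config a \linkS4class{ThresholdConfig} (uses \code{cis_window}).
#' @return Edge data.frame with columns \code{source}, \code{target},
#'   \code{type}, \code{r}, \code{p}, \code{distance}, \code{score};
#'   \code{distance} holds the gap.
#' @examples
#' lnc <- data.frame(transcript_id = "L1", chrom = "chr1",
#'                   start = 1000000, end = 1001000)
#' gen <- data.frame(transcript_id = "g1", chrom = "chr1",
#'                   start = 1050000, end = 1051000)
#' cisTargets(lnc, gen)  # gap 48999 <= 100 kb
#' @export
cisTargets <- function(lncs, genes, config = thresholdConfig()) {
    stopifnot(is(config, "ThresholdConfig"))
    if (!nrow(lncs) || !nrow(genes))
        return(.empty_edges())
    lnc_gr <- .df_to_granges(lncs)
    gene_gr <- .df_to_granges(genes)
    hits <- suppressWarnings(
        GenomicRanges::findOverlaps(lnc_gr, gene_gr,
                                    maxgap = config@cis_window,
                                    ignore.strand = TRUE))
    if (!length(hits))
        return(.empty_edges())
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    d <- GenomicRanges::distance(lnc_gr[qi], gene_gr[si],
                                 ignore.strand = TRUE)
    d[is.na(d)] <- 0   # overlapping ranges
    keep <- d <= config@cis_window
    data.frame(source = lncs$transcript_id[qi][keep],
               target = genes$transcript_id[si][keep],
               type = "lnc_cis", r = NA_real_, p = NA_real_,
               distance = as.numeric(d[keep]), score = NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation with a t-distribution p-value
#'
#' \code{r} is the sample Pearson correlation; the two-sided p-value comes
#' from \code{t = r * sqrt((n - 2) / (1 - r^2))} on \code{n - 2} degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length \code{n >= 3}, both
#'   non-constant.
#' @return Named list with \code{r} and \code{p}.
#' @examples
#' pearsonP(1:10, 2 * (1:10) + 1)  # r = 1, p = 0
#' @export
pearsonP <- function(x, y) {
    n <- length(x)
    if (length(y) != n)
        stop("'x' and 'y' must have equal length")
    if (n < 3L)
        stop("need at least 3 paired observations")
    if (sd(x) == 0 || sd(y) == 0)
        stop("undefined correlation: constant vector")
    r <- cor(x, y)
    p <- .pearson_pvalue(r, n)
    list(r = r, p = p)
}

.pearson_pvalue <- function(r, n) {
    r2 <- pmin(r^2, 1)
    tstat <- ifelse(r2 >= 1, Inf, abs(r) * sqrt((n - 2) / (1 - r2)))
    2 * pt(-tstat, df = n - 2)
}

#' Trans-target assignment by expression correlation
#'
#' Correlates every lncRNA against every gene across the shared samples and
#' keeps pairs with \code{|r| > trans_r} and \code{p < trans_p} (strict).
#' Constant-expression features cannot be correlated and are skipped with a
#' message. No multiplicity correction is applied to the correlation
#' p-values.
#'
#' @param lnc_expr,gene_expr \linkS4class{ExpressionLayer}s (any unit; FPKM
#'   in the standard pipeline) or plain matrices with identical sample
#'   columns in any order.
#' @param config a \linkS4class{ThresholdConfig} (uses \code{trans_r},
#'   \code{trans_p}).
#' @return Edge data.frame (see \code{\link{cisTargets}}) with \code{type}
#'   \code{"lnc_trans"} and \code{r}, \code{p} filled in.
#' @examples
#' s <- paste0("s", 1:12)
#' lnc <- matrix(rnorm(12, 10), 1, 12, dimnames = list("L1", s))
#' gen <- rbind(L1copy = lnc[1, ] , g2 = rnorm(12, 10))
#' colnames(gen) <- s
#' transTargets(lnc, gen)  # the duplicated row gives r = 1
#' @export
transTargets <- function(lnc_expr, gene_expr, config = thresholdConfig()) {
    stopifnot(is(config, "ThresholdConfig"))
    lm <- if (is(lnc_expr, "ExpressionLayer")) exprValues(lnc_expr)
          else as.matrix(lnc_expr)
    gm <- if (is(gene_expr, "ExpressionLayer")) exprValues(gene_expr)
          else as.matrix(gene_expr)
    extra <- setdiff(colnames(lm), colnames(gm))
    miss <- setdiff(colnames(gm), colnames(lm))
    if (length(extra) || length(miss))
        stop("sample mismatch between matrices: ",
             paste(c(extra, miss), collapse = ", "))
    gm <- gm[, colnames(lm), drop = FALSE]
    n <- ncol(lm)
    if (n < 3L)
        stop("need at least 3 shared samples")
    lnc_const <- apply(lm, 1, sd) == 0
    gene_const <- apply(gm, 1, sd) == 0
    if (any(lnc_const) || any(gene_const))
        message("skipping constant feature(s): ",
                paste(c(rownames(lm)[lnc_const], rownames(gm)[gene_const]),
                      collapse = ", "))
    lm <- lm[!lnc_const, , drop = FALSE]
    gm <- gm[!gene_const, , drop = FALSE]
    if (!nrow(lm) || !nrow(gm))
        return(.empty_edges())
    rmat <- cor(t(lm), t(gm))
    pmat <- .pearson_pvalue(rmat, n)
    hit <- which(abs(rmat) > config@trans_r & pmat < config@trans_p,
                 arr.ind = TRUE)
    if (!nrow(hit))
        return(.empty_edges())
    data.frame(source = rownames(lm)[hit[, 1]],
               target = rownames(gm)[hit[, 2]],
               type = "lnc_trans", r = rmat[hit], p = pmat[hit],
               distance = NA_real_, score = NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Plant miRNA target complementarity penalty
#'
#' Scores an antiparallel alignment of a mature miRNA against a candidate
#' target site of the same length with the standard plant rubric: each
#' mismatch costs 1, each G:U wobble 0.5, and penalties are doubled at
#' miRNA positions 2-13 (5' end = position 1). A perfect reverse complement
#' scores 0; edges are conventionally emitted at score <= 4.
#'
#' @param mirna mature miRNA sequence, 5'->3', over \code{A,C,G,U},
#'   18-30 nt.
#' @param site candidate target subsequence, 5'->3', same alphabet and same
#'   length as \code{mirna}.
#' @return Numeric penalty score (>= 0).
#' @examples
#' mirTargetScore("UGGAAGCUA", "UAGCUUCCA")  # perfect match: 0
#' @export
mirTargetScore <- function(mirna, site) {
    m <- .check_rna(mirna, "mirna")
    s <- .check_rna(site, "site")
    if (length(s) != length(m))
        stop("'site' must have the same length as 'mirna' (",
             length(m), " nt)")
    s_rev <- rev(s)   # site base opposite miRNA position i
    pair <- paste0(m, s_rev)
    penalty <- ifelse(pair %in% c("AU", "UA", "GC", "CG"), 0,
                      ifelse(pair %in% c("GU", "UG"), 0.5, 1))
    core <- seq_along(m) >= 2 & seq_along(m) <= 13
    sum(penalty * ifelse(core, 2, 1))
}

.check_rna <- function(seq, what) {
    if (length(seq) != 1L || !is.character(seq))
        stop("'", what, "' must be a single character string")
    chars <- strsplit(toupper(seq), "")[[1]]
    bad <- setdiff(unique(chars), c("A", "C", "G", "U"))
    if (length(bad))
        stop("invalid base(s) in '", what, "': ",
             paste(bad, collapse = ", "), " (alphabet is A, C, G, U)")
    chars
}

#' Scan target sequences for miRNA complementarity sites
#'
#' Slides each miRNA along each target sequence, scores every window with
#' \code{\link{mirTargetScore}}, and emits an edge for each (miRNA, target)
#' pair whose best window scores at most \code{mir_score_max}.
#'
#' @param mirnas named character vector of mature miRNA sequences (5'->3').
#' @param targets named character vector of target RNA sequences (5'->3').
#' @param config a \linkS4class{ThresholdConfig} (uses \code{mir_score_max}).
#' @param type edge type to emit (\code{"mir2mrna"} or \code{"mir2lnc"}).
#' @return Edge data.frame with the best \code{score} per emitted pair.
#' @examples
#' scanMirTargets(c(m1 = "UGGAAGCUA"),
#'                c(t1 = "AAAUAGCUUCCAAAA"), type = "mir2mrna")
#' @export
scanMirTargets <- function(mirnas, targets, config = thresholdConfig(),
                           type = c("mir2mrna", "mir2lnc")) {
    stopifnot(is(config, "ThresholdConfig"))
    type <- match.arg(type)
    rows <- list()
    for (mi in names(mirnas)) {
        mseq <- mirnas[[mi]]
        L <- nchar(mseq)
        for (ti in names(targets)) {
            tseq <- targets[[ti]]
            if (nchar(tseq) < L) next
            best <- Inf
            for (off in seq_len(nchar(tseq) - L + 1L)) {
                sc <- mirTargetScore(mseq, substr(tseq, off, off + L - 1L))
                if (sc < best) best <- sc
            }
            if (best <= config@mir_score_max)
                rows[[length(rows) + 1L]] <- data.frame(
                    source = mi, target = ti, type = type, r = NA_real_,
                    p = NA_real_, distance = NA_real_, score = best,
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) .empty_edges() else
        `rownames<-`(do.call(rbind, rows), NULL)
}
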