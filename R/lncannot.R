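#' Consensus lncRNA candidate filter
#'
#' A transcript is accepted as a lncRNA when it has unknown/novel biotype,
#' is longer than \code{min_lnc_length} nt (strict), has at least
#' \code{min_lnc_exons} exons (strictly more when \code{strict_exon_gt}),
#' and all four coding-potential tools (CPC, CNCI, CPAT, Pfam stand-ins)
#' vote noncoding — the intersection of the four tool calls.
#'
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{biotype} (\code{"unknown"} marks candidates), \code{length} (nt)
#'   and \code{n_exons}.
#' @param verdicts data.frame with columns \code{transcript_id}, \code{cpc},
#'   \code{cnci}, \code{cpat}, \code{pfam}; 1 = noncoding, 0 = coding.
#'   Every transcript in \code{transcripts} must have a verdict row.
#' @param config a \linkS4class{ThresholdConfig}.
#' @return Character vector of accepted transcript ids.
#' @examples
#' tx <- data.frame(transcript_id = c("t1", "t2"), biotype = "unknown",
#'                  length = c(300, 150), n_exons = c(3, 3))
#' vd <- data.frame(transcript_id = c("t1", "t2"), cpc = 1, cnci = 1,
#'                  cpat = 1, pfam = 1)
#' consensusFilter(tx, vd)  # "t1" only: t2 is too short
#' @export
consensusFilter <- function(transcripts, verdicts,
                            config = thresholdConfig()) {
    stopifnot(is(config, "ThresholdConfig"))
    need <- c("transcript_id", "biotype", "length", "n_exons")
    miss <- setdiff(need, colnames(transcripts))
    if (length(miss))
        stop("'transcripts' is missing column(s): ",
             paste(miss, collapse = ", "))
    tools <- c("cpc", "cnci", "cpat", "pfam")
    if (!all(c("transcript_id", tools) %in% colnames(verdicts)))
        stop("'verdicts' needs columns transcript_id, cpc, cnci, cpat, pfam")
    idx <- match(transcripts$transcript_id, verdicts$transcript_id)
    if (anyNA(idx))
        stop("missing verdict for transcript(s): ",
             paste(transcripts$transcript_id[is.na(idx)], collapse = ", "))
    noncoding <- rowSums(verdicts[idx, tools, drop = FALSE] == 1L) == 4L
    exon_ok <- if (config@strict_exon_gt)
        transcripts$n_exons > config@min_lnc_exons
    else transcripts$n_exons >= config@min_lnc_exons
    keep <- transcripts$biotype == "unknown" &
        transcripts$length > config@min_lnc_length & exon_ok & noncoding
    transcripts$transcript_id[keep]
}

#' Positional classification of lncRNAs against gene models
#'
#' Classifies each lncRNA by its genomic relation to annotated genes, in
#' precedence order: no overlap with any gene body gives \code{lincRNA};
#' overlap with a gene on the opposite strand gives \code{antisense}; full
#' containment within an intron of a same-strand gene gives \code{intronic};
#' any remaining same-strand overlap (necessarily touching an exon) gives
#' \code{sense}. Opposite-strand evidence outranks intron containment.
#' lncRNAs on chromosomes absent from the gene models are classified
#' \code{lincRNA} with a warning.
#'
#' @param lncs data.frame of lncRNA transcripts with columns
#'   \code{transcript_id}, \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive), \code{strand}.
#' @param genes data.frame of gene bodies with the same coordinate columns.
#' @param exons data.frame of gene exons with columns \code{transcript_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}; introns are the
#'   within-gene complement of these.
#' @return data.frame with columns \code{transcript_id} and \code{class}
#'   (one of \code{lincRNA}, \code{antisense}, \code{intronic},
#'   \code{sense}), one row per lncRNA.
#' @examples
#' genes <- data.frame(transcript_id = "g1", chrom = "chr1",
#'                     start = 1000, end = 5000, strand = "+")
#' exons <- data.frame(transcript_id = "g1", chrom = "chr1",
#'                     start = c(1000, 4000), end = c(2000, 5000),
#'                     strand = "+")
#' lnc <- data.frame(transcript_id = "L1", chrom = "chr1",
#'                   start = 2500, end = 3000, strand = "+")
#' classifyLnc(lnc, genes, exons)  # intronic
#' @export
classifyLnc <- function(lncs, genes, exons) {
    lnc_gr <- .df_to_granges(lncs)
    gene_gr <- .df_to_granges(genes)
    exon_gr <- .df_to_granges(exons)

    off_chrom <- !(lncs$chrom %in% unique(genes$chrom))
    if (any(off_chrom))
        warning("lncRNA(s) on chromosome(s) absent from the gene models, ",
                "classified lincRNA: ",
                paste(lncs$transcript_id[off_chrom], collapse = ", "))

    ## introns: per-gene complement of its exons within the gene body
    exon_grl <- GenomicRanges::GRangesList(
        S4Vectors::split(GenomicRanges::GRanges(
            seqnames = exons$chrom,
            ranges = IRanges::IRanges(exons$start, exons$end)),
            factor(exons$transcript_id, levels = genes$transcript_id)))
    gene_unstranded <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gene_gr), GenomicRanges::ranges(gene_gr))
    intron_grl <- GenomicRanges::psetdiff(gene_unstranded, exon_grl)
    intron_gr <- unlist(intron_grl, use.names = FALSE)
    intron_strand <- rep(as.character(GenomicRanges::strand(gene_gr)),
                         S4Vectors::elementNROWS(intron_grl))

    lnc_strand <- as.character(GenomicRanges::strand(lnc_gr))
    hits <- suppressWarnings(
        GenomicRanges::findOverlaps(lnc_gr, gene_gr, ignore.strand = TRUE))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    gene_strand <- as.character(GenomicRanges::strand(gene_gr))
    overlaps_any <- seq_along(lnc_gr) %in% qi
    anti <- seq_along(lnc_gr) %in% qi[gene_strand[si] != lnc_strand[qi]]
    w <- suppressWarnings(
        GenomicRanges::findOverlaps(lnc_gr, intron_gr, type = "within",
                                    ignore.strand = TRUE))
    wq <- S4Vectors::queryHits(w)
    ws <- S4Vectors::subjectHits(w)
    in_intron <- seq_along(lnc_gr) %in% wq[intron_strand[ws] ==
                                           lnc_strand[wq]]
    cls <- rep("lincRNA", length(lnc_gr))
    cls[overlaps_any] <- "sense"
    cls[overlaps_any & in_intron] <- "intronic"
    cls[anti] <- "antisense"
    data.frame(transcript_id = lncs$transcript_id, class = cls,
               row.names = NULL, stringsAsFactors = FALSE)
}

.df_to_granges <- function(df) {
    GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start, end = df$end),
        strand = if ("strand" %in% colnames(df)) df$strand else "*")
}
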