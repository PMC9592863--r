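#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over features
#' with a nonzero geometric mean, of the ratio of each sample's count to the
#' across-sample geometric-mean reference. The median is taken on the log
#' scale (so an even number of usable features averages the two central
#' ratios geometrically), matching the conventional median-of-ratios
#' estimator.
#'
#' @param object an \linkS4class{ExpressionLayer} with unit \code{"counts"},
#'   or a plain count matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' BiocGenerics::sizeFactors(m)  # ratio 1 : 2
#' @importFrom BiocGenerics sizeFactors
#' @export
#' @rdname sizeFactors
setMethod("sizeFactors", "ExpressionLayer", function(object) {
    if (exprUnit(object) != "counts")
        stop("size factors require unit 'counts', got '",
             exprUnit(object), "'")
    .median_of_ratios(exprValues(object))
})

#' @rdname sizeFactors
#' @export
setMethod("sizeFactors", "matrix", function(object) .median_of_ratios(object))

.median_of_ratios <- function(counts) {
    counts <- as.matrix(counts)
    if (all(counts == 0))
        stop("degenerate input: all counts are zero")
    log_gm <- rowMeans(log(counts))          # -Inf where any zero
    use <- is.finite(log_gm)
    if (!any(use))
        stop("degenerate input: no feature has nonzero counts in every sample")
    sf <- apply(counts[use, , drop = FALSE], 2,
                function(col) exp(median(log(col) - log_gm[use])))
    if (any(sf <= 0) || any(!is.finite(sf)))
        stop("degenerate input: non-positive size factor")
    sf
}

#' Convert counts to FPKM
#'
#' \code{FPKM = count * 1e9 / (column total * feature length)}.
#'
#' @param object an \linkS4class{ExpressionLayer} with unit \code{"counts"}.
#' @param lengths named numeric vector of feature lengths in bp covering
#'   every feature of \code{object}.
#' @return An \linkS4class{ExpressionLayer} with unit \code{"FPKM"}.
#' @examples
#' d <- data.frame(sample = c("DTCK1", "DTCK2", "DTT1", "DTT2"),
#'                 genotype = "DT", condition = rep(c("CK", "drought"), each = 2),
#'                 replicate = c(1, 2, 1, 2))
#' m <- matrix(rpois(8, 50), 2, 4, dimnames = list(c("g1", "g2"), d$sample))
#' x <- ExpressionLayer(m, d, "counts", "mRNA")
#' fpkm(x, c(g1 = 1000, g2 = 2500))
#' @export
fpkm <- function(object, lengths) {
    stopifnot(is(object, "ExpressionLayer"))
    if (exprUnit(object) != "counts")
        stop("fpkm requires unit 'counts', got '", exprUnit(object), "'")
    k <- exprValues(object)
    miss <- setdiff(rownames(k), names(lengths))
    if (length(miss))
        stop("missing length for feature(s): ", paste(miss, collapse = ", "))
    len <- lengths[rownames(k)]
    if (any(len <= 0) || anyNA(len))
        stop("feature lengths must be positive")
    tot <- colSums(k)
    if (any(tot == 0))
        stop("degenerate input: zero column total in sample(s) ",
             paste(colnames(k)[tot == 0], collapse = ", "))
    v <- sweep(k, 2, tot, `/`) / len * 1e9
    out <- object
    SummarizedExperiment::assay(out, "values", withDimnames = FALSE) <- v
    out@unit <- "FPKM"
    validObject(out)
    out
}

#' Convert small-RNA counts to TPM
#'
#' Read-count TPM for fixed-length small RNAs:
#' \code{TPM = count * 1e6 / column total}, with no length term. Every
#' output column sums to 1e6.
#'
#' @param object an \linkS4class{ExpressionLayer} with unit \code{"counts"}.
#' @return An \linkS4class{ExpressionLayer} with unit \code{"TPM"}.
#' @examples
#' d <- data.frame(sample = c("DTCK1", "DTCK2", "DTT1", "DTT2"),
#'                 genotype = "DT", condition = rep(c("CK", "drought"), each = 2),
#'                 replicate = c(1, 2, 1, 2))
#' m <- matrix(rpois(8, 50), 2, 4, dimnames = list(c("m1", "m2"), d$sample))
#' tpmSmallRna(ExpressionLayer(m, d, "counts", "miRNA"))
#' @export
tpmSmallRna <- function(object) {
    stopifnot(is(object, "ExpressionLayer"))
    if (exprUnit(object) != "counts")
        stop("tpmSmallRna requires unit 'counts', got '", exprUnit(object), "'")
    k <- exprValues(object)
    tot <- colSums(k)
    if (any(tot == 0))
        stop("degenerate input: zero column total in sample(s) ",
             paste(colnames(k)[tot == 0], collapse = ", "))
    v <- sweep(k, 2, tot, `/`) * 1e6
    out <- object
    SummarizedExperiment::assay(out, "values", withDimnames = FALSE) <- v
    out@unit <- "TPM"
    validObject(out)
    out
}
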