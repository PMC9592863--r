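#' Construct an ExpressionLayer
#'
#' @param values numeric matrix, features x samples. Row names are feature
#'   ids, column names sample ids.
#' @param design data.frame with columns \code{sample}, \code{genotype},
#'   \code{condition}, \code{replicate}; rows must match the matrix columns
#'   (matched by \code{sample}).
#' @param unit one of \code{"counts"}, \code{"FPKM"}, \code{"TPM"}.
#' @param layer one of \code{"mRNA"}, \code{"lncRNA"}, \code{"miRNA"}.
#'
#' @return An \linkS4class{ExpressionLayer}.
#' @examples
#' d <- data.frame(sample = c("DTCK1", "DTCK2", "DTT1", "DTT2"),
#'                 genotype = "DT", condition = rep(c("CK", "drought"), each = 2),
#'                 replicate = c(1, 2, 1, 2))
#' m <- matrix(rpois(8, 50), 2, 4,
#'             dimnames = list(c("g1", "g2"), d$sample))
#' ExpressionLayer(m, d, unit = "counts", layer = "mRNA")
#' @export
ExpressionLayer <- function(values, design, unit = c("counts", "FPKM", "TPM"),
                            layer = c("mRNA", "lncRNA", "miRNA")) {
    unit <- match.arg(unit)
    layer <- match.arg(layer)
    values <- as.matrix(values)
    if (!"sample" %in% colnames(design))
        stop("'design' must have a 'sample' column")
    if (is.null(colnames(values)))
        stop("'values' must have sample column names")
    idx <- match(colnames(values), design$sample)
    if (anyNA(idx))
        stop("design is missing sample(s): ",
             paste(colnames(values)[is.na(idx)], collapse = ", "))
    design <- design[idx, , drop = FALSE]
    cd <- S4Vectors::DataFrame(design[setdiff(colnames(design), "sample")],
                               row.names = design$sample)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = values), colData = cd)
    new("ExpressionLayer", se, unit = unit, layer = layer)
}

#' @describeIn ExpressionLayer the unit tag of the stored values.
#' @param object,x an ExpressionLayer.
#' @export
setGeneric("exprUnit", function(object) standardGeneric("exprUnit"))

#' @rdname ExpressionLayer
#' @export
setMethod("exprUnit", "ExpressionLayer", function(object) object@unit)

#' @describeIn ExpressionLayer the RNA layer tag.
#' @export
setGeneric("rnaLayer", function(object) standardGeneric("rnaLayer"))

#' @rdname ExpressionLayer
#' @export
setMethod("rnaLayer", "ExpressionLayer", function(object) object@layer)

#' @describeIn ExpressionLayer the expression matrix.
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ExpressionLayer
#' @export
setMethod("exprValues", "ExpressionLayer",
          function(object) SummarizedExperiment::assay(object, "values"))

#' @describeIn ExpressionLayer the sample design as a plain data.frame with a
#'   \code{sample} column.
#' @export
setGeneric("sampleDesign", function(object) standardGeneric("sampleDesign"))

#' @rdname ExpressionLayer
#' @export
setMethod("sampleDesign", "ExpressionLayer", function(object) {
    cd <- SummarizedExperiment::colData(object)
    data.frame(sample = rownames(cd), as.data.frame(cd),
               row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "ExpressionLayer", function(object) {
    cat(sprintf("ExpressionLayer: %d %s features x %d samples [%s]\n",
                nrow(object), object@layer, ncol(object), object@unit))
    cd <- SummarizedExperiment::colData(object)
    tab <- table(cd$genotype, cd$condition)
    cat("design (samples per genotype x condition):\n")
    print(tab)
    invisible(NULL)
})
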