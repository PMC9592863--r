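#' Read and write pipeline tables
#'
#' Plain-text interchange for the pipeline's inputs and outputs: expression
#' matrices and the sample design as TSV, annotation as GTF (1-based
#' inclusive coordinates per the GTF convention), target edges as TSV, and
#' planted truth as JSON.
#'
#' @name triadscreen-io
NULL

#' @describeIn triadscreen-io write an \linkS4class{ExpressionLayer}'s
#'   matrix as TSV (feature id in the first column, samples as columns).
#' @param object an ExpressionLayer.
#' @param path file path.
#' @export
writeCountsTsv <- function(object, path) {
    m <- exprValues(object)
    df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @describeIn triadscreen-io read a counts TSV plus design TSV back into an
#'   \linkS4class{ExpressionLayer}.
#' @param counts_path,design_path TSV paths.
#' @param unit,layer tags for the new layer.
#' @export
readCountsTsv <- function(counts_path, design_path,
                          unit = "counts", layer = "mRNA") {
    df <- read.delim(counts_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    design <- read.delim(design_path, stringsAsFactors = FALSE)
    ExpressionLayer(m, design, unit = unit, layer = layer)
}

#' @describeIn triadscreen-io write an edge table as TSV.
#' @param edges edge data.frame.
#' @export
writeEdgesTsv <- function(edges, path) {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}

#' @describeIn triadscreen-io read an edge TSV.
#' @export
readEdgesTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    for (col in c("r", "p", "distance", "score"))
        if (col %in% colnames(df)) df[[col]] <- as.numeric(df[[col]])
    df
}

#' @describeIn triadscreen-io write annotation + exons as GTF via
#'   \pkg{rtracklayer} (transcript and exon rows; layer and biotype carried
#'   as attributes).
#' @param annotation,exons tables as produced by
#'   \code{\link{simulateExperiment}}.
#' @export
writeAnnotationGtf <- function(annotation, exons, path) {
    tx <- GenomicRanges::GRanges(
        seqnames = annotation$chrom,
        ranges = IRanges::IRanges(annotation$start, annotation$end),
        strand = annotation$strand,
        type = "transcript",
        source = "TriadScreen",
        transcript_id = annotation$transcript_id,
        gene_id = annotation$gene_id,
        layer = annotation$layer,
        biotype = annotation$biotype)
    idx <- match(exons$transcript_id, annotation$transcript_id)
    ex <- GenomicRanges::GRanges(
        seqnames = exons$chrom,
        ranges = IRanges::IRanges(exons$start, exons$end),
        strand = exons$strand,
        type = "exon",
        source = "TriadScreen",
        transcript_id = exons$transcript_id,
        gene_id = annotation$gene_id[idx],
        layer = annotation$layer[idx],
        biotype = annotation$biotype[idx])
    rtracklayer::export(c(tx, ex), path, format = "gtf")
    invisible(path)
}

#' @describeIn triadscreen-io read a GTF written by
#'   \code{writeAnnotationGtf} back into annotation and exon tables.
#' @export
readAnnotationGtf <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    tx <- df[df$type == "transcript", , drop = FALSE]
    ex <- df[df$type == "exon", , drop = FALSE]
    ex_len <- tapply(ex$end - ex$start + 1L, ex$transcript_id, sum)
    ex_n <- tapply(ex$transcript_id, ex$transcript_id, length)
    annotation <- data.frame(
        transcript_id = tx$transcript_id, gene_id = tx$gene_id,
        layer = tx$layer, biotype = tx$biotype,
        chrom = as.character(tx$seqnames), start = tx$start, end = tx$end,
        strand = as.character(tx$strand),
        n_exons = as.integer(ex_n[tx$transcript_id]),
        length = as.integer(ex_len[tx$transcript_id]),
        stringsAsFactors = FALSE)
    ord <- order(ex$transcript_id, ex$start)
    ex <- ex[ord, , drop = FALSE]
    exon_number <- unlist(lapply(split(seq_len(nrow(ex)), ex$transcript_id),
                                 seq_along), use.names = FALSE)
    exons <- data.frame(
        transcript_id = ex$transcript_id,
        chrom = as.character(ex$seqnames), start = ex$start, end = ex$end,
        strand = as.character(ex$strand), exon_number = exon_number,
        stringsAsFactors = FALSE)
    rownames(annotation) <- rownames(exons) <- NULL
    list(annotation = annotation, exons = exons)
}

#' @describeIn triadscreen-io write a \linkS4class{PlantedTruth} as JSON.
#' @param truth a PlantedTruth.
#' @export
writeTruthJson <- function(truth, path) {
    jsonlite::write_json(list(
        de_features = deFeatures(truth),
        planted_edges = plantedEdges(truth),
        planted_triads = plantedTriads(truth)), path, auto_unbox = FALSE,
        digits = NA)
    invisible(path)
}

#' @describeIn triadscreen-io write every output of a
#'   \code{\link{runPipeline}} result bundle into a directory.
#' @param res a runPipeline result bundle.
#' @param dir output directory (created if missing).
#' @export
writePipelineResults <- function(res, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(dir, ...)
    sim <- res$sim
    writeCountsTsv(sim$layers$mrna, fp("counts_mrna.tsv"))
    writeCountsTsv(sim$layers$lncrna, fp("counts_lncrna.tsv"))
    writeCountsTsv(sim$layers$mirna, fp("counts_mirna.tsv"))
    write.table(sim$design, fp("design.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeAnnotationGtf(sim$annotation, sim$exons, fp("annotation.gtf"))
    write.table(sim$verdicts, fp("coding_verdicts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeEdgesTsv(res$edges, fp("edges.tsv"))
    writeTruthJson(sim$truth, fp("truth.json"))
    for (g in names(res$de))
        for (l in names(res$de[[g]]))
            write.table(res$de[[g]][[l]],
                        fp(sprintf("de_%s_%s.tsv", l, g)), sep = "\t",
                        quote = FALSE, row.names = FALSE)
    write.table(res$drought_classes, fp("drought_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$summary, fp("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
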