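#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom stats cor median p.adjust pt rnbinom rnorm runif
#'   sd var setNames
#' @importFrom utils read.delim write.table
NULL

.LAYERS <- c("mRNA", "lncRNA", "miRNA")
.UNITS <- c("counts", "FPKM", "TPM")
.GENOTYPES <- c("DT", "DS")
.CONDITIONS <- c("CK", "drought")

#' ExpressionLayer: one RNA layer's abundance matrix with its sample design
#'
#' A thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' carrying a single assay for one RNA layer (mRNA, lncRNA or miRNA), a unit
#' tag (\code{"counts"}, \code{"FPKM"} or \code{"TPM"}), and the 2-genotype
#' by 2-condition sample design in \code{colData} (columns \code{genotype},
#' \code{condition}, \code{replicate}).
#'
#' @slot unit character(1), one of \code{"counts"}, \code{"FPKM"},
#'   \code{"TPM"}.
#' @slot layer character(1), one of \code{"mRNA"}, \code{"lncRNA"},
#'   \code{"miRNA"}.
#'
#' @exportClass ExpressionLayer
setClass("ExpressionLayer",
    contains = "SummarizedExperiment",
    representation(unit = "character", layer = "character"))

setValidity("ExpressionLayer", function(object) {
    msg <- character()
    if (length(object@unit) != 1L || !object@unit %in% .UNITS)
        msg <- c(msg, sprintf("'unit' must be one of %s",
                              paste(.UNITS, collapse = ", ")))
    if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
        msg <- c(msg, sprintf("'layer' must be one of %s",
                              paste(.LAYERS, collapse = ", ")))
    a <- SummarizedExperiment::assay(object)
    if (any(is.na(a)))
        msg <- c(msg, "values must not contain NA")
    else {
        if (any(a < 0))
            msg <- c(msg, "values must be non-negative")
        if (identical(object@unit, "counts") &&
            any(abs(a - round(a)) > 1e-8))
            msg <- c(msg, "unit is 'counts' but values are not integers")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("genotype", "condition", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, sprintf("design is missing column(s): %s",
                              paste(miss, collapse = ", ")))
    else {
        key <- paste(cd$genotype, cd$condition, cd$replicate)
        if (anyDuplicated(key))
            msg <- c(msg, "(genotype, condition, replicate) must be unique")
    }
    if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
        msg <- c(msg, "sample ids must be present and unique")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic three-layer experiment
#'
#' Holds every knob of the synthetic-data generator. Construct with
#' \code{\link{simulationConfig}}, which supplies defaults and validates.
#'
#' @slot n_genes,n_lncRNAs,n_miRNAs integer feature counts per layer.
#' @slot n_replicates integer replicates per genotype x condition cell.
#' @slot genotypes character(2) genotype labels.
#' @slot baseline_mean numeric NB mean scale shared by all features.
#' @slot dispersion numeric NB dispersion alpha (variance = mu + alpha mu^2).
#' @slot n_planted_triads_per_genotype integer planted modules per genotype.
#' @slot triad_n_lncs,triad_n_mrnas integer lncRNA / mRNA members per triad.
#' @slot planted_log2fc numeric planted effect magnitude (log2 scale).
#' @slot frac_background_de numeric proportion of non-triad features given a
#'   background condition effect.
#' @slot cis_fraction numeric proportion of planted lncRNA-mRNA pairs realized
#'   as genomic neighbours (boundary gap <= 100 kb).
#' @slot trans_coexpr_sd numeric log-sd of the shared per-sample factor given
#'   to trans-realized pairs.
#' @slot n_background_edges integer decoy miRNA target edges.
#' @slot verdict_flip_rate numeric probability a coding-potential verdict is
#'   flipped (exercises the consensus filter).
#' @slot depth_jitter numeric half-width of the log-uniform library-size
#'   factor (0.2 means factors in [0.8, 1.2] of nominal).
#' @slot genome_n_chromosomes integer chromosome count.
#' @slot chromosome_length numeric chromosome length in bp.
#' @slot seed integer RNG seed.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
    n_genes = "integer", n_lncRNAs = "integer", n_miRNAs = "integer",
    n_replicates = "integer", genotypes = "character",
    baseline_mean = "numeric", dispersion = "numeric",
    n_planted_triads_per_genotype = "integer",
    triad_n_lncs = "integer", triad_n_mrnas = "integer",
    planted_log2fc = "numeric", frac_background_de = "numeric",
    cis_fraction = "numeric", trans_coexpr_sd = "numeric",
    n_background_edges = "integer", verdict_flip_rate = "numeric",
    depth_jitter = "numeric", genome_n_chromosomes = "integer",
    chromosome_length = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    chk_count <- function(field, min = 1L) {
        v <- slot(object, field)
        if (length(v) != 1L || is.na(v) || v < min)
            sprintf("'%s' must be a single integer >= %d", field, min)
        else character()
    }
    for (f in c("n_genes", "n_lncRNAs", "n_miRNAs", "n_replicates",
                "genome_n_chromosomes"))
        msg <- c(msg, chk_count(f))
    for (f in c("n_planted_triads_per_genotype", "triad_n_lncs",
                "triad_n_mrnas", "n_background_edges"))
        msg <- c(msg, chk_count(f, 0L))
    chk_pos <- function(field) {
        v <- slot(object, field)
        if (length(v) != 1L || is.na(v) || v <= 0)
            sprintf("'%s' must be a single positive number", field)
        else character()
    }
    for (f in c("baseline_mean", "dispersion", "planted_log2fc",
                "chromosome_length"))
        msg <- c(msg, chk_pos(f))
    chk_prop <- function(field) {
        v <- slot(object, field)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            sprintf("'%s' must be a proportion in [0, 1]", field)
        else character()
    }
    for (f in c("frac_background_de", "cis_fraction", "verdict_flip_rate"))
        msg <- c(msg, chk_prop(f))
    if (object@trans_coexpr_sd < 0)
        msg <- c(msg, "'trans_coexpr_sd' must be >= 0")
    if (object@depth_jitter < 0 || object@depth_jitter >= 1)
        msg <- c(msg, "'depth_jitter' must be in [0, 1)")
    if (length(object@genotypes) != 2L || anyDuplicated(object@genotypes))
        msg <- c(msg, "'genotypes' must be two distinct labels")
    ntriad <- object@n_planted_triads_per_genotype * 2L
    if (!length(msg)) {
        if (ntriad * object@triad_n_mrnas > object@n_genes)
            msg <- c(msg, "'n_planted_triads_per_genotype' too large for 'n_genes'")
        if (ntriad * object@triad_n_lncs > object@n_lncRNAs)
            msg <- c(msg, "'n_planted_triads_per_genotype' too large for 'n_lncRNAs'")
        if (ntriad > object@n_miRNAs)
            msg <- c(msg, "'n_planted_triads_per_genotype' too large for 'n_miRNAs'")
    }
    if (length(msg)) msg else TRUE
})

#' ThresholdConfig: every numeric threshold of the screening pipeline
#'
#' Construct with \code{\link{thresholdConfig}}. Defaults reproduce the
#' published screening rules: p < 0.05 and |log2FC| > 1 for differential
#' calls; |log2FC in DT| > 2 for DT-specific drought classes;
#' log2FC(DT)/log2FC(DS) > 3 for shared-direction classes; |r| > 0.9 and
#' p < 0.01 for trans targets; a 100 kb cis window; lncRNA candidates longer
#' than 200 nt with at least 2 exons; mature miRNAs of 18-30 nt.
#'
#' @slot de_p,de_lfc numeric differential-call thresholds.
#' @slot dt_specific_lfc numeric |log2FC in DT| floor for classes A/B.
#' @slot lfc_ratio numeric log2FC(DT)/log2FC(DS) floor for classes C/D.
#' @slot trans_r,trans_p numeric trans-target correlation thresholds.
#' @slot cis_window numeric cis window in bp.
#' @slot min_lnc_length,min_lnc_exons numeric lncRNA candidate filters.
#' @slot strict_exon_gt logical require exon count strictly greater than
#'   \code{min_lnc_exons} instead of >=.
#' @slot mirna_len_min,mirna_len_max numeric small-RNA length window (nt).
#' @slot mir_score_max numeric maximum complementarity penalty for a miRNA
#'   target edge.
#' @slot use_adjusted_p logical gate calls on BH-adjusted p-values.
#' @slot require_pair_link logical retain module members only if they
#'   participate in a linked (lncRNA, mRNA) pair (the stricter reading);
#'   \code{FALSE} keeps all candidates once one pair is linked.
#'
#' @exportClass ThresholdConfig
setClass("ThresholdConfig", representation(
    de_p = "numeric", de_lfc = "numeric", dt_specific_lfc = "numeric",
    lfc_ratio = "numeric", trans_r = "numeric", trans_p = "numeric",
    cis_window = "numeric", min_lnc_length = "numeric",
    min_lnc_exons = "numeric", strict_exon_gt = "logical",
    mirna_len_min = "numeric", mirna_len_max = "numeric",
    mir_score_max = "numeric", use_adjusted_p = "logical",
    require_pair_link = "logical"))

setValidity("ThresholdConfig", function(object) {
    msg <- character()
    for (f in c("de_p", "de_lfc", "dt_specific_lfc", "lfc_ratio", "trans_r",
                "trans_p", "cis_window", "min_lnc_length", "min_lnc_exons",
                "mirna_len_min", "mirna_len_max", "mir_score_max")) {
        v <- slot(object, f)
        if (length(v) != 1L || is.na(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", f))
    }
    if (!length(msg)) {
        if (object@de_p >= 1)
            msg <- c(msg, "'de_p' must be in (0, 1)")
        if (object@trans_p >= 1)
            msg <- c(msg, "'trans_p' must be in (0, 1)")
        if (object@trans_r >= 1)
            msg <- c(msg, "'trans_r' must be in (0, 1)")
        if (object@mirna_len_min > object@mirna_len_max)
            msg <- c(msg, "'mirna_len_min' must be <= 'mirna_len_max'")
    }
    if (length(msg)) msg else TRUE
})

#' PlantedTruth: the generator's record of what was planted
#'
#' @slot deFeatures data.frame with columns \code{feature}, \code{layer},
#'   \code{genotype}, \code{direction} ("up"/"down"), \code{log2fc}.
#' @slot plantedEdges data.frame of planted target edges (columns
#'   \code{source}, \code{target}, \code{type}, \code{realization}).
#' @slot plantedTriads data.frame with one row per planted module: columns
#'   \code{dem}, \code{dels}, \code{degs} (list columns of character),
#'   \code{module_type} (1 or 2), \code{genotype}.
#'
#' @exportClass PlantedTruth
setClass("PlantedTruth", representation(
    deFeatures = "data.frame", plantedEdges = "data.frame",
    plantedTriads = "data.frame"))

setValidity("PlantedTruth", function(object) {
    msg <- character()
    de <- object@deFeatures
    need <- c("feature", "layer", "genotype", "direction", "log2fc")
    if (!all(need %in% colnames(de)))
        msg <- c(msg, "deFeatures must have columns feature, layer, genotype, direction, log2fc")
    tr <- object@plantedTriads
    needt <- c("dem", "dels", "degs", "module_type", "genotype")
    if (!all(needt %in% colnames(tr)))
        msg <- c(msg, "plantedTriads must have columns dem, dels, degs, module_type, genotype")
    if (!length(msg) && nrow(tr)) {
        for (i in seq_len(nrow(tr))) {
            type <- tr$module_type[i]
            gt <- tr$genotype[i]
            dir_mir <- if (type == 1L) "up" else "down"
            dir_tgt <- if (type == 1L) "down" else "up"
            ok_dir <- function(ids, d) {
                hit <- de$feature %in% ids & de$genotype == gt
                all(ids %in% de$feature[hit]) && all(de$direction[hit] == d)
            }
            if (!ok_dir(tr$dem[i], dir_mir) ||
                !ok_dir(tr$dels[[i]], dir_tgt) ||
                !ok_dir(tr$degs[[i]], dir_tgt)) {
                msg <- c(msg, sprintf(
                    "triad %d: member directions inconsistent with module type", i))
                next
            }
            ed <- object@plantedEdges
            have <- function(s, t, ty) any(ed$source == s & ed$target == t &
                                           ed$type %in% ty)
            for (l in tr$dels[[i]])
                if (!have(tr$dem[i], l, "mir2lnc"))
                    msg <- c(msg, sprintf("triad %d: missing mir2lnc edge", i))
            for (g in tr$degs[[i]])
                if (!have(tr$dem[i], g, "mir2mrna"))
                    msg <- c(msg, sprintf("triad %d: missing mir2mrna edge", i))
            for (l in tr$dels[[i]])
                for (g in tr$degs[[i]])
                    if (!have(l, g, c("lnc_cis", "lnc_trans")))
                        msg <- c(msg, sprintf("triad %d: missing lnc->mRNA edge", i))
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

#' TriadModule: one DEM-centered regulatory module
#'
#' A differentially expressed miRNA (DEM) together with the differentially
#' expressed lncRNAs (DELs) and genes (DEGs) it targets in the opposite
#' direction, where retained DEL/DEG members share a cis or trans targeting
#' relation. Module type 1 is DEL-down / DEM-up / DEG-down; type 2 is the
#' mirror pattern.
#'
#' @slot genotype character(1) genotype of origin.
#' @slot dem character(1) miRNA id.
#' @slot dels,degs character vectors of retained member ids.
#' @slot moduleType integer(1), 1 or 2.
#' @slot edgeEvidence data.frame subset of the input edges supporting the
#'   module.
#'
#' @exportClass TriadModule
setClass("TriadModule", representation(
    genotype = "character", dem = "character", dels = "character",
    degs = "character", moduleType = "integer", edgeEvidence = "data.frame"))

setValidity("TriadModule", function(object) {
    msg <- character()
    if (length(object@dem) != 1L)
        msg <- c(msg, "'dem' must be a single miRNA id")
    if (!length(object@dels) || !length(object@degs))
        msg <- c(msg, "'dels' and 'degs' must be non-empty")
    if (length(object@moduleType) != 1L || !object@moduleType %in% c(1L, 2L))
        msg <- c(msg, "'moduleType' must be 1 or 2")
    if (length(msg)) msg else TRUE
})
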