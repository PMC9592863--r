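#' Build a simulation configuration
#'
#' Defaults describe the emulated study: two genotypes (drought-tolerant DT,
#' drought-sensitive DS), control (CK) vs drought, three replicates, negative
#' binomial counts with variance mu + alpha mu^2, planted two-fold-squared
#' (log2FC = 2) condition effects on triad members, and coordinates that
#' realize planted lncRNA-mRNA pairs as cis neighbours within 100 kb.
#'
#' @param n_genes,n_lncRNAs,n_miRNAs feature counts per layer.
#' @param n_replicates replicates per genotype x condition cell.
#' @param genotypes two genotype labels.
#' @param baseline_mean NB mean for every non-shifted feature/sample.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2),
#'   shared across features.
#' @param n_planted_triads_per_genotype planted modules per genotype.
#' @param triad_n_lncs,triad_n_mrnas lncRNA / mRNA members per planted triad.
#' @param planted_log2fc planted effect magnitude (log2 scale).
#' @param frac_background_de proportion of remaining features given a
#'   background effect of the same magnitude in one random genotype.
#' @param cis_fraction proportion of planted lncRNA-mRNA pairs realized as
#'   genomic neighbours; the rest are placed apart and co-expressed through a
#'   shared per-sample factor.
#' @param trans_coexpr_sd log-sd of that shared factor.
#' @param n_background_edges decoy miRNA target edges (half mir2lnc, half
#'   mir2mrna) among random features.
#' @param verdict_flip_rate probability each coding-potential verdict is
#'   flipped.
#' @param depth_jitter library-size factors are drawn log-uniformly in
#'   \code{[1 - depth_jitter, 1 + depth_jitter]}.
#' @param genome_n_chromosomes,chromosome_length synthetic genome shape.
#' @param seed RNG seed; identical seeds give bit-identical output.
#'
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(n_genes = 50, n_lncRNAs = 20, n_miRNAs = 10, seed = 1)
#' @export
simulationConfig <- function(n_genes = 300L, n_lncRNAs = 120L,
                             n_miRNAs = 60L, n_replicates = 3L,
                             genotypes = c("DT", "DS"),
                             baseline_mean = 500, dispersion = 0.05,
                             n_planted_triads_per_genotype = 3L,
                             triad_n_lncs = 1L, triad_n_mrnas = 2L,
                             planted_log2fc = 2,
                             frac_background_de = 0.05,
                             cis_fraction = 1.0, trans_coexpr_sd = 0.5,
                             n_background_edges = 60L,
                             verdict_flip_rate = 0,
                             depth_jitter = 0.2,
                             genome_n_chromosomes = 7L,
                             chromosome_length = 5e7,
                             seed = 1L) {
    cfg <- new("SimulationConfig",
        n_genes = .as_count(n_genes, "n_genes"),
        n_lncRNAs = .as_count(n_lncRNAs, "n_lncRNAs"),
        n_miRNAs = .as_count(n_miRNAs, "n_miRNAs"),
        n_replicates = .as_count(n_replicates, "n_replicates"),
        genotypes = as.character(genotypes),
        baseline_mean = as.numeric(baseline_mean),
        dispersion = as.numeric(dispersion),
        n_planted_triads_per_genotype =
            .as_count(n_planted_triads_per_genotype,
                      "n_planted_triads_per_genotype"),
        triad_n_lncs = .as_count(triad_n_lncs, "triad_n_lncs"),
        triad_n_mrnas = .as_count(triad_n_mrnas, "triad_n_mrnas"),
        planted_log2fc = as.numeric(planted_log2fc),
        frac_background_de = as.numeric(frac_background_de),
        cis_fraction = as.numeric(cis_fraction),
        trans_coexpr_sd = as.numeric(trans_coexpr_sd),
        n_background_edges = .as_count(n_background_edges,
                                       "n_background_edges"),
        verdict_flip_rate = as.numeric(verdict_flip_rate),
        depth_jitter = as.numeric(depth_jitter),
        genome_n_chromosomes = .as_count(genome_n_chromosomes,
                                         "genome_n_chromosomes"),
        chromosome_length = as.numeric(chromosome_length),
        seed = .as_count(seed, "seed", min = 0L))
    validObject(cfg)
    cfg
}

.as_count <- function(x, field, min = 0L) {
    if (length(x) != 1L || is.na(x) || !is.finite(as.numeric(x)) ||
        abs(as.numeric(x) - round(as.numeric(x))) > 1e-8)
        stop(sprintf("'%s' must be a single integer", field))
    as.integer(round(as.numeric(x)))
}

#' Build a threshold configuration
#'
#' Defaults reproduce the published screening rules; see
#' \linkS4class{ThresholdConfig} for the meaning of each field.
#'
#' @param de_p,de_lfc differential-call thresholds (p < de_p and
#'   |log2FC| > de_lfc, strict inequalities).
#' @param dt_specific_lfc |log2FC in DT| floor for DT-specific classes.
#' @param lfc_ratio log2FC(DT)/log2FC(DS) floor for shared-direction classes.
#' @param trans_r,trans_p trans-target thresholds (|r| > trans_r and
#'   p < trans_p).
#' @param cis_window cis window in bp (boundary gap, inclusive).
#' @param min_lnc_length minimum lncRNA length in nt (strict >).
#' @param min_lnc_exons minimum exon count.
#' @param strict_exon_gt require strictly more than \code{min_lnc_exons}
#'   exons instead of at least that many.
#' @param mirna_len_min,mirna_len_max retained small-RNA length window (nt,
#'   inclusive).
#' @param mir_score_max maximum complementarity penalty for a target edge.
#' @param use_adjusted_p gate calls on Benjamini-Hochberg adjusted p-values.
#' @param require_pair_link per-member (TRUE) vs per-module (FALSE) reading
#'   of the DEL-DEG mutual-targeting retention rule.
#'
#' @return A validated \linkS4class{ThresholdConfig}.
#' @examples
#' thresholdConfig()
#' thresholdConfig(use_adjusted_p = TRUE)
#' @export
thresholdConfig <- function(de_p = 0.05, de_lfc = 1, dt_specific_lfc = 2,
                            lfc_ratio = 3, trans_r = 0.9, trans_p = 0.01,
                            cis_window = 1e5, min_lnc_length = 200,
                            min_lnc_exons = 2, strict_exon_gt = FALSE,
                            mirna_len_min = 18, mirna_len_max = 30,
                            mir_score_max = 4, use_adjusted_p = FALSE,
                            require_pair_link = TRUE) {
    cfg <- new("ThresholdConfig",
        de_p = as.numeric(de_p), de_lfc = as.numeric(de_lfc),
        dt_specific_lfc = as.numeric(dt_specific_lfc),
        lfc_ratio = as.numeric(lfc_ratio),
        trans_r = as.numeric(trans_r), trans_p = as.numeric(trans_p),
        cis_window = as.numeric(cis_window),
        min_lnc_length = as.numeric(min_lnc_length),
        min_lnc_exons = as.numeric(min_lnc_exons),
        strict_exon_gt = isTRUE(strict_exon_gt),
        mirna_len_min = as.numeric(mirna_len_min),
        mirna_len_max = as.numeric(mirna_len_max),
        mir_score_max = as.numeric(mir_score_max),
        use_adjusted_p = isTRUE(use_adjusted_p),
        require_pair_link = isTRUE(require_pair_link))
    validObject(cfg)
    cfg
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  layers: %d mRNA, %d lncRNA, %d miRNA\n",
                object@n_genes, object@n_lncRNAs, object@n_miRNAs))
    cat(sprintf("  design: %s x {CK, drought} x %d replicates\n",
                paste(object@genotypes, collapse = "/"),
                object@n_replicates))
    cat(sprintf("  NB: mean %g, dispersion %g; planted log2FC %g (%d triads/genotype)\n",
                object@baseline_mean, object@dispersion,
                object@planted_log2fc,
                object@n_planted_triads_per_genotype))
    cat(sprintf("  seed: %d\n", object@seed))
    invisible(NULL)
})

setMethod("show", "ThresholdConfig", function(object) {
    cat("ThresholdConfig\n")
    cat(sprintf("  DE: p < %g, |log2FC| > %g%s\n", object@de_p, object@de_lfc,
                if (object@use_adjusted_p) " (BH-adjusted)" else ""))
    cat(sprintf("  drought classes: |log2FC(DT)| > %g, ratio > %g\n",
                object@dt_specific_lfc, object@lfc_ratio))
    cat(sprintf("  targets: cis <= %g bp; trans |r| > %g, p < %g\n",
                object@cis_window, object@trans_r, object@trans_p))
    invisible(NULL)
})
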