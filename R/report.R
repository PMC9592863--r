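#' Relative expression by the comparative 2^-ddCt method
#'
#' \code{fold = 2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))}. Ct values must lie in (0, 50).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (target and reference gene, treated and control
#'   states); vectorized.
#' @return Relative expression fold(s).
#' @examples
#' ddct(23, 20, 25, 20)  # ddCt = -2, fold 4
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
    cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
             ct_ref_control)
    if (anyNA(cts) || any(cts <= 0) || any(cts >= 50))
        stop("Ct values must lie in (0, 50)")
    ddct_val <- (ct_target_treated - ct_ref_treated) -
        (ct_target_control - ct_ref_control)
    2^(-ddct_val)
}

#' Filter mature miRNAs by length
#'
#' Keeps small RNAs whose length is within the configured window
#' (18-30 nt by default, inclusive), the standard clean-read length filter
#' for mature miRNAs.
#'
#' @param lengths named numeric vector of miRNA lengths in nt.
#' @param config a \linkS4class{ThresholdConfig}.
#' @return Character vector of retained ids.
#' @examples
#' filterMirnaLengths(c(m1 = 21, m2 = 17, m3 = 30, m4 = 31))
#' @export
filterMirnaLengths <- function(lengths, config = thresholdConfig()) {
    stopifnot(is(config, "ThresholdConfig"))
    names(lengths)[lengths >= config@mirna_len_min &
                   lengths <= config@mirna_len_max]
}

#' Run the full screening pipeline on simulated data
#'
#' Executes simulate -> normalize -> differential calling -> lncRNA
#' filtering/classification -> target assignment -> screens, and returns a
#' result bundle with a summary mirroring the usual reporting granularity
#' (per-genotype up/down tallies, Venn quadruples, drought-class counts,
#' module list, and truth-recovery scores). Deterministic given the
#' simulation seed. With \code{out_dir} set, all stage outputs are written
#' as TSV/GTF/JSON.
#'
#' @param sim_config a \linkS4class{SimulationConfig}.
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @param out_dir optional output directory.
#' @param verbose log stage boundaries with row counts.
#' @return List with elements \code{sim}, \code{de} (nested
#'   genotype -> layer results), \code{accepted_lncs}, \code{lnc_classes},
#'   \code{edges}, \code{drought_classes}, \code{modules}, \code{recovery},
#'   \code{summary}.
#' @examples
#' res <- runPipeline(simulationConfig(n_genes = 60, n_lncRNAs = 20,
#'     n_miRNAs = 10, n_planted_triads_per_genotype = 1, seed = 11))
#' res$summary$modules
#' @export
runPipeline <- function(sim_config = simulationConfig(),
                        thresholds = thresholdConfig(),
                        out_dir = NULL, verbose = FALSE) {
    say <- function(...) if (verbose) message(sprintf(...))
    sim <- simulateExperiment(sim_config)
    say("simulate: %d mRNA, %d lncRNA, %d miRNA features x %d samples",
        nrow(sim$layers$mrna), nrow(sim$layers$lncrna),
        nrow(sim$layers$mirna), nrow(sim$design))

    genotypes <- sim_config@genotypes
    layers <- c("mrna", "lncrna", "mirna")
    de <- lapply(setNames(genotypes, genotypes), function(g)
        lapply(setNames(layers, layers), function(l)
            nbTest(sim$layers[[l]], g, thresholds)))
    say("diffexpr: %s",
        paste(vapply(genotypes, function(g) sprintf("%s %d/%d/%d called", g,
            sum(de[[g]]$mrna$direction != "none"),
            sum(de[[g]]$lncrna$direction != "none"),
            sum(de[[g]]$mirna$direction != "none")), character(1)),
            collapse = "; "))

    ann <- sim$annotation
    cand <- ann[ann$biotype == "unknown", , drop = FALSE]
    accepted <- consensusFilter(cand, sim$verdicts, thresholds)
    genes_ann <- ann[ann$layer == "mRNA", , drop = FALSE]
    lnc_ann <- ann[ann$transcript_id %in% accepted, , drop = FALSE]
    gene_exons <- sim$exons[sim$exons$transcript_id %in%
                            genes_ann$transcript_id, , drop = FALSE]
    classes <- if (nrow(lnc_ann))
        classifyLnc(lnc_ann, genes_ann, gene_exons)
    else data.frame(transcript_id = character(), class = character())
    say("lncannot: %d/%d candidates accepted", length(accepted), nrow(cand))

    kept_mirs <- filterMirnaLengths(
        setNames(ann$length[ann$layer == "miRNA"],
                 ann$transcript_id[ann$layer == "miRNA"]), thresholds)

    lengths <- setNames(ann$length, ann$transcript_id)
    fpkm_mrna <- fpkm(sim$layers$mrna, lengths)
    fpkm_lnc <- fpkm(sim$layers$lncrna, lengths)
    tpm_mir <- tpmSmallRna(sim$layers$mirna)

    cis <- cisTargets(lnc_ann, genes_ann, thresholds)
    trans <- transTargets(exprValues(fpkm_lnc)[accepted, , drop = FALSE],
                          exprValues(fpkm_mrna), thresholds)
    mir_edges <- sim$edges[sim$edges$type %in% c("mir2lnc", "mir2mrna") &
                           sim$edges$source %in% kept_mirs,
                           c("source", "target", "type", "r", "p",
                             "distance", "score"), drop = FALSE]
    edges <- rbind(mir_edges, cis, trans)
    rownames(edges) <- NULL
    say("targeting: %d cis, %d trans, %d miRNA edges",
        nrow(cis), nrow(trans), nrow(mir_edges))

    dcls <- classifyDroughtDegs(de$DS$mrna, de$DT$mrna, thresholds)

    restrict <- function(res, ids) res[res$feature %in% ids, , drop = FALSE]
    modules <- list()
    for (g in genotypes) {
        de_g <- list(mrna = de[[g]]$mrna,
                     lncrna = restrict(de[[g]]$lncrna, accepted),
                     mirna = restrict(de[[g]]$mirna, kept_mirs))
        modules <- c(modules, screenTriads(de_g, edges, thresholds,
                                           genotype = g))
    }
    recovery <- scoreTriadRecovery(modules, sim$truth)
    say("screens: %d modules (precision %.2f, recall %.2f)",
        length(modules), recovery$precision, recovery$recall)

    summary <- .pipeline_summary(de, accepted, classes, dcls, modules,
                                 recovery, genotypes)
    res <- list(sim = sim, de = de, accepted_lncs = accepted,
                lnc_classes = classes, edges = edges,
                drought_classes = dcls, modules = modules,
                recovery = recovery, summary = summary,
                normalized = list(fpkm_mrna = fpkm_mrna,
                                  fpkm_lnc = fpkm_lnc, tpm_mir = tpm_mir))
    if (!is.null(out_dir))
        writePipelineResults(res, out_dir)
    res
}

.pipeline_summary <- function(de, accepted, classes, dcls, modules,
                              recovery, genotypes) {
    tallies <- list()
    venns <- list()
    for (l in c("mrna", "lncrna", "mirna")) {
        for (g in genotypes) {
            r <- de[[g]][[l]]
            if (l == "lncrna") r <- r[r$feature %in% accepted, , drop = FALSE]
            tallies[[paste(l, g, sep = "_")]] <- list(
                up = sum(r$direction == "up"),
                down = sum(r$direction == "down"),
                total = sum(r$direction != "none"))
        }
        ids <- lapply(genotypes, function(g) {
            r <- de[[g]][[l]]
            if (l == "lncrna") r <- r[r$feature %in% accepted, , drop = FALSE]
            r$feature[r$direction != "none"]
        })
        names(ids) <- genotypes
        venns[[l]] <- vennCounts(ids$DS, ids$DT)
    }
    class_counts <- as.list(table(factor(dcls$class,
        levels = c("A", "B", "C", "D", "E", "F", "none"))))
    module_tab <- lapply(modules, function(m) list(
        genotype = m@genotype, dem = m@dem, dels = m@dels, degs = m@degs,
        module_type = m@moduleType))
    list(tallies = tallies, venns = venns,
         lnc_classes = as.list(table(classes$class)),
         n_accepted_lncs = length(accepted),
         drought_class_counts = class_counts,
         n_drought_degs = sum(dcls$class != "none"),
         modules = module_tab, n_modules = length(modules),
         recovery = recovery[c("n_emitted", "n_planted", "n_matched",
                               "precision", "recall")])
}
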