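#' Three-class drought-resistance DEG screen
#'
#' Assigns each feature to one of six drought-resistance classes from its
#' per-genotype differential results, or \code{"none"}:
#' \describe{
#'   \item{A / B}{called in DT only, with \code{|log2FC(DT)| >
#'     dt_specific_lfc}; A up, B down.}
#'   \item{C / D}{called in both genotypes with the same sign and
#'     \code{log2FC(DT) / log2FC(DS) > lfc_ratio}; C up, D down.}
#'   \item{E / F}{called in both genotypes with opposite signs; E is
#'     DS-down / DT-up, F is DS-up / DT-down.}
#' }
#' "Called in DT only" means called at the base differential thresholds in
#' DT and not called in DS. A feature present in only one genotype's
#' results is treated as not called in the other.
#'
#' @param res_ds,res_dt data.frames from \code{\link{nbTest}} for DS and DT
#'   (same layer), with columns \code{feature}, \code{log2fc},
#'   \code{direction}.
#' @param config a \linkS4class{ThresholdConfig}.
#' @return data.frame with columns \code{feature}, \code{class},
#'   \code{log2fc_ds}, \code{log2fc_dt}.
#' @examples
#' ds <- data.frame(feature = c("a", "b"), layer = "mRNA",
#'                  log2fc = c(0, 1.05), direction = c("none", "up"))
#' dt <- data.frame(feature = c("a", "b"), layer = "mRNA",
#'                  log2fc = c(2.5, 3.5), direction = c("up", "up"))
#' classifyDroughtDegs(ds, dt)  # a -> A, b -> C (ratio 3.33 > 3)
#' @export
classifyDroughtDegs <- function(res_ds, res_dt, config = thresholdConfig()) {
    stopifnot(is(config, "ThresholdConfig"))
    feats <- union(res_ds$feature, res_dt$feature)
    only <- c(setdiff(res_ds$feature, res_dt$feature),
              setdiff(res_dt$feature, res_ds$feature))
    if (length(only))
        message(length(only),
                " feature(s) present in one genotype's results only; ",
                "treated as not called there")
    ids <- match(feats, res_ds$feature)
    idt <- match(feats, res_dt$feature)
    lfc_ds <- ifelse(is.na(ids), NA_real_, res_ds$log2fc[ids])
    lfc_dt <- ifelse(is.na(idt), NA_real_, res_dt$log2fc[idt])
    called_ds <- !is.na(ids) & res_ds$direction[ids] != "none"
    called_dt <- !is.na(idt) & res_dt$direction[idt] != "none"

    cls <- rep("none", length(feats))
    dt_only <- called_dt & !called_ds & abs(lfc_dt) > config@dt_specific_lfc
    cls[dt_only & lfc_dt > 0] <- "A"
    cls[dt_only & lfc_dt < 0] <- "B"
    both <- called_dt & called_ds
    same <- both & sign(lfc_dt) == sign(lfc_ds)
    ratio_ok <- same & (lfc_dt / lfc_ds) > config@lfc_ratio
    cls[ratio_ok & lfc_dt > 0] <- "C"
    cls[ratio_ok & lfc_dt < 0] <- "D"
    opp <- both & sign(lfc_dt) != sign(lfc_ds)
    cls[opp & lfc_dt > 0] <- "E"
    cls[opp & lfc_dt < 0] <- "F"
    data.frame(feature = feats, class = cls, log2fc_ds = lfc_ds,
               log2fc_dt = lfc_dt, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Direction-constrained lncRNA-miRNA-mRNA module screen
#'
#' For each differentially expressed miRNA (DEM) of one genotype: candidate
#' DELs are the DEM's \code{mir2lnc} targets called in the opposite
#' direction; candidate DEGs are its \code{mir2mrna} targets called in the
#' opposite direction. Members are then retained only if they participate
#' in at least one (DEL, DEG) pair linked by a \code{lnc_cis} or
#' \code{lnc_trans} edge (the mutual-targeting rule; set
#' \code{require_pair_link = FALSE} in the config for the looser reading
#' that keeps all candidates once any pair is linked). One module is
#' emitted per DEM with non-empty DEL and DEG sets; an up-regulated DEM
#' gives module type 1 (DEL down / DEM up / DEG down), a down-regulated
#' DEM type 2.
#'
#' @param de named list of \code{\link{nbTest}} result data.frames for one
#'   genotype: elements \code{mrna}, \code{lncrna}, \code{mirna}.
#' @param edges edge data.frame with columns \code{source}, \code{target},
#'   \code{type} (types \code{mir2lnc}, \code{mir2mrna}, \code{lnc_cis},
#'   \code{lnc_trans}); edges naming unknown features are ignored.
#' @param config a \linkS4class{ThresholdConfig}.
#' @return List of \linkS4class{TriadModule} objects (possibly empty).
#' @examples
#' de <- list(
#'   mirna = data.frame(feature = "mir1", direction = "up", log2fc = 2),
#'   lncrna = data.frame(feature = "lnc1", direction = "down", log2fc = -2),
#'   mrna = data.frame(feature = "g1", direction = "down", log2fc = -2))
#' edges <- data.frame(source = c("mir1", "mir1", "lnc1"),
#'                     target = c("lnc1", "g1", "g1"),
#'                     type = c("mir2lnc", "mir2mrna", "lnc_trans"))
#' screenTriads(de, edges, genotype = "DT")
#' @param genotype genotype label recorded in the emitted modules.
#' @export
screenTriads <- function(de, edges, config = thresholdConfig(),
                         genotype = "DT") {
    stopifnot(is(config, "ThresholdConfig"),
              all(c("mrna", "lncrna", "mirna") %in% names(de)))
    dir_of <- function(res) setNames(res$direction, res$feature)
    dmir <- dir_of(de$mirna); dlnc <- dir_of(de$lncrna)
    dgene <- dir_of(de$mrna)
    e_ml <- edges[edges$type == "mir2lnc", , drop = FALSE]
    e_mg <- edges[edges$type == "mir2mrna", , drop = FALSE]
    e_lg <- edges[edges$type %in% c("lnc_cis", "lnc_trans"), , drop = FALSE]
    modules <- list()
    dems <- names(dmir)[dmir %in% c("up", "down")]
    for (dem in dems) {
        d <- dmir[[dem]]
        opp <- if (d == "up") "down" else "up"
        cand_del <- unique(e_ml$target[e_ml$source == dem])
        cand_del <- cand_del[!is.na(dlnc[cand_del]) & dlnc[cand_del] == opp]
        cand_deg <- unique(e_mg$target[e_mg$source == dem])
        cand_deg <- cand_deg[!is.na(dgene[cand_deg]) & dgene[cand_deg] == opp]
        if (!length(cand_del) || !length(cand_deg)) next
        link <- e_lg[e_lg$source %in% cand_del & e_lg$target %in% cand_deg,
                     , drop = FALSE]
        if (!nrow(link)) next
        if (config@require_pair_link) {
            dels <- sort(unique(link$source))
            degs <- sort(unique(link$target))
        } else {
            dels <- sort(cand_del)
            degs <- sort(cand_deg)
        }
        ev <- rbind(
            e_ml[e_ml$source == dem & e_ml$target %in% dels, , drop = FALSE],
            e_mg[e_mg$source == dem & e_mg$target %in% degs, , drop = FALSE],
            link)
        rownames(ev) <- NULL
        modules[[length(modules) + 1L]] <- new("TriadModule",
            genotype = genotype, dem = dem, dels = dels, degs = degs,
            moduleType = if (d == "up") 1L else 2L, edgeEvidence = ev)
    }
    modules
}

#' @describeIn screenTriads the module's miRNA id.
#' @param module a \linkS4class{TriadModule}.
#' @export
demId <- function(module) module@dem

#' @describeIn screenTriads the module's retained lncRNA ids.
#' @export
delIds <- function(module) module@dels

#' @describeIn screenTriads the module's retained gene ids.
#' @export
degIds <- function(module) module@degs

#' @describeIn screenTriads the module type (1 or 2).
#' @export
moduleType <- function(module) module@moduleType

#' @describeIn screenTriads the genotype the module was screened in.
#' @export
moduleGenotype <- function(module) module@genotype

setMethod("show", "TriadModule", function(object) {
    cat(sprintf("TriadModule (type %d, %s): %s\n", object@moduleType,
                object@genotype, object@dem))
    cat("  DELs:", paste(object@dels, collapse = ", "), "\n")
    cat("  DEGs:", paste(object@degs, collapse = ", "), "\n")
    invisible(NULL)
})

#' Score recovered modules against planted truth
#'
#' A planted triad counts as recovered when an emitted module of the same
#' genotype has the same DEM, the same module type, and exactly the planted
#' DEL and DEG member sets. Precision is the matched fraction of emitted
#' modules, recall the matched fraction of planted triads.
#'
#' @param modules list of \linkS4class{TriadModule} (pooled genotypes).
#' @param truth a \linkS4class{PlantedTruth}.
#' @return Named list: \code{n_emitted}, \code{n_planted}, \code{n_matched},
#'   \code{precision}, \code{recall} (both \code{NA} when undefined).
#' @export
scoreTriadRecovery <- function(modules, truth) {
    tr <- plantedTriads(truth)
    key <- function(genotype, dem, type, dels, degs)
        paste(genotype, dem, type,
              paste(sort(dels), collapse = ","),
              paste(sort(degs), collapse = ","), sep = "|")
    planted <- if (nrow(tr))
        vapply(seq_len(nrow(tr)), function(i)
            key(tr$genotype[i], tr$dem[i], tr$module_type[i],
                tr$dels[[i]], tr$degs[[i]]), character(1))
    else character()
    emitted <- vapply(modules, function(m)
        key(m@genotype, m@dem, m@moduleType, m@dels, m@degs), character(1))
    n_matched <- length(intersect(unique(planted), unique(emitted)))
    list(n_emitted = length(emitted), n_planted = length(planted),
         n_matched = n_matched,
         precision = if (length(emitted)) n_matched / length(emitted)
                     else NA_real_,
         recall = if (length(planted)) n_matched / length(planted)
                  else NA_real_)
}
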