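#' Negative-binomial Wald test for drought vs control within one genotype
#'
#' Counts are normalized by median-of-ratios size factors (computed on the
#' genotype's samples), per-condition means are formed, a per-feature NB
#' dispersion is estimated by the method of moments from the pooled
#' within-condition variance (floored at 1e-8), and a two-sided Wald test is
#' performed on \code{log2fc = log2((mean_drought + c) / (mean_CK + c))}
#' with pseudocount \code{c = 0.5}. The Wald statistic is referred to a t
#' distribution with \code{n1 + n2 - 2} degrees of freedom, which keeps the
#' type-I error near nominal at three replicates (a normal reference is
#' markedly anti-conservative there). A feature is called when
#' \code{p < de_p} (or BH-adjusted p when \code{use_adjusted_p}) and
#' \code{|log2fc| > de_lfc}, both strict.
#'
#' @param object an \linkS4class{ExpressionLayer} with unit \code{"counts"}.
#' @param genotype genotype label to test (its CK and drought samples are
#'   used; each condition needs >= 2 replicates).
#' @param config a \linkS4class{ThresholdConfig}.
#'
#' @return data.frame with columns \code{feature}, \code{layer},
#'   \code{genotype}, \code{mean_ck}, \code{mean_drought}, \code{log2fc},
#'   \code{p}, \code{padj}, \code{direction} ("up", "down" or "none").
#' @examples
#' sim <- simulateExperiment(simulationConfig(
#'     n_genes = 50, n_lncRNAs = 20, n_miRNAs = 10,
#'     n_planted_triads_per_genotype = 1, seed = 3))
#' head(nbTest(sim$layers$mrna, "DT", thresholdConfig()))
#' @export
nbTest <- function(object, genotype, config = thresholdConfig()) {
    stopifnot(is(object, "ExpressionLayer"), is(config, "ThresholdConfig"))
    if (exprUnit(object) != "counts")
        stop("nbTest requires unit 'counts', got '", exprUnit(object), "'")
    des <- sampleDesign(object)
    sel <- des$genotype == genotype
    if (!any(sel))
        stop("no samples for genotype '", genotype, "'")
    des <- des[sel, , drop = FALSE]
    k <- exprValues(object)[, des$sample, drop = FALSE]
    ck <- des$sample[des$condition == "CK"]
    trt <- des$sample[des$condition != "CK"]
    if (length(ck) < 2L || length(trt) < 2L)
        stop("each condition needs >= 2 replicates for genotype '",
             genotype, "' (got ", length(ck), " CK, ", length(trt),
             " drought)")
    sf <- .median_of_ratios(k)
    q <- sweep(k, 2, sf, `/`)
    res <- .nb_wald(q[, ck, drop = FALSE], q[, trt, drop = FALSE])
    padj <- p.adjust(res$p, method = "BH")
    p_gate <- if (config@use_adjusted_p) padj else res$p
    called <- !is.na(p_gate) & p_gate < config@de_p &
        abs(res$log2fc) > config@de_lfc
    direction <- ifelse(!called, "none",
                        ifelse(res$log2fc > 0, "up", "down"))
    data.frame(feature = rownames(k), layer = rnaLayer(object),
               genotype = genotype, mean_ck = res$m1,
               mean_drought = res$m2, log2fc = res$log2fc, p = res$p,
               padj = padj, direction = direction,
               row.names = NULL, stringsAsFactors = FALSE)
}

## q1, q2: normalized counts, control / treated; rows = features
.nb_wald <- function(q1, q2, pseudocount = 0.5, dispersion_floor = 1e-8) {
    n1 <- ncol(q1); n2 <- ncol(q2)
    m1 <- rowMeans(q1); m2 <- rowMeans(q2)
    v1 <- apply(q1, 1, var); v2 <- apply(q2, 1, var)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    mbar <- (m1 + m2) / 2
    alpha <- ifelse(mbar > 0,
                    pmax((s2 - mbar) / mbar^2, dispersion_floor),
                    dispersion_floor)
    log2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
    var_m1 <- (m1 + alpha * m1^2) / n1
    var_m2 <- (m2 + alpha * m2^2) / n2
    se <- sqrt(var_m1 / (m1 + pseudocount)^2 +
               var_m2 / (m2 + pseudocount)^2) / log(2)
    z <- ifelse(se > 0, log2fc / se, 0)
    p <- 2 * pt(-abs(z), df = n1 + n2 - 2)
    p[se == 0 & log2fc == 0] <- 1
    list(m1 = m1, m2 = m2, log2fc = log2fc, se = se, stat = z, p = p)
}

#' Per-genotype up/down call sets
#'
#' Splits two genotypes' differential results into the four id sets behind
#' the published Venn diagrams: DS-up, DS-down, DT-up, DT-down. A feature
#' may appear in one DS set and one DT set simultaneously; duplicate
#' features within one genotype's results are an error.
#'
#' @param res_ds,res_dt data.frames from \code{\link{nbTest}} for the DS and
#'   DT genotypes of the same layer.
#' @return Named list of character vectors \code{ds_up}, \code{ds_down},
#'   \code{dt_up}, \code{dt_down}.
#' @examples
#' r <- data.frame(feature = c("a", "b"), layer = "mRNA", genotype = "DS",
#'                 log2fc = c(2, -2), p = 0.01,
#'                 direction = c("up", "down"))
#' r2 <- transform(r, genotype = "DT", direction = c("up", "none"))
#' callSets(r, r2)
#' @export
callSets <- function(res_ds, res_dt) {
    layers <- unique(c(res_ds$layer, res_dt$layer))
    if (length(layers) > 1L)
        stop("results mix layers: ", paste(layers, collapse = ", "))
    if (anyDuplicated(res_ds$feature))
        stop("duplicate feature(s) in DS results: ",
             paste(unique(res_ds$feature[duplicated(res_ds$feature)]),
                   collapse = ", "))
    if (anyDuplicated(res_dt$feature))
        stop("duplicate feature(s) in DT results: ",
             paste(unique(res_dt$feature[duplicated(res_dt$feature)]),
                   collapse = ", "))
    list(ds_up = res_ds$feature[res_ds$direction == "up"],
         ds_down = res_ds$feature[res_ds$direction == "down"],
         dt_up = res_dt$feature[res_dt$direction == "up"],
         dt_down = res_dt$feature[res_dt$direction == "down"])
}

#' Venn counts for two id sets
#'
#' @param ds_set,dt_set character vectors of feature ids (direction-pooled
#'   differential calls of each genotype).
#' @return Named list with \code{common}, \code{ds_specific},
#'   \code{dt_specific}, \code{union}; the identity
#'   \code{union = |ds| + |dt| - common} holds by construction.
#' @examples
#' vennCounts(letters[1:5], letters[4:8])
#' @export
vennCounts <- function(ds_set, dt_set) {
    ds_set <- unique(ds_set); dt_set <- unique(dt_set)
    common <- length(intersect(ds_set, dt_set))
    list(common = common,
         ds_specific = length(ds_set) - common,
         dt_specific = length(dt_set) - common,
         union = length(ds_set) + length(dt_set) - common)
}

#' Venn counts from printed set sizes
#'
#' Reconstructs union and genotype-specific counts from a reported pair of
#' set sizes and their overlap, as printed in summary tables.
#'
#' @param n_ds,n_dt set sizes; \code{n_common} their overlap.
#' @return Named list with \code{common}, \code{ds_specific},
#'   \code{dt_specific}, \code{union}.
#' @examples
#' vennFromSizes(15909, 11233, 6680)  # union 20462, specific 9229 / 4553
#' @export
vennFromSizes <- function(n_ds, n_dt, n_common) {
    if (n_common > min(n_ds, n_dt))
        stop("overlap exceeds a set size")
    list(common = n_common,
         ds_specific = n_ds - n_common,
         dt_specific = n_dt - n_common,
         union = n_ds + n_dt - n_common)
}
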