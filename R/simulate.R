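#' Simulate a three-layer drought expression experiment with planted truth
#'
#' Generates negative-binomial count matrices for mRNA, lncRNA and miRNA
#' layers over a 2-genotype x 2-condition x n-replicate design, a synthetic
#' genome annotation, coding-potential verdicts, a target-edge table, and a
#' \linkS4class{PlantedTruth} record of everything planted:
#' \itemize{
#'   \item each planted triad gets a miRNA shifted by
#'     \code{2^planted_log2fc} in its genotype's drought samples and lncRNA /
#'     mRNA members shifted the opposite way (module type 1: miRNA up,
#'     targets down; type 2 mirrored — types alternate over triads);
#'   \item planted lncRNA-mRNA pairs are realized cis (same chromosome,
#'     boundary gap <= 100 kb) with probability \code{cis_fraction},
#'     otherwise placed apart and co-expressed through a shared per-sample
#'     lognormal factor;
#'   \item a \code{frac_background_de} fraction of remaining features gets
#'     the same effect magnitude in one random genotype and direction;
#'   \item decoy miRNA target edges are sprinkled among random features.
#' }
#' Identical seeds give bit-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#'
#' @return A list with elements \code{layers} (list of three
#'   \linkS4class{ExpressionLayer} count matrices: \code{mrna},
#'   \code{lncrna}, \code{mirna}), \code{design} (data.frame),
#'   \code{annotation} (transcript table), \code{exons} (exon table),
#'   \code{verdicts} (coding-potential 0/1 table, 1 = noncoding),
#'   \code{edges} (declared target edges), \code{truth}
#'   (\linkS4class{PlantedTruth}) and \code{config}.
#'
#' @examples
#' sim <- simulateExperiment(simulationConfig(
#'     n_genes = 40, n_lncRNAs = 15, n_miRNAs = 8,
#'     n_planted_triads_per_genotype = 1, seed = 7))
#' sim$layers$mrna
#' plantedTriads(sim$truth)
#' @export
simulateExperiment <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)

    gids <- sprintf("gene_%04d", seq_len(config@n_genes))
    lids <- sprintf("lnc_%04d", seq_len(config@n_lncRNAs))
    mids <- sprintf("mir_%04d", seq_len(config@n_miRNAs))
    design <- .sim_design(config)

    plan <- .sim_plan_triads(config, gids, lids, mids)
    ann <- .sim_annotation(config, gids, lids, mids, plan)
    counts <- .sim_counts(config, design, gids, lids, mids, plan)
    verdicts <- .sim_verdicts(config, gids, lids)
    edges <- .sim_edges(config, plan, ann$annotation, gids, lids, mids)
    truth <- .sim_truth(plan, edges)

    layers <- list(
        mrna = ExpressionLayer(counts$mrna, design, "counts", "mRNA"),
        lncrna = ExpressionLayer(counts$lncrna, design, "counts", "lncRNA"),
        mirna = ExpressionLayer(counts$mirna, design, "counts", "miRNA"))
    list(layers = layers, design = design, annotation = ann$annotation,
         exons = ann$exons, verdicts = verdicts,
         edges = edges$declared, truth = truth, config = config)
}

.sim_design <- function(config) {
    g <- rep(config@genotypes, each = 2L * config@n_replicates)
    cond <- rep(rep(.CONDITIONS, each = config@n_replicates), 2L)
    rep_i <- rep(seq_len(config@n_replicates), 4L)
    sample <- paste0(g, ifelse(cond == "CK", "CK", "T"), rep_i)
    data.frame(sample = sample, genotype = g, condition = cond,
               replicate = rep_i, stringsAsFactors = FALSE)
}

## Decide triad membership, module types, per-feature planted effects and
## pair realizations before any placement or count draw.
.sim_plan_triads <- function(config, gids, lids, mids) {
    ntr <- config@n_planted_triads_per_genotype
    lfc <- config@planted_log2fc
    ## signed planted lfc per feature per genotype, 0 = not DE
    eff <- list()
    for (g in config@genotypes) {
        eff[[g]] <- c(setNames(numeric(length(gids)), gids),
                      setNames(numeric(length(lids)), lids),
                      setNames(numeric(length(mids)), mids))
    }
    dem_v <- character(); geno_v <- character(); type_v <- integer()
    dels_l <- list(); degs_l <- list()
    pairs <- NULL
    used <- character()
    k <- 0L
    for (g in config@genotypes) {
        for (t in seq_len(ntr)) {
            k <- k + 1L
            type <- if (k %% 2L == 1L) 1L else 2L
            dem <- setdiff(mids, used)[1L]
            dels <- setdiff(lids, used)[seq_len(config@triad_n_lncs)]
            degs <- setdiff(gids, used)[seq_len(config@triad_n_mrnas)]
            used <- c(used, dem, dels, degs)
            s_mir <- if (type == 1L) 1 else -1
            eff[[g]][dem] <- s_mir * lfc
            eff[[g]][dels] <- -s_mir * lfc
            eff[[g]][degs] <- -s_mir * lfc
            dem_v <- c(dem_v, dem); geno_v <- c(geno_v, g)
            type_v <- c(type_v, type)
            dels_l[[k]] <- dels; degs_l[[k]] <- degs
            for (l in dels) for (m in degs) {
                cis <- runif(1) < config@cis_fraction
                pairs <- rbind(pairs, data.frame(
                    lnc = l, gene = m, triad = k,
                    realization = if (cis) "cis" else "trans",
                    stringsAsFactors = FALSE))
            }
        }
    }
    triads <- if (k > 0L) {
        tr <- data.frame(dem = dem_v, genotype = geno_v,
                         module_type = type_v, stringsAsFactors = FALSE)
        tr$dels <- dels_l
        tr$degs <- degs_l
        tr
    } else NULL
    ## background DE among untouched features
    bg <- NULL
    if (config@frac_background_de > 0) {
        free <- setdiff(c(gids, lids, mids), used)
        hit <- free[runif(length(free)) < config@frac_background_de]
        if (length(hit)) {
            bgg <- sample(config@genotypes, length(hit), replace = TRUE)
            dirs <- sample(c(1, -1), length(hit), replace = TRUE)
            for (i in seq_along(hit))
                eff[[bgg[i]]][hit[i]] <- dirs[i] * lfc
            bg <- data.frame(feature = hit, genotype = bgg,
                             log2fc = dirs * lfc, stringsAsFactors = FALSE)
        }
    }
    list(eff = eff, triads = triads, pairs = pairs, background = bg)
}

.sim_exon_structure <- function(n_exons, exon_range, intron_range) {
    ex <- sample(exon_range[1]:exon_range[2], n_exons, replace = TRUE)
    intr <- if (n_exons > 1L)
        sample(intron_range[1]:intron_range[2], n_exons - 1L, replace = TRUE)
    else integer()
    list(exons = ex, introns = intr, span = sum(ex) + sum(intr))
}

.sim_annotation <- function(config, gids, lids, mids, plan) {
    chroms <- sprintf("chr%d", seq_len(config@genome_n_chromosomes))
    L <- config@chromosome_length
    place_one <- function(id, layer, biotype, n_exons, exon_range,
                          intron_range) {
        st <- .sim_exon_structure(n_exons, exon_range, intron_range)
        chrom <- sample(chroms, 1L)
        start <- sample.int(max(1L, as.integer(L - st$span)), 1L)
        strand <- sample(c("+", "-"), 1L)
        list(id = id, layer = layer, biotype = biotype, chrom = chrom,
             start = start, strand = strand, st = st)
    }
    recs <- list()
    for (id in gids)
        recs[[id]] <- place_one(id, "mRNA", "known",
                                sample(2:5, 1L), c(200L, 500L),
                                c(100L, 2000L))
    for (id in lids)
        recs[[id]] <- place_one(id, "lncRNA", "unknown",
                                sample(2:3, 1L), c(150L, 400L),
                                c(100L, 1500L))
    for (id in mids)
        recs[[id]] <- place_one(id, "miRNA", "miRNA", 1L, c(21L, 24L),
                                c(0L, 0L))
    ## realize planted pair placement
    if (!is.null(plan$pairs)) for (i in seq_len(nrow(plan$pairs))) {
        l <- recs[[plan$pairs$lnc[i]]]
        m <- recs[[plan$pairs$gene[i]]]
        lnc_end <- l$start + l$st$span - 1L
        if (plan$pairs$realization[i] == "cis") {
            gap <- sample.int(100000L, 1L) - 1L   # boundary gap in [0, 99999]
            m$chrom <- l$chrom
            m$start <- lnc_end + 1L + gap
            if (m$start + m$st$span - 1L > L) {
                ## place upstream of the lncRNA instead
                m$start <- max(1L, l$start - 1L - gap - m$st$span)
            }
        } else {
            other <- setdiff(chroms, l$chrom)
            if (length(other)) {
                m$chrom <- sample(other, 1L)
                m$start <- sample.int(max(1L, as.integer(L - m$st$span)), 1L)
            } else {
                ## single chromosome: force a gap well beyond 100 kb
                m$start <- if (lnc_end + 200001L + m$st$span < L)
                    lnc_end + 200001L else max(1L, l$start - 200001L - m$st$span)
            }
        }
        recs[[plan$pairs$gene[i]]] <- m
    }
    ann <- do.call(rbind, lapply(recs, function(r) data.frame(
        transcript_id = r$id, gene_id = r$id, layer = r$layer,
        biotype = r$biotype, chrom = r$chrom, start = r$start,
        end = r$start + r$st$span - 1L, strand = r$strand,
        n_exons = length(r$st$exons), length = sum(r$st$exons),
        stringsAsFactors = FALSE)))
    rownames(ann) <- NULL
    exons <- do.call(rbind, lapply(recs, function(r) {
        starts <- r$start + cumsum(c(0L, r$st$exons[-length(r$st$exons)] +
                                     r$st$introns))
        data.frame(transcript_id = r$id, chrom = r$chrom, start = starts,
                   end = starts + r$st$exons - 1L, strand = r$strand,
                   exon_number = seq_along(starts), stringsAsFactors = FALSE)
    }))
    rownames(exons) <- NULL
    list(annotation = ann, exons = exons)
}

.sim_counts <- function(config, design, gids, lids, mids, plan) {
    n_s <- nrow(design)
    jit <- config@depth_jitter
    draw_layer <- function(ids) {
        depth <- if (jit > 0)
            exp(runif(n_s, log(1 - jit), log(1 + jit))) else rep(1, n_s)
        mu <- matrix(config@baseline_mean, length(ids), n_s,
                     dimnames = list(ids, design$sample))
        for (j in seq_len(n_s)) {
            if (design$condition[j] == "drought") {
                e <- plan$eff[[design$genotype[j]]][ids]
                mu[, j] <- mu[, j] * 2^e
            }
        }
        list(mu = mu, depth = depth)
    }
    lay <- list(mrna = draw_layer(gids), lncrna = draw_layer(lids),
                mirna = draw_layer(mids))
    ## shared per-sample co-expression factor for trans-realized pairs:
    ## one factor vector per triad, applied to its lncRNA(s) and the
    ## trans-realized mRNA partners
    if (!is.null(plan$pairs) && any(plan$pairs$realization == "trans") &&
        config@trans_coexpr_sd > 0) {
        for (k in unique(plan$pairs$triad[plan$pairs$realization == "trans"])) {
            fac <- exp(rnorm(n_s, 0, config@trans_coexpr_sd))
            pk <- plan$pairs[plan$pairs$triad == k &
                             plan$pairs$realization == "trans", ]
            for (l in unique(pk$lnc))
                lay$lncrna$mu[l, ] <- lay$lncrna$mu[l, ] * fac
            for (m in unique(pk$gene))
                lay$mrna$mu[m, ] <- lay$mrna$mu[m, ] * fac
        }
    }
    out <- lapply(lay, function(x) {
        mu <- sweep(x$mu, 2, x$depth, `*`)
        k <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config@dispersion),
                    nrow(mu), ncol(mu), dimnames = dimnames(mu))
        storage.mode(k) <- "double"
        k
    })
    out
}

.sim_verdicts <- function(config, gids, lids) {
    ids <- c(lids, gids)
    base <- c(rep(1L, length(lids)), rep(0L, length(gids)))
    one_tool <- function() {
        flip <- runif(length(ids)) < config@verdict_flip_rate
        ifelse(flip, 1L - base, base)
    }
    data.frame(transcript_id = ids, cpc = one_tool(), cnci = one_tool(),
               cpat = one_tool(), pfam = one_tool(),
               stringsAsFactors = FALSE)
}

.sim_edges <- function(config, plan, ann, gids, lids, mids) {
    edge_row <- function(source, target, type, realization = NA_character_,
                         distance = NA_real_) {
        data.frame(source = source, target = target, type = type,
                   r = NA_real_, p = NA_real_, distance = distance,
                   score = NA_real_, realization = realization,
                   stringsAsFactors = FALSE)
    }
    rows <- list()
    if (!is.null(plan$triads)) for (i in seq_len(nrow(plan$triads))) {
        dem <- plan$triads$dem[i]
        for (l in plan$triads$dels[[i]])
            rows[[length(rows) + 1L]] <- edge_row(dem, l, "mir2lnc", "planted")
        for (m in plan$triads$degs[[i]])
            rows[[length(rows) + 1L]] <- edge_row(dem, m, "mir2mrna", "planted")
    }
    coord <- setNames(split(ann[, c("chrom", "start", "end")],
                            seq_len(nrow(ann))), ann$transcript_id)
    if (!is.null(plan$pairs)) for (i in seq_len(nrow(plan$pairs))) {
        l <- coord[[plan$pairs$lnc[i]]]
        m <- coord[[plan$pairs$gene[i]]]
        if (plan$pairs$realization[i] == "cis") {
            d <- max(0L, max(l$start, m$start) - min(l$end, m$end) - 1L)
            rows[[length(rows) + 1L]] <- edge_row(
                plan$pairs$lnc[i], plan$pairs$gene[i], "lnc_cis", "cis", d)
        } else {
            rows[[length(rows) + 1L]] <- edge_row(
                plan$pairs$lnc[i], plan$pairs$gene[i], "lnc_trans", "trans")
        }
    }
    planted <- do.call(rbind, rows)
    ## decoy miRNA edges among random features (may duplicate planted by
    ## chance on tiny instances; deduplicated below)
    nbg <- config@n_background_edges
    if (nbg > 0) {
        src <- sample(mids, nbg, replace = TRUE)
        is_lnc <- seq_len(nbg) <= nbg / 2
        tgt <- ifelse(is_lnc, sample(lids, nbg, replace = TRUE),
                      sample(gids, nbg, replace = TRUE))
        bg <- edge_row(src, tgt, ifelse(is_lnc, "mir2lnc", "mir2mrna"),
                       "background")
        declared <- rbind(planted, bg)
    } else declared <- planted
    if (is.null(declared))
        declared <- data.frame(
            source = character(), target = character(), type = character(),
            r = numeric(), p = numeric(), distance = numeric(),
            score = numeric(), realization = character(),
            stringsAsFactors = FALSE)
    declared <- declared[!duplicated(declared[, c("source", "target", "type")]), ]
    rownames(declared) <- NULL
    list(declared = declared, planted = planted)
}

.sim_truth <- function(plan, edges) {
    de <- NULL
    layer_of <- function(id) c(gene = "mRNA", lnc = "lncRNA",
                               mir = "miRNA")[[sub("_.*", "", id)]]
    for (g in names(plan$eff)) {
        e <- plan$eff[[g]]
        hit <- e != 0
        if (any(hit)) {
            ids <- names(e)[hit]
            de <- rbind(de, data.frame(
                feature = ids,
                layer = vapply(ids, layer_of, character(1)),
                genotype = g,
                direction = ifelse(e[hit] > 0, "up", "down"),
                log2fc = unname(e[hit]), stringsAsFactors = FALSE))
        }
    }
    if (is.null(de))
        de <- data.frame(feature = character(), layer = character(),
                         genotype = character(), direction = character(),
                         log2fc = numeric(), stringsAsFactors = FALSE)
    rownames(de) <- NULL
    triads <- plan$triads
    if (is.null(triads)) {
        triads <- data.frame(dem = character(), genotype = character(),
                             module_type = integer(), stringsAsFactors = FALSE)
        triads$dels <- list()
        triads$degs <- list()
    }
    pe <- if (is.null(edges$planted))
        data.frame(source = character(), target = character(),
                   type = character(), realization = character(),
                   stringsAsFactors = FALSE)
    else edges$planted[, c("source", "target", "type", "realization")]
    truth <- new("PlantedTruth", deFeatures = de, plantedEdges = pe,
                 plantedTriads = triads)
    validObject(truth)
    truth
}

#' @describeIn simulateExperiment accessor for the planted DE feature table.
#' @param truth a \linkS4class{PlantedTruth}.
#' @export
deFeatures <- function(truth) truth@deFeatures

#' @describeIn simulateExperiment accessor for the planted edge table.
#' @export
plantedEdges <- function(truth) truth@plantedEdges

#' @describeIn simulateExperiment accessor for the planted triad table.
#' @export
plantedTriads <- function(truth) truth@plantedTriads

setMethod("show", "PlantedTruth", function(object) {
    cat(sprintf(
        "PlantedTruth: %d planted DE calls, %d planted edges, %d triads\n",
        nrow(object@deFeatures), nrow(object@plantedEdges),
        nrow(object@plantedTriads)))
    invisible(NULL)
})
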