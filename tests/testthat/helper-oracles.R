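# Independent brute-force oracles. Deliberately naive: plain loops and
# direct predicate evaluation, sharing no code with the implementation.

bf_call_sets <- function(res_ds, res_dt, config = thresholdConfig()) {
    pick <- function(res, want_up) {
        out <- character()
        for (i in seq_len(nrow(res))) {
            called <- res$p[i] < config@de_p &&
                abs(res$log2fc[i]) > config@de_lfc
            if (called && ((want_up && res$log2fc[i] > 0) ||
                           (!want_up && res$log2fc[i] < 0)))
                out <- c(out, res$feature[i])
        }
        out
    }
    list(ds_up = pick(res_ds, TRUE), ds_down = pick(res_ds, FALSE),
         dt_up = pick(res_dt, TRUE), dt_down = pick(res_dt, FALSE))
}

bf_cis <- function(lncs, genes, window = 1e5) {
    out <- NULL
    for (i in seq_len(nrow(lncs))) for (j in seq_len(nrow(genes))) {
        if (lncs$chrom[i] != genes$chrom[j]) next
        gap <- max(lncs$start[i], genes$start[j]) -
            min(lncs$end[i], genes$end[j]) - 1
        gap <- max(0, gap)
        if (gap <= window)
            out <- rbind(out, data.frame(
                source = lncs$transcript_id[i],
                target = genes$transcript_id[j], distance = gap,
                stringsAsFactors = FALSE))
    }
    out
}

bf_trans <- function(lm, gm, r_min = 0.9, p_max = 0.01) {
    out <- NULL
    for (i in seq_len(nrow(lm))) for (j in seq_len(nrow(gm))) {
        ct <- cor.test(lm[i, ], gm[j, , drop = TRUE], method = "pearson")
        if (abs(ct$estimate) > r_min && ct$p.value < p_max)
            out <- rbind(out, data.frame(
                source = rownames(lm)[i], target = rownames(gm)[j],
                r = unname(ct$estimate), stringsAsFactors = FALSE))
    }
    out
}

bf_drought_classes <- function(res_ds, res_dt, config = thresholdConfig()) {
    feats <- union(res_ds$feature, res_dt$feature)
    out <- character(length(feats))
    for (k in seq_along(feats)) {
        f <- feats[k]
        i <- match(f, res_ds$feature); j <- match(f, res_dt$feature)
        called_ds <- !is.na(i) && res_ds$direction[i] != "none"
        called_dt <- !is.na(j) && res_dt$direction[j] != "none"
        l_ds <- if (is.na(i)) NA else res_ds$log2fc[i]
        l_dt <- if (is.na(j)) NA else res_dt$log2fc[j]
        out[k] <-
            if (called_dt && !called_ds &&
                abs(l_dt) > config@dt_specific_lfc)
                if (l_dt > 0) "A" else "B"
            else if (called_dt && called_ds && sign(l_dt) == sign(l_ds) &&
                     l_dt / l_ds > config@lfc_ratio)
                if (l_dt > 0) "C" else "D"
            else if (called_dt && called_ds && sign(l_dt) != sign(l_ds))
                if (l_dt > 0) "E" else "F"
            else "none"
    }
    setNames(out, feats)
}

# Exhaustive (DEL, DEM, DEG) triple enumeration followed by per-DEM grouping
bf_screen_triads <- function(de, edges, genotype = "DT") {
    has_edge <- function(s, t, types)
        any(edges$source == s & edges$target == t & edges$type %in% types)
    dir_of <- function(res, f) {
        i <- match(f, res$feature)
        if (is.na(i)) "none" else res$direction[i]
    }
    mods <- list()
    for (dem in de$mirna$feature) {
        d <- dir_of(de$mirna, dem)
        if (d == "none") next
        opp <- if (d == "up") "down" else "up"
        dels <- character(); degs <- character()
        for (del in de$lncrna$feature) for (deg in de$mrna$feature) {
            ok <- has_edge(dem, del, "mir2lnc") &&
                has_edge(dem, deg, "mir2mrna") &&
                dir_of(de$lncrna, del) == opp &&
                dir_of(de$mrna, deg) == opp &&
                has_edge(del, deg, c("lnc_cis", "lnc_trans"))
            if (ok) {
                dels <- union(dels, del)
                degs <- union(degs, deg)
            }
        }
        if (length(dels) && length(degs))
            mods[[length(mods) + 1L]] <- list(
                genotype = genotype, dem = dem, dels = sort(dels),
                degs = sort(degs),
                module_type = if (d == "up") 1L else 2L)
    }
    mods
}

canon_modules <- function(mods) {
    keys <- vapply(mods, function(m) {
        dem <- if (is.list(m)) m$dem else demId(m)
        dels <- if (is.list(m)) m$dels else delIds(m)
        degs <- if (is.list(m)) m$degs else degIds(m)
        type <- if (is.list(m)) m$module_type else moduleType(m)
        g <- if (is.list(m)) m$genotype else moduleGenotype(m)
        paste(g, dem, type, paste(sort(dels), collapse = ","),
              paste(sort(degs), collapse = ","), sep = "|")
    }, character(1))
    sort(keys)
}

# random small screening instance: directions + edges over tiny id sets
random_screen_instance <- function(seed) {
    set.seed(seed)
    n_mir <- sample(2:5, 1); n_lnc <- sample(2:6, 1); n_gene <- sample(2:8, 1)
    mk <- function(prefix, n) {
        data.frame(feature = paste0(prefix, seq_len(n)),
                   direction = sample(c("up", "down", "none"), n,
                                      replace = TRUE),
                   log2fc = round(runif(n, -3, 3), 2),
                   stringsAsFactors = FALSE)
    }
    de <- list(mirna = mk("mir", n_mir), lncrna = mk("lnc", n_lnc),
               mrna = mk("g", n_gene))
    edge <- function(s, t, type) data.frame(source = s, target = t,
                                            type = type,
                                            stringsAsFactors = FALSE)
    es <- list()
    for (m in de$mirna$feature) for (l in de$lncrna$feature)
        if (runif(1) < 0.4) es[[length(es) + 1]] <- edge(m, l, "mir2lnc")
    for (m in de$mirna$feature) for (g in de$mrna$feature)
        if (runif(1) < 0.4) es[[length(es) + 1]] <- edge(m, g, "mir2mrna")
    for (l in de$lncrna$feature) for (g in de$mrna$feature)
        if (runif(1) < 0.3)
            es[[length(es) + 1]] <- edge(l, g, sample(c("lnc_cis",
                                                        "lnc_trans"), 1))
    edges <- if (length(es)) do.call(rbind, es) else
        data.frame(source = character(), target = character(),
                   type = character(), stringsAsFactors = FALSE)
    list(de = de, edges = edges)
}

random_placement <- function(seed, n_lnc = 6, n_gene = 8, chrom_n = 2,
                             L = 1e6) {
    set.seed(seed)
    mk <- function(prefix, n, span_max = 5e4) {
        start <- sample.int(L, n)
        data.frame(transcript_id = paste0(prefix, seq_len(n)),
                   chrom = paste0("chr", sample.int(chrom_n, n, replace = TRUE)),
                   start = start,
                   end = start + sample.int(span_max, n),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
    }
    list(lncs = mk("lnc", n_lnc), genes = mk("g", n_gene))
}
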