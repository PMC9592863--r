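# Small fixture builders shared across test files.

tiny_design <- function(genotypes = c("DT", "DS"), n_rep = 3) {
    g <- rep(genotypes, each = 2 * n_rep)
    cond <- rep(rep(c("CK", "drought"), each = n_rep), length(genotypes))
    rep_i <- rep(seq_len(n_rep), 2 * length(genotypes))
    data.frame(sample = paste0(g, ifelse(cond == "CK", "CK", "T"), rep_i),
               genotype = g, condition = cond, replicate = rep_i,
               stringsAsFactors = FALSE)
}

tiny_layer <- function(counts, design = tiny_design(), layer = "mRNA",
                       unit = "counts") {
    if (is.null(colnames(counts))) colnames(counts) <- design$sample
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("f", seq_len(nrow(counts)))
    ExpressionLayer(counts, design, unit = unit, layer = layer)
}

# NB count layer for one genotype pair of conditions; the first n_de
# features get a drought multiplier (kept a minority so size-factor
# normalization is not distorted)
nb_layer <- function(n_feat, mu = 500, dispersion = 0.05, n_rep = 3,
                     fold = 1, n_de = n_feat, genotype = "DT",
                     layer = "mRNA") {
    design <- tiny_design(genotypes = genotype, n_rep = n_rep)
    mu_mat <- matrix(mu, n_feat, nrow(design))
    de_rows <- seq_len(min(n_de, n_feat))
    mu_mat[de_rows, design$condition == "drought"] <-
        mu_mat[de_rows, design$condition == "drought"] * fold
    k <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 1 / dispersion),
                n_feat, nrow(design))
    tiny_layer(k, design, layer = layer)
}

small_sim_config <- function(seed = 1, ...) {
    args <- list(n_genes = 60, n_lncRNAs = 24, n_miRNAs = 12,
                 n_planted_triads_per_genotype = 2, n_background_edges = 10,
                 seed = seed)
    args[names(list(...))] <- list(...)
    do.call(simulationConfig, args)
}

# reverse complement of an RNA string (5'->3' both ways)
rna_revcomp <- function(s) {
    chartr("ACGU", "UGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# random differential-result table obeying the call invariant
random_results <- function(n, genotype, layer = "mRNA", config = thresholdConfig(),
                           seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    lfc <- round(runif(n, -4, 4), 2)
    p <- round(runif(n)^2, 4)
    called <- p < config@de_p & abs(lfc) > config@de_lfc
    data.frame(feature = paste0("f", seq_len(n)), layer = layer,
               genotype = genotype, log2fc = lfc, p = p,
               direction = ifelse(!called, "none",
                                  ifelse(lfc > 0, "up", "down")),
               stringsAsFactors = FALSE)
}
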