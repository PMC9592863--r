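mk_res <- function(feature, log2fc, called = TRUE) {
    data.frame(feature = feature, layer = "mRNA", log2fc = log2fc,
               p = ifelse(called, 0.001, 0.5),
               direction = ifelse(!called, "none",
                                  ifelse(log2fc > 0, "up", "down")),
               stringsAsFactors = FALSE)
}

test_that("drought classes follow their defining predicates", {
    ds <- mk_res(c("a", "b", "c", "d"), c(0.2, 1.05, 1.2, 1.5),
                 called = c(FALSE, TRUE, TRUE, TRUE))
    dt <- mk_res(c("a", "b", "c", "d"), c(2.5, 3.5, -1.3, 3.0))
    got <- classifyDroughtDegs(ds, dt)
    cls <- setNames(got$class, got$feature)
    expect_identical(cls[["a"]], "A")     # DT-specific up, |lfc| > 2
    expect_identical(cls[["b"]], "C")     # ratio 3.5/1.05 = 3.33 > 3
    expect_identical(cls[["c"]], "F")     # DS up, DT down
    expect_identical(cls[["d"]], "none")  # ratio 2 < 3
    # DT-specific but |lfc| <= 2 stays none
    ds2 <- mk_res("e", 0.1, called = FALSE)
    dt2 <- mk_res("e", 1.8)
    expect_identical(classifyDroughtDegs(ds2, dt2)$class, "none")
    # down-regulated variants
    ds3 <- mk_res(c("f", "g"), c(-0.3, -1.05), called = c(FALSE, TRUE))
    dt3 <- mk_res(c("f", "g"), c(-2.5, -3.5))
    got3 <- classifyDroughtDegs(ds3, dt3)
    expect_identical(setNames(got3$class, got3$feature),
                     c(f = "B", g = "D"))
})

test_that("classes partition and match brute-force predicate evaluation", {
    for (seed in 1:15) {
        ds <- random_results(50, "DS", seed = seed)
        dt <- random_results(50, "DT", seed = seed + 500)
        got <- classifyDroughtDegs(ds, dt)
        expect_identical(anyDuplicated(got$feature), 0L)
        want <- bf_drought_classes(ds, dt)
        expect_identical(setNames(got$class, got$feature), want[got$feature])
    }
})

test_that("features known to one genotype only are treated as not called", {
    ds <- mk_res("a", 1.5)
    dt <- mk_res(c("a", "b"), c(1.6, 2.5))
    expect_message(got <- classifyDroughtDegs(ds, dt), "one genotype")
    cls <- setNames(got$class, got$feature)
    expect_identical(cls[["b"]], "A")
})

minimal_de <- function(deg_dir = "down") {
    list(mirna = data.frame(feature = "mir1", direction = "up",
                            log2fc = 2, stringsAsFactors = FALSE),
         lncrna = data.frame(feature = "lnc1", direction = "down",
                             log2fc = -2, stringsAsFactors = FALSE),
         mrna = data.frame(feature = "g1",
                           direction = deg_dir,
                           log2fc = if (deg_dir == "down") -2 else 2,
                           stringsAsFactors = FALSE))
}

minimal_edges <- data.frame(
    source = c("mir1", "mir1", "lnc1"),
    target = c("lnc1", "g1", "g1"),
    type = c("mir2lnc", "mir2mrna", "lnc_trans"),
    stringsAsFactors = FALSE)

test_that("a minimal consistent instance yields exactly one type-1 module", {
    mods <- screenTriads(minimal_de(), minimal_edges, genotype = "DT")
    expect_length(mods, 1)
    m <- mods[[1]]
    expect_identical(demId(m), "mir1")
    expect_identical(delIds(m), "lnc1")
    expect_identical(degIds(m), "g1")
    expect_identical(moduleType(m), 1L)
    expect_identical(moduleGenotype(m), "DT")
})

test_that("the opposite-direction constraint is enforced", {
    mods <- screenTriads(minimal_de(deg_dir = "up"), minimal_edges)
    expect_length(mods, 0)
    # missing del-deg link also kills the module
    mods2 <- screenTriads(minimal_de(), minimal_edges[1:2, ])
    expect_length(mods2, 0)
})

test_that("a down-regulated DEM produces a type-2 module", {
    de <- list(
        mirna = data.frame(feature = "mir1", direction = "down", log2fc = -2),
        lncrna = data.frame(feature = "lnc1", direction = "up", log2fc = 2),
        mrna = data.frame(feature = "g1", direction = "up", log2fc = 2))
    mods <- screenTriads(de, minimal_edges, genotype = "DS")
    expect_length(mods, 1)
    expect_identical(moduleType(mods[[1]]), 2L)
})

test_that("module screening equals exhaustive triple enumeration", {
    for (seed in 1:20) {
        inst <- random_screen_instance(seed)
        got <- screenTriads(inst$de, inst$edges, genotype = "DT")
        want <- bf_screen_triads(inst$de, inst$edges, genotype = "DT")
        expect_identical(canon_modules(got), canon_modules(want))
    }
})

test_that("adding an edge never removes a module member", {
    for (seed in 1:10) {
        inst <- random_screen_instance(seed + 100)
        base <- screenTriads(inst$de, inst$edges)
        extra <- data.frame(source = inst$de$lncrna$feature[1],
                            target = inst$de$mrna$feature[1],
                            type = "lnc_cis", stringsAsFactors = FALSE)
        grown <- screenTriads(inst$de, rbind(inst$edges, extra))
        for (m in base) {
            match_new <- Filter(function(x) demId(x) == demId(m), grown)
            expect_length(match_new, 1)
            expect_true(all(delIds(m) %in% delIds(match_new[[1]])))
            expect_true(all(degIds(m) %in% degIds(match_new[[1]])))
        }
    }
})

test_that("the looser retention reading keeps all opposite-direction candidates", {
    de <- list(
        mirna = data.frame(feature = "mir1", direction = "up", log2fc = 2),
        lncrna = data.frame(feature = c("lnc1", "lnc2"),
                            direction = "down", log2fc = -2),
        mrna = data.frame(feature = "g1", direction = "down", log2fc = -2))
    edges <- data.frame(
        source = c("mir1", "mir1", "mir1", "lnc1"),
        target = c("lnc1", "lnc2", "g1", "g1"),
        type = c("mir2lnc", "mir2lnc", "mir2mrna", "lnc_trans"))
    strict <- screenTriads(de, edges)
    expect_identical(delIds(strict[[1]]), "lnc1")  # lnc2 has no linked pair
    loose <- screenTriads(de, edges,
                          thresholdConfig(require_pair_link = FALSE))
    expect_identical(delIds(loose[[1]]), c("lnc1", "lnc2"))
})

test_that("emitted modules always satisfy the module invariants", {
    for (seed in c(3, 4, 5)) {
        res <- runPipeline(small_sim_config(seed = seed))
        edges <- res$edges
        for (m in res$modules) {
            expect_true(validObject(m))
            d_mir <- res$de[[moduleGenotype(m)]]$mirna
            expect_identical(
                d_mir$direction[d_mir$feature == demId(m)],
                if (moduleType(m) == 1L) "up" else "down")
            for (l in delIds(m))
                expect_true(any(edges$source == demId(m) &
                                edges$target == l &
                                edges$type == "mir2lnc"))
            for (g in degIds(m))
                expect_true(any(edges$source == demId(m) &
                                edges$target == g &
                                edges$type == "mir2mrna"))
            linked <- edges$type %in% c("lnc_cis", "lnc_trans") &
                edges$source %in% delIds(m) & edges$target %in% degIds(m)
            for (l in delIds(m))
                expect_true(l %in% edges$source[linked])
            for (g in degIds(m))
                expect_true(g %in% edges$target[linked])
        }
    }
})
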