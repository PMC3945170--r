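test_that("untestable designs are flagged with a reason", {
    # single status level
    a <- interactionAnova(rnorm(20), rep("hyper", 20),
                          rep(c("Body", "TSS200"), 10))
    expect_true(is.na(a$F))
    expect_equal(a$untestable_reason, "single_factor_level")
    # one status per location: interaction inestimable by rank
    b <- interactionAnova(rnorm(24),
                          rep(c("hyper", "hypo"), each = 12),
                          rep(c("Body", "TSS200"), each = 12))
    expect_equal(b$untestable_reason, "interaction_inestimable")
    # three populated cells of a 2x2 still leave no interaction df
    cells <- rbind(c("hyper", "Body"), c("hypo", "Body"),
                   c("hypo", "TSS200"))
    idx <- rep(1:3, each = 6)
    c3 <- interactionAnova(rnorm(18), cells[idx, 1], cells[idx, 2])
    expect_equal(c3$untestable_reason, "interaction_inestimable")
})

test_that("a perfect 2x2 interaction gives F = Inf, p = 0", {
    # 2 CpGs per cell x 4 samples = 8 obs per cell, zero noise, one
    # deviant cell mean
    status <- rep(c("hyper", "hypo", "hyper", "hypo"), each = 8)
    loc <- rep(c("Body", "Body", "TSS200", "TSS200"), each = 8)
    y <- rep(c(0.2, 0.2, 0.2, 0.6), each = 8)
    a <- interactionAnova(y, status, loc)
    expect_true(is.infinite(a$F))
    expect_equal(a$p, 0)
    expect_equal(a$untestable_reason, "")
})

test_that("F matches a pseudoinverse least-squares oracle", {
    skip_if_not_installed("MASS")
    set.seed(16)
    for (rep in 1:40) {
        n <- sample(12:30, 1)
        status <- sample(c("hyper", "hypo"), n, replace = TRUE)
        loc <- sample(c("Body", "TSS1500", "UTR3"), n, replace = TRUE)
        y <- rnorm(n, 0.5, 0.1)
        got <- interactionAnova(y, status, loc)
        want <- interactionFOracle(y, status, loc)
        if (is.null(want) || got$untestable_reason != "") {
            expect_true(is.null(want) == (got$untestable_reason != ""))
            next
        }
        expect_equal(got$F, want$F, tolerance = 1e-8)
        expect_equal(got$df1, want$df1)
        expect_equal(got$df2, want$df2)
    }
})

test_that("balanced designs reproduce the classical cell-means F", {
    set.seed(17)
    for (rep in 1:10) {
        r <- sample(3:5, 1)
        status <- rep(rep(c("hyper", "hypo"), each = r), 3)
        loc <- rep(c("Body", "TSS1500", "OpenSea"), each = 2 * r)
        y <- rnorm(length(status), 0.5, 0.1)
        got <- interactionAnova(y, status, loc)
        want <- balancedInteractionF(y, status, loc)
        expect_equal(got$F, want$F, tolerance = 1e-10)
        expect_equal(got$df1, want$df1)
        expect_equal(got$df2, want$df2)
        # and the stats::lm route agrees too
        lm_tab <- anova(lm(y ~ factor(status) * factor(loc)))
        expect_equal(got$F, lm_tab[["F value"]][3], tolerance = 1e-10)
    }
})

test_that("F is invariant to relabeling, permutation and offsets", {
    set.seed(18)
    n <- 24
    status <- sample(c("hyper", "hypo"), n, replace = TRUE, prob = c(.6, .4))
    loc <- sample(c("Body", "TSS200"), n, replace = TRUE)
    y <- rnorm(n, 0.5, 0.1)
    base <- interactionAnova(y, status, loc)
    swap <- c(hyper = "hypo", hypo = "hyper")
    expect_equal(interactionAnova(y, swap[status], loc)$F, base$F,
                 tolerance = 1e-10)
    perm <- sample(n)
    expect_equal(interactionAnova(y[perm], status[perm], loc[perm])$F,
                 base$F, tolerance = 1e-10)
    expect_equal(interactionAnova(y + 0.17, status, loc)$F, base$F,
                 tolerance = 1e-10)
})

test_that("per-gene analysis keeps untestable genes out of the BH family", {
    set.seed(19)
    ns <- 12
    beta <- matrix(rnorm(8 * ns, 0.5, 0.05), 8, ns,
                   dimnames = list(paste0("cg", 1:8), paste0("S", 1:ns)))
    pairs <- data.frame(
        cpg_id = paste0("cg", 1:8),
        transcript_id = c(rep("T1", 4), rep("T2", 2), rep("T3", 2)),
        direction = c("hyper", "hypo", "hyper", "hypo",
                      "hyper", "hyper",          # T2: single status
                      "hyper", "hypo"),          # T3: one status/location
        gene_context = c("Body", "Body", "TSS1500", "TSS1500",
                         "Body", "TSS1500", "Body", "TSS1500"),
        island_context = c("Island", "Island", "Shore", "Shore",
                           "Island", "Shore", "OpenSea", "OpenSea"),
        stringsAsFactors = FALSE)
    res <- runInteractionAnalysis(pairs, beta)
    expect_equal(nrow(res), 3)
    testable <- !is.na(res$p_gene_ctx)
    expect_identical(res$gene_id[testable], "T1")
    # BH over a family of one testable gene: adjusted = raw
    expect_equal(res$p_adj_gene_ctx[res$gene_id == "T1"],
                 res$p_gene_ctx[res$gene_id == "T1"])
    expect_equal(res$untestable_reason[res$gene_id == "T2"],
                 "single_factor_level")
    # p_min is the smaller raw p across taxonomies
    t1 <- res[res$gene_id == "T1", ]
    expect_equal(t1$p_min, min(t1$p_gene_ctx, t1$p_island_ctx))
    # a gene with a single CpG is untestable by bookkeeping
    one <- runInteractionAnalysis(pairs[5, ], beta)
    expect_equal(one$untestable_reason, "fewer_than_2_cpgs")
})

test_that("planted interaction genes are recovered end to end", {
    plants <- c(
        lapply(1:10, function(i)
            plantInteractionGene(paste0("gene", i), 0.25, 0.6)),
        ## equal-gap genes: testable but carrying no interaction
        lapply(11:20, function(i)
            plantInteractionGene(paste0("gene", i), 0.4, 0.4)))
    cfg <- pipelineConfig(seed = 77, out_dir = withr::local_tempdir(),
                          sim = simConfig(seed = 77), plants = plants)
    res <- runAll(cfg)
    sig <- res$interaction$gene_id[which(res$interaction$significant)]
    planted_tx <- sprintf("NM_%06d", 1:10)
    null_tx <- sprintf("NM_%06d", 11:20)
    expect_gte(sum(planted_tx %in% sig), 8)
    expect_lte(sum(null_tx %in% sig), 2)
})
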