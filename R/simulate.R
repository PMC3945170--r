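#' Simulation configuration
#'
#' Collects the parameters of the synthetic two-group array study. The
#' defaults emulate a 6 + 6 phenotype design (control "EIUM" vs case
#' "OSIS") with a bimodal beta-value landscape: unmethylated CpGs
#' centered at \code{unmethylated_mode} and methylated CpGs at
#' \code{methylated_mode}, with beta-distributed noise of the given
#' precision (variance \code{m(1-m)/(1+precision)} about mean m).
#'
#' @param seed master seed; every stage derives its own sub-seed from it
#'   so the whole dataset is reproducible bit-for-bit.
#' @param n_genes number of simulated transcripts (default 200).
#' @param cpgs_per_gene linked CpGs per gene (default 10).
#' @param context_mix target island-context proportions for body CpGs,
#'   named Island/Shore/OpenSea, summing to 1.
#' @param samples_per_group samples in each phenotype (default 6, >= 2).
#' @param beta_precision beta-noise precision (default 50).
#' @param unmethylated_mode,methylated_mode group beta centers in (0,1).
#' @param expr_noise_sd residual sd of log2 expression (default 0.5).
#' @param detection_dropout_rate per-(probe,sample) probability that the
#'   detection p is drawn above the presence threshold (default 0.01).
#' @param frac_unlinked extra intergenic probes with no transcript link,
#'   as a fraction of the linked probes (default 0.1).
#' @param n_sex_probes,n_noncpg_probes probes destined for the exclusion
#'   rules (chrX/Y and non-CpG probes).
#' @param treatment_effect optional uniform beta shift applied to
#'   IVD-treated samples (default 0: the design ships both treatment
#'   arms as controls).
#' @return a validated list of class "SimConfig".
#' @export
simConfig <- function(seed = 1L, n_genes = 200L, cpgs_per_gene = 10L,
                      context_mix = c(Island = 0.31, Shore = 0.33,
                                      OpenSea = 0.36),
                      samples_per_group = 6L, beta_precision = 50,
                      unmethylated_mode = 0.10, methylated_mode = 0.85,
                      expr_noise_sd = 0.5, detection_dropout_rate = 0.01,
                      frac_unlinked = 0.1, n_sex_probes = 20L,
                      n_noncpg_probes = 20L, treatment_effect = 0) {
    stopifnot(samples_per_group >= 2,
              unmethylated_mode > 0, unmethylated_mode < 1,
              methylated_mode > 0, methylated_mode < 1,
              beta_precision > 0, n_genes >= 1, cpgs_per_gene >= 1)
    if (abs(sum(context_mix) - 1) > 1e-8)
        stop("context_mix proportions must sum to 1")
    structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                   cpgs_per_gene = as.integer(cpgs_per_gene),
                   context_mix = context_mix,
                   samples_per_group = as.integer(samples_per_group),
                   beta_precision = beta_precision,
                   unmethylated_mode = unmethylated_mode,
                   methylated_mode = methylated_mode,
                   expr_noise_sd = expr_noise_sd,
                   detection_dropout_rate = detection_dropout_rate,
                   frac_unlinked = frac_unlinked,
                   n_sex_probes = as.integer(n_sex_probes),
                   n_noncpg_probes = as.integer(n_noncpg_probes),
                   treatment_effect = treatment_effect),
              class = "SimConfig")
}

#' Plant a differential-methylation / expression effect on one gene
#'
#' Declares a gene whose CpGs in the named contexts receive a signed
#' group-2 beta shift, and whose transcript receives a log2 fold change
#' whose sign is chosen so the requested Spearman correlation sign holds
#' in expectation (positive = hypermethylation with overexpression or
#' hypomethylation with underexpression).
#'
#' @param gene_id gene identifier ("gene<k>" in the simulated manifest).
#' @param effects named numeric vector, names in
#'   TSS1500/TSS200/UTR5/FirstExon/Body/UTR3; signed group-2 minus
#'   group-1 beta difference applied to every CpG in that context.
#'   Affected CpGs are given a direction-appropriate baseline (0.3 for
#'   sites gaining methylation, 0.7 for sites losing it) so the shifted
#'   mean stays inside (0, 1).
#' @param logfc absolute log2 fold change of the transcript (default 2.5).
#' @param correlation_sign "+" or "-"; the Spearman sign to enforce
#'   between the (first nonzero) planted CpG shift and expression.
#' @return a list of class "PlantedGeneSpec".
#' @export
plantedGene <- function(gene_id, effects, logfc = 2.5,
                        correlation_sign = c("+", "-")) {
    correlation_sign <- match.arg(correlation_sign)
    stopifnot(is.numeric(effects), length(effects) >= 1,
              all(names(effects) %in% .CONTEXT_GENE))
    if (any(abs(effects) > 0.6))
        stop("|effect| > 0.6 would push a group mean outside (0, 1) ",
             "from the direction-appropriate baseline")
    dom <- effects[effects != 0][1]
    if (is.na(dom)) dom <- 0
    lfc_sign <- if (correlation_sign == "+") sign(dom) else -sign(dom)
    if (lfc_sign == 0) lfc_sign <- 1
    structure(list(gene_id = gene_id, effects = effects,
                   logfc = lfc_sign * abs(logfc),
                   correlation_sign = correlation_sign,
                   both_directions = FALSE,
                   is_interaction_gene = FALSE),
              class = "PlantedGeneSpec")
}

#' Plant a status-by-location interaction gene
#'
#' Declares a gene whose promoter (TSS1500) and body CpGs each contain
#' both hyper- and hypomethylated sites, with a hyper-minus-hypo gap of
#' \code{|promoter_effect|} in the promoter group means and
#' \code{|body_effect|} in the body. An interaction between CpG
#' status and CpG location requires both statuses within at least two
#' locations and unequal gaps across locations: a gene with a single
#' status per location has cell means explained by location alone (the
#' interaction is rank-inestimable), and equal gaps everywhere carry no
#' interaction signal. The gene is therefore flagged
#' \code{is_interaction_gene} only when the two magnitudes differ.
#'
#' @param gene_id gene identifier.
#' @param promoter_effect,body_effect nonzero beta-shift magnitudes (the
#'   sign marks the dominant direction in that context; CpGs of both
#'   directions are planted either way). Magnitudes must be above the
#'   differential-methylation threshold for the gene to be callable.
#' @param logfc absolute log2 fold change of the transcript.
#' @return a list of class "PlantedGeneSpec" with
#'   \code{is_interaction_gene = (|promoter| != |body|)}.
#' @export
plantInteractionGene <- function(gene_id, promoter_effect, body_effect,
                                 logfc = 2.5) {
    if (promoter_effect == 0 || body_effect == 0)
        stop("both contexts need a nonzero (callable) effect; a zero ",
             "effect leaves a single differentially methylated location")
    if (abs(promoter_effect) > 0.6 || abs(body_effect) > 0.6)
        stop("|effect| > 0.6 would push a group mean outside (0, 1)")
    structure(list(gene_id = gene_id,
                   effects = c(TSS1500 = promoter_effect,
                               Body = body_effect),
                   logfc = abs(logfc) * sign(body_effect + promoter_effect +
                                             .Machine$double.eps),
                   correlation_sign = "+",
                   both_directions = TRUE,
                   is_interaction_gene =
                       abs(promoter_effect) != abs(body_effect)),
              class = "PlantedGeneSpec")
}

.stageSeeds <- function(seed, n = 6L) {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
}

# Gene structures: one transcript per gene, spaced 1 Mb apart on the
# autosomes, with a promoter CGI spanning [tss-600, tss+800] (+ strand).
.simGeneTable <- function(n_genes) {
    chrom <- paste0("chr", (seq_len(n_genes) - 1L) %% 22L + 1L)
    slot <- (seq_len(n_genes) - 1L) %/% 22L
    tss <- 1e6 * (slot + 1L) + 5e4
    data.frame(gene_id = paste0("gene", seq_len(n_genes)),
               transcript_id = sprintf("NM_%06d", seq_len(n_genes)),
               chrom = chrom, strand = "+", tss = tss,
               body_start = tss, body_end = tss + 30000L,
               stringsAsFactors = FALSE)
}

# Sample positions for CpGs given gene context and target island
# context, using the promoter-CGI geometry of .simGeneTable (CGI =
# [tss - 600, tss + 800]). Vectorized over probes.
.simCpGPositions <- function(ctx, island_target, tss) {
    n <- length(ctx)
    runifInt <- function(lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))
    offset <- integer(n)
    i <- ctx == "TSS200"
    offset[i] <- -runifInt(1, 200)[i]
    i <- ctx == "TSS1500"
    isl <- island_target == "Island"
    offset[i & isl] <- -runifInt(201, 600)[i & isl]
    offset[i & !isl] <- -runifInt(601, 1500)[i & !isl]
    i <- ctx == "FirstExon"
    offset[i] <- runifInt(0, 199)[i]
    i <- ctx == "UTR5"
    offset[i] <- runifInt(200, 349)[i]
    i <- ctx == "UTR3"
    offset[i] <- 30000L - runifInt(0, 299)[i]
    i <- ctx == "Body"
    offset[i & island_target == "Island"] <-
        runifInt(350, 800)[i & island_target == "Island"]
    offset[i & island_target == "Shore"] <-
        runifInt(801, 4800)[i & island_target == "Shore"]
    rest <- i & !(island_target %in% c("Island", "Shore"))
    offset[rest] <- runifInt(4801, 25000)[rest]
    tss + offset
}

#' Simulate a two-group methylation + expression dataset
#'
#' Generates a probe manifest (with genuine coordinates, a promoter CGI
#' per gene, and contexts re-derived from those coordinates), beta-value
#' and detection matrices for all samples, a coupled expression matrix,
#' the sample design, a gene-category annotation for enrichment demos,
#' and a truth table recording every planted effect.
#'
#' Null CpGs sit at one of the two bimodal modes (island CpGs at the
#' unmethylated mode; other CpGs methylated with probability 0.75).
#' CpGs carrying a planted effect are given a direction-appropriate
#' baseline (0.3 when gaining, 0.7 when losing methylation) so that the
#' shifted group mean stays inside (0, 1); a planted effect that would
#' leave (0.02, 0.98) raises an error before any sampling.
#'
#' @param config a [simConfig()].
#' @param plants list of [plantedGene()] / [plantInteractionGene()]
#'   specs; gene ids must exist in the simulated manifest.
#' @return a list of class "SimulatedDataset" with elements
#'   \code{manifest}, \code{islands}, \code{beta} (a
#'   \linkS4class{BetaSet}), \code{expr} (an \linkS4class{ExprSet}),
#'   \code{design}, \code{genes}, \code{categories}, \code{truth}
#'   (list \code{cpgs}, \code{genes}) and \code{config}.
#' @export
simulateDataset <- function(config = simConfig(), plants = list()) {
    stopifnot(inherits(config, "SimConfig"))
    for (p in plants) stopifnot(inherits(p, "PlantedGeneSpec"))
    seeds <- .stageSeeds(config$seed, 6L)
    genes <- .simGeneTable(config$n_genes)
    plant_ids <- vapply(plants, `[[`, character(1), "gene_id")
    if (anyDuplicated(plant_ids))
        stop("duplicate planted gene ids")
    bad <- setdiff(plant_ids, genes$gene_id)
    if (length(bad))
        stop("planted gene not in manifest: ", bad[1])
    plant_by_gene <- stats::setNames(plants, plant_ids)

    ## --- manifest -------------------------------------------------------
    set.seed(seeds[1])
    gene_ctx_mix <- c(TSS1500 = 0.13, TSS200 = 0.09, UTR5 = 0.09,
                      FirstExon = 0.09, Body = 0.50, UTR3 = 0.10)
    n_cpg <- config$cpgs_per_gene
    ctx_all <- character(config$n_genes * n_cpg)
    for (g in seq_len(config$n_genes)) {
        gid <- genes$gene_id[g]
        plant <- plant_by_gene[[gid]]
        if (is.null(plant)) {
            ctx <- sample(names(gene_ctx_mix), n_cpg, replace = TRUE,
                          prob = gene_ctx_mix)
        } else if (length(plant$effects) > 1) {
            ## both planted contexts populated, balanced enough for a
            ## full status x location design
            ctxs <- names(plant$effects)
            n1 <- max(4L, floor(n_cpg / 2))
            ctx <- c(rep(ctxs[1], n1), rep(ctxs[2], n_cpg - n1))
        } else {
            ctx <- rep(names(plant$effects), n_cpg)
        }
        ctx_all[((g - 1L) * n_cpg + 1L):(g * n_cpg)] <- ctx
    }
    gidx <- rep(seq_len(config$n_genes), each = n_cpg)
    isl_target <- sample(names(config$context_mix),
                         length(ctx_all), replace = TRUE,
                         prob = config$context_mix)
    pos <- .simCpGPositions(ctx_all, isl_target, genes$tss[gidx])
    man <- data.frame(
        probe_id = sprintf("cg%d_%02d", gidx,
                           rep(seq_len(n_cpg), config$n_genes)),
        chrom = genes$chrom[gidx], pos = as.integer(pos),
        gene_id = genes$gene_id[gidx],
        gene_links = paste(genes$transcript_id[gidx], ctx_all, sep = ":"),
        gene_context = ctx_all, is_cpg = TRUE, stringsAsFactors = FALSE)
    ## unlinked intergenic probes, far from any gene or CGI
    n_unl <- round(config$frac_unlinked * nrow(man))
    if (n_unl > 0) {
        man <- rbind(man, data.frame(
            probe_id = sprintf("cgU_%04d", seq_len(n_unl)),
            chrom = paste0("chr", sample(1:22, n_unl, replace = TRUE)),
            pos = as.integer(sample(1:5e5, n_unl, replace = TRUE)),
            gene_id = NA_character_, gene_links = "",
            gene_context = NA_character_, is_cpg = TRUE,
            stringsAsFactors = FALSE))
    }
    if (config$n_sex_probes > 0) {
        man <- rbind(man, data.frame(
            probe_id = sprintf("cgX_%03d", seq_len(config$n_sex_probes)),
            chrom = sample(c("chrX", "chrY"), config$n_sex_probes,
                           replace = TRUE),
            pos = as.integer(sample(1e5:1e6, config$n_sex_probes)),
            gene_id = NA_character_, gene_links = "",
            gene_context = NA_character_, is_cpg = TRUE,
            stringsAsFactors = FALSE))
    }
    if (config$n_noncpg_probes > 0) {
        man <- rbind(man, data.frame(
            probe_id = sprintf("chN_%03d", seq_len(config$n_noncpg_probes)),
            chrom = paste0("chr", sample(1:22, config$n_noncpg_probes,
                                         replace = TRUE)),
            pos = as.integer(sample(1:5e5, config$n_noncpg_probes)),
            gene_id = NA_character_, gene_links = "",
            gene_context = NA_character_, is_cpg = FALSE,
            stringsAsFactors = FALSE))
    }
    islands <- data.frame(chrom = genes$chrom,
                          start = genes$tss - 600L,
                          end = genes$tss + 800L,
                          stringsAsFactors = FALSE)
    man$island_context <- probeIslandContext(man$chrom, man$pos, islands)

    ## --- planted CpG effects -------------------------------------------
    man$effect <- 0
    man$baseline <- ifelse(man$island_context == "Island",
                           config$unmethylated_mode, NA)
    set.seed(seeds[2])
    meth_pick <- stats::runif(nrow(man)) < 0.75
    man$baseline[is.na(man$baseline)] <-
        ifelse(meth_pick[is.na(man$baseline)],
               config$methylated_mode, config$unmethylated_mode)
    for (plant in plants) {
        idx_gene <- which(man$gene_id %in% plant$gene_id)
        for (ctx in names(plant$effects)) {
            e <- plant$effects[[ctx]]
            if (e == 0) next
            idx <- idx_gene[man$gene_context[idx_gene] == ctx]
            if (length(idx) == 0)
                stop("gene ", plant$gene_id, " has no CpGs in context ", ctx)
            if (isTRUE(plant$both_directions)) {
                ## both directions within the context, status gap = |e|
                sgn <- rep_len(c(1, -1), length(idx)) * sign(e)
                man$effect[idx] <- sgn * abs(e)
            } else {
                man$effect[idx] <- e
            }
        }
    }
    ## planted CpGs start from a direction-appropriate baseline:
    ## sites gaining methylation start low, sites losing it start high
    planted_idx <- man$effect != 0
    man$baseline[planted_idx] <- 0.5 - 0.2 * sign(man$effect[planted_idx])
    m2 <- man$baseline + man$effect
    if (any(man$baseline < 0.02 | man$baseline > 0.98 |
            m2 < 0.02 | m2 > 0.98))
        stop("a planted effect pushes a group mean outside (0.02, 0.98)")

    ## --- design ---------------------------------------------------------
    spg <- config$samples_per_group
    design <- sampleDesign(
        sample_id = sprintf("S%02d", seq_len(2L * spg)),
        phenotype = rep(c("EIUM", "OSIS"), each = spg),
        treatment = "control")

    ## --- beta + detection ----------------------------------------------
    set.seed(seeds[3])
    grp2 <- design$phenotype == "OSIS"
    mu <- outer(man$baseline, rep(1, nrow(design))) +
        outer(man$effect, as.numeric(grp2))
    if (config$treatment_effect != 0) {
        ivd <- design$treatment == "IVD"
        mu <- mu + outer(rep(config$treatment_effect, nrow(man)),
                         as.numeric(ivd))
    }
    phi <- config$beta_precision
    beta <- matrix(stats::rbeta(length(mu), mu * phi, (1 - mu) * phi),
                   nrow = nrow(man),
                   dimnames = list(man$probe_id, design$sample_id))
    det <- matrix(stats::runif(length(mu), 0, 0.005), nrow = nrow(man),
                  dimnames = dimnames(beta))
    drop <- matrix(stats::runif(length(mu)) < config$detection_dropout_rate,
                   nrow = nrow(man))
    det[drop] <- stats::runif(sum(drop), 0.02, 1)

    ## --- expression -----------------------------------------------------
    set.seed(seeds[4])
    lfc <- stats::setNames(rep(0, config$n_genes), genes$gene_id)
    for (plant in plants) lfc[plant$gene_id] <- plant$logfc
    mu_e <- stats::rnorm(config$n_genes, 8, 1.2)
    ## one probe per transcript plus a duplicate probe for every 10th
    ## transcript and a handful of unmapped probes
    dup <- seq(10, config$n_genes, by = 10)
    probe_gene <- c(seq_len(config$n_genes), dup)
    expr_probes <- sprintf("ILMN_%05d", seq_along(probe_gene))
    latent <- outer(mu_e[probe_gene], rep(1, nrow(design))) +
        outer(lfc[probe_gene], as.numeric(grp2)) +
        matrix(stats::rnorm(length(probe_gene) * nrow(design), 0,
                            config$expr_noise_sd),
               nrow = length(probe_gene))
    n_unmapped <- 5L
    latent <- rbind(latent,
                    matrix(stats::rnorm(n_unmapped * nrow(design), 7, 1),
                           nrow = n_unmapped))
    expr <- 2^latent
    expr_ids <- c(expr_probes, sprintf("ILMN_U%02d", seq_len(n_unmapped)))
    dimnames(expr) <- list(expr_ids, design$sample_id)
    edet <- matrix(stats::runif(length(expr), 0, 0.005), nrow = nrow(expr),
                   dimnames = dimnames(expr))
    expr_row <- data.frame(
        probe_id = expr_ids,
        transcript_id = c(genes$transcript_id[probe_gene],
                          rep(NA_character_, n_unmapped)),
        gene_id = c(genes$gene_id[probe_gene],
                    rep(NA_character_, n_unmapped)),
        chrom = c(genes$chrom[probe_gene], rep("chr1", n_unmapped)),
        stringsAsFactors = FALSE)

    ## --- categories (for enrichment demos) ------------------------------
    set.seed(seeds[5])
    interaction_ids <- plant_ids[vapply(plants, `[[`, logical(1),
                                        "is_interaction_gene")]
    cat_pool <- c("Enzymes", "Receptors", "Kinases", "Other")
    category <- sample(cat_pool, config$n_genes, replace = TRUE,
                       prob = c(0.15, 0.1, 0.05, 0.7))
    category[genes$gene_id %in% interaction_ids] <- "Transcription factors"
    category[sample(config$n_genes, max(1L, round(0.04 * config$n_genes)))] <-
        "Transcription factors"
    categories <- data.frame(gene_id = genes$gene_id, category = category,
                             stringsAsFactors = FALSE)

    ## --- truth ----------------------------------------------------------
    truth_cpg <- data.frame(
        probe_id = man$probe_id,
        gene_id = man$gene_id,
        true_direction = ifelse(man$effect > 0, "hyper",
                                ifelse(man$effect < 0, "hypo", "null")),
        true_delta = man$effect, stringsAsFactors = FALSE)
    truth_gene <- data.frame(
        gene_id = genes$gene_id,
        true_de = lfc != 0, true_logfc = lfc,
        true_interaction = genes$gene_id %in% interaction_ids,
        correlation_sign = NA_character_, stringsAsFactors = FALSE)
    for (plant in plants)
        truth_gene$correlation_sign[truth_gene$gene_id == plant$gene_id] <-
            plant$correlation_sign

    manifest <- man[, c("probe_id", "chrom", "pos", "gene_links",
                        "island_context", "is_cpg")]
    rownames(manifest) <- NULL
    beta_set <- BetaSet(beta, det, rowData = manifest, colData = design)
    expr_set <- ExprSet(expr, edet, rowData = expr_row, colData = design)
    structure(list(manifest = manifest, islands = islands,
                   beta = beta_set, expr = expr_set, design = design,
                   genes = genes, categories = categories,
                   truth = list(cpgs = truth_cpg, genes = truth_gene),
                   config = config),
              class = "SimulatedDataset")
}

#' Emit two-color intensities for a simulated beta matrix
#'
#' Optional intensity layer: returns methylated/unmethylated channel
#' matrices such that \code{computeBeta(M, U, alpha)} reproduces the
#' simulated beta-values, for exercising the intensity-to-beta path.
#'
#' @param sim a "SimulatedDataset".
#' @param total per-cell total intensity M + U (default 10000).
#' @param alpha the beta-value offset (default 100).
#' @return list with matrices \code{M} and \code{U}.
#' @export
simulateIntensities <- function(sim, total = 10000, alpha = 100) {
    beta <- betaValues(sim$beta)
    M <- beta * (total + alpha)
    M <- pmin(pmax(M, 0), total)
    list(M = M, U = total - M)
}

#' Write a simulated dataset to disk
#'
#' Persists the manifest CSV, probes-by-samples beta and detection TSVs,
#' expression and expression-detection TSVs, the probe-to-transcript
#' map, the design CSV, the category map and the truth tables, in the
#' same dialects the pipeline readers consume.
#'
#' @param sim a "SimulatedDataset".
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeManifest(sim$manifest, file.path(dir, "manifest.csv"))
    .writeMatrixTSV(betaValues(sim$beta), file.path(dir, "beta.tsv"))
    .writeMatrixTSV(detectionP(sim$beta),
                    file.path(dir, "beta.detection.tsv"))
    .writeMatrixTSV(exprsValues(sim$expr), file.path(dir, "expr.tsv"))
    .writeMatrixTSV(detectionP(sim$expr),
                    file.path(dir, "expr.detection.tsv"))
    utils::write.csv(as.data.frame(rowData(sim$expr)),
                     file.path(dir, "expr_probes.csv"), row.names = FALSE)
    utils::write.csv(sim$design, file.path(dir, "design.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$categories, file.path(dir, "categories.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$truth$cpgs, file.path(dir, "truth_cpgs.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$truth$genes, file.path(dir, "truth_genes.csv"),
                     row.names = FALSE)
    invisible(dir)
}

.writeMatrixTSV <- function(m, path) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Read a probes-by-samples TSV written by [writeDataset()]
#'
#' @param path TSV path with a probe_id column and one column per sample.
#' @return numeric matrix with probe rownames.
#' @export
readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}
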