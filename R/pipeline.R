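#' Pipeline configuration
#'
#' Collects every threshold the integrated analysis uses, with the
#' study defaults: detection p < 0.01 presence rule, >= 5-of-6 present
#' per phenotype, delta-beta > 0.15 for differential methylation,
#' BH-adjusted p < 0.05 for differential expression and for the
#' interaction test, 4-kb shores.
#'
#' @param input directory holding a dataset written by [writeDataset()]
#'   (manifest.csv, beta.tsv, beta.detection.tsv, expr.tsv,
#'   expr.detection.tsv, expr_probes.csv, design.csv, categories.csv),
#'   or NULL to simulate from \code{seed}.
#' @param out_dir artifact directory.
#' @param det_p detection p-value presence threshold.
#' @param min_present minimum present samples per phenotype (NULL =
#'   ceiling(5/6 of the group size)).
#' @param delta_beta differential-methylation threshold (strict).
#' @param de_alpha adjusted-p threshold for differential expression.
#' @param anova_alpha adjusted-p threshold for the interaction test.
#' @param shore_bp shore half-width in bp.
#' @param case,control phenotype labels of the contrast (defaults:
#'   alphabetical order, first = control).
#' @param seed master seed used when simulating and logged in any case.
#' @param sim a [simConfig()] for simulated input (seed is overridden
#'   by \code{seed}).
#' @param plants planted effects for simulated input.
#' @return a validated list of class "PipelineConfig".
#' @export
pipelineConfig <- function(input = NULL, out_dir = tempfile("methylink_"),
                           det_p = 0.01, min_present = NULL,
                           delta_beta = 0.15, de_alpha = 0.05,
                           anova_alpha = 0.05, shore_bp = 4000,
                           case = NULL, control = NULL, seed = 1L,
                           sim = NULL, plants = list()) {
    stopifnot(det_p > 0, det_p < 1, delta_beta >= 0, delta_beta <= 1,
              de_alpha > 0, de_alpha < 1, anova_alpha > 0,
              anova_alpha < 1, shore_bp >= 0)
    if (is.null(sim)) sim <- simConfig(seed = seed)
    sim$seed <- as.integer(seed)
    structure(list(input = input, out_dir = out_dir, det_p = det_p,
                   min_present = min_present, delta_beta = delta_beta,
                   de_alpha = de_alpha, anova_alpha = anova_alpha,
                   shore_bp = shore_bp, case = case, control = control,
                   seed = as.integer(seed), sim = sim, plants = plants),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys are an
#' error. Nested \code{sim:} keys are passed to [simConfig()].
#'
#' @param path YAML file.
#' @return a "PipelineConfig".
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    sim <- NULL
    if (!is.null(y$sim)) {
        sim <- do.call(simConfig, y$sim)
        y$sim <- NULL
    }
    known <- setdiff(names(formals(pipelineConfig)), c("sim", "plants"))
    bad <- setdiff(names(y), known)
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(pipelineConfig, c(y, list(sim = sim)))
}

.stage <- function(log, name, n_in, n_out, t0, params = "") {
    rbind(log, data.frame(stage = name, n_in = n_in, n_out = n_out,
                          params = params,
                          seconds = round(as.numeric(Sys.time()) - t0, 3),
                          stringsAsFactors = FALSE))
}

#' Run the full integrated pipeline
#'
#' Executes preprocess -> differential expression -> differential
#' methylation -> CpG/transcript matching -> correlation classification
#' and context tables -> interaction analysis -> over-representation ->
#' report, persisting every stage's output as a CSV/TSV/JSON artifact
#' plus a structured run log. Empty intermediate results propagate as
#' valid empty tables. The run is deterministic given the config seed.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with every intermediate result and
#'   \code{run_log}.
#' @export
runAll <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- data.frame()
    t0 <- as.numeric(Sys.time())

    ## ---- inputs --------------------------------------------------------
    if (is.null(config$input)) {
        sim <- simulateDataset(config$sim, config$plants)
        manifest <- sim$manifest
        beta <- betaValues(sim$beta); bdet <- detectionP(sim$beta)
        expr <- exprsValues(sim$expr); edet <- detectionP(sim$expr)
        probe_map <- as.data.frame(rowData(sim$expr))
        design <- sim$design
        categories <- data.frame(gene_id = sim$categories$gene_id,
                                 category = sim$categories$category,
                                 stringsAsFactors = FALSE)
    } else {
        manifest <- readManifest(file.path(config$input, "manifest.csv"),
                                 shore_bp = config$shore_bp)
        beta <- readMatrixTSV(file.path(config$input, "beta.tsv"))
        bdet <- readMatrixTSV(file.path(config$input, "beta.detection.tsv"))
        expr <- readMatrixTSV(file.path(config$input, "expr.tsv"))
        edet <- readMatrixTSV(file.path(config$input, "expr.detection.tsv"))
        probe_map <- utils::read.csv(file.path(config$input,
                                               "expr_probes.csv"),
                                     stringsAsFactors = FALSE)
        design <- utils::read.csv(file.path(config$input, "design.csv"),
                                  stringsAsFactors = FALSE)
        cat_path <- file.path(config$input, "categories.csv")
        categories <- if (file.exists(cat_path))
            utils::read.csv(cat_path, stringsAsFactors = FALSE) else NULL
    }
    utils::write.csv(design, file.path(config$out_dir, "design.csv"),
                     row.names = FALSE)

    ## ---- methylation preprocessing ------------------------------------
    ts <- as.numeric(Sys.time())
    excl <- excludeProbes(manifest, c("sex_chromosomes", "non_cpg"))
    man_kept <- excl$records
    beta <- beta[man_kept$probe_id, , drop = FALSE]
    bdet <- bdet[man_kept$probe_id, , drop = FALSE]
    log <- .stage(log, "exclude_probes", nrow(manifest), nrow(man_kept), ts,
                  paste(names(excl$removed), excl$removed,
                        sep = "=", collapse = ";"))

    ts <- as.numeric(Sys.time())
    pf <- presenceFilter(bdet, design, p_threshold = config$det_p,
                         min_present = config$min_present)
    beta_f <- beta[pf$keep, , drop = FALSE]
    present_f <- pf$present[pf$keep, , drop = FALSE]
    man_f <- man_kept[pf$keep, , drop = FALSE]
    log <- .stage(log, "presence_filter", nrow(beta), nrow(beta_f), ts,
                  sprintf("det_p=%g", config$det_p))

    ## ---- expression ----------------------------------------------------
    ts <- as.numeric(Sys.time())
    expr_t <- quantileNormalize(vstExpression(expr))
    de <- callDE(expr_t, design, case = config$case,
                 control = config$control)
    de_tx <- collapseToTranscripts(de$table, probe_map)
    de_sig <- de_tx[de_tx$p_adj < config$de_alpha, , drop = FALSE]
    log <- .stage(log, "differential_expression", nrow(expr_t),
                  nrow(de_sig), ts,
                  sprintf("de_alpha=%g;d0=%.3g", config$de_alpha,
                          de$params$d0))
    utils::write.csv(de$table, file.path(config$out_dir, "de_results.csv"),
                     row.names = FALSE)
    utils::write.csv(de_tx, file.path(config$out_dir,
                                      "de_transcripts.csv"),
                     row.names = FALSE)

    ## ---- differential methylation -------------------------------------
    ts <- as.numeric(Sys.time())
    dm <- callDM(beta_f, design, delta = config$delta_beta,
                 present = present_f, case = config$case,
                 control = config$control)
    log <- .stage(log, "differential_methylation", nrow(beta_f),
                  nrow(dm), ts, sprintf("delta=%g", config$delta_beta))
    utils::write.csv(dm, file.path(config$out_dir, "dm_results.csv"),
                     row.names = FALSE)

    ## ---- matching + correlation ---------------------------------------
    ts <- as.numeric(Sys.time())
    pairs <- matchPairs(dm, de_sig$transcript_id, man_f)
    expr_by_tx <- expr_t[de_sig$probe_id, , drop = FALSE]
    rownames(expr_by_tx) <- de_sig$transcript_id
    pairs <- classifyPairs(pairs, beta_f, expr_by_tx,
                           present = present_f)
    log <- .stage(log, "match_pairs", nrow(dm), nrow(pairs), ts)
    utils::write.csv(pairs, file.path(config$out_dir,
                                      "matched_pairs.csv"),
                     row.names = FALSE)

    tab_gene <- tabulateByContext(pairs, "gene")
    tab_isl <- tabulateByContext(pairs, "island")
    utils::write.csv(tab_gene,
                     file.path(config$out_dir, "table_gene_context.csv"),
                     row.names = FALSE)
    utils::write.csv(tab_isl,
                     file.path(config$out_dir, "table_island_context.csv"),
                     row.names = FALSE)

    ## ---- interaction ---------------------------------------------------
    ts <- as.numeric(Sys.time())
    inter <- runInteractionAnalysis(pairs, beta_f,
                                    alpha = config$anova_alpha,
                                    present = present_f)
    n_sig <- sum(inter$significant, na.rm = TRUE)
    log <- .stage(log, "interaction", length(unique(pairs$transcript_id)),
                  n_sig, ts, sprintf("anova_alpha=%g", config$anova_alpha))
    utils::write.csv(inter, file.path(config$out_dir,
                                      "interaction_results.csv"),
                     row.names = FALSE)

    ## ---- enrichment ----------------------------------------------------
    enrich <- data.frame()
    if (!is.null(categories) && n_sig > 0) {
        ts <- as.numeric(Sys.time())
        sig_tx <- inter$gene_id[which(inter$significant)]
        gid <- probe_map$gene_id[match(sig_tx, probe_map$transcript_id)]
        gid <- unique(gid[!is.na(gid)])
        if (length(gid) > 0)
            enrich <- ora(gid, categories)
        log <- .stage(log, "enrichment", length(gid), nrow(enrich), ts)
    }
    utils::write.csv(enrich, file.path(config$out_dir, "enrichment.csv"),
                     row.names = FALSE)

    ## ---- report --------------------------------------------------------
    ts <- as.numeric(Sys.time())
    pca_m <- pcaSummary(beta_f)
    pca_e <- pcaSummary(expr_t)
    pca_df <- rbind(
        data.frame(platform = "methylation",
                   component = seq_along(pca_m$variance_fraction),
                   variance_fraction = pca_m$variance_fraction),
        data.frame(platform = "expression",
                   component = seq_along(pca_e$variance_fraction),
                   variance_fraction = pca_e$variance_fraction))
    utils::write.csv(pca_df, file.path(config$out_dir, "pca.csv"),
                     row.names = FALSE)
    dens <- betaDensity(beta_f)
    utils::write.csv(dens, file.path(config$out_dir, "density.csv"),
                     row.names = FALSE)
    counts <- dmScatterCounts(dm)
    jsonlite::write_json(counts, file.path(config$out_dir,
                                           "scatter_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    hm <- heatmapTable(pairs, beta_f)
    utils::write.csv(hm, file.path(config$out_dir, "heatmap.csv"),
                     row.names = FALSE)
    tree <- clusterSamples(beta_f)
    jsonlite::write_json(tree, file.path(config$out_dir, "tree.json"),
                         digits = NA)
    log <- .stage(log, "report", nrow(beta_f), nrow(pca_df), ts)

    log <- .stage(log, "total", nrow(manifest), n_sig, t0,
                  sprintf("seed=%d", config$seed))
    utils::write.csv(log, file.path(config$out_dir, "run_log.csv"),
                     row.names = FALSE)
    invisible(list(manifest = man_f, beta = beta_f, present = present_f,
                   expr = expr_t, de = de, de_transcripts = de_tx,
                   de_significant = de_sig, dm = dm, pairs = pairs,
                   table_gene = tab_gene, table_island = tab_isl,
                   interaction = inter, enrichment = enrich,
                   pca = pca_df, scatter_counts = counts,
                   run_log = log, config = config))
}
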