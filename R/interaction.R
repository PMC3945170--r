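#' Status-by-location ANOVA interaction F-test
#'
#' The core prioritization statistic: observations are per-(CpG, sample)
#' beta-values for the differentially methylated CpGs linked to one
#' gene; factors are the CpG's methylation status (hypo/hyper) and its
#' location (gene context or island context). The full model
#' \code{beta ~ status + location + status:location} is compared with
#' the additive model by extra sum of squares:
#' \code{F = [(SSE_add - SSE_full) / ddf] / [SSE_full / df_resid]},
#' where \code{ddf} is the rank difference of the two design matrices —
#' well-defined for unbalanced and empty-cell designs.
#'
#' Untestable patterns return NA with a reason: a single observed
#' status or location level ("single_factor_level"), an interaction of
#' rank zero, i.e. cell means already explained by the additive model
#' structure ("interaction_inestimable"), or no residual degrees of
#' freedom ("no_residual_df"). A saturated perfect fit (SSE_full = 0
#' with interaction signal) yields F = Inf, p = 0.
#'
#' @param beta numeric vector of observations (beta-values).
#' @param status factor-like, the CpG status per observation.
#' @param location factor-like, the CpG location per observation.
#' @return list with F, df1, df2, p, and untestable_reason ("" when
#'   testable).
#' @export
interactionAnova <- function(beta, status, location) {
    stopifnot(length(beta) == length(status),
              length(beta) == length(location))
    ok <- is.finite(beta)
    beta <- beta[ok]
    status <- droplevels(factor(status[ok]))
    location <- droplevels(factor(location[ok]))
    bad <- function(reason) list(F = NA_real_, df1 = NA_real_,
                                 df2 = NA_real_, p = NA_real_,
                                 untestable_reason = reason)
    if (nlevels(status) < 2 || nlevels(location) < 2)
        return(bad("single_factor_level"))
    X_full <- stats::model.matrix(~ status * location)
    X_add <- stats::model.matrix(~ status + location)
    fit_full <- .lsFit(X_full, beta)
    fit_add <- .lsFit(X_add, beta)
    ddf <- fit_full$rank - fit_add$rank
    if (ddf < 1) return(bad("interaction_inestimable"))
    df_resid <- length(beta) - fit_full$rank
    if (df_resid < 1) return(bad("no_residual_df"))
    ss_int <- fit_add$sse - fit_full$sse
    if (fit_full$sse <= 1e-12 * max(1, fit_add$sse)) {
        if (ss_int <= 1e-12) return(bad("interaction_inestimable"))
        return(list(F = Inf, df1 = ddf, df2 = df_resid, p = 0,
                    untestable_reason = ""))
    }
    Fstat <- (ss_int / ddf) / (fit_full$sse / df_resid)
    Fstat <- max(Fstat, 0)
    list(F = Fstat, df1 = ddf, df2 = df_resid,
         p = stats::pf(Fstat, ddf, df_resid, lower.tail = FALSE),
         untestable_reason = "")
}

# Rank and residual sum of squares of a least-squares fit via QR with
# column pivoting (handles rank deficiency).
.lsFit <- function(X, y) {
    qr_ <- qr(X)
    fit <- qr.fitted(qr_, y)
    list(rank = qr_$rank, sse = sum((y - fit)^2))
}

#' Per-gene interaction analysis over both location taxonomies
#'
#' For every gene with matched differentially methylated CpGs, pools
#' the per-(CpG, sample) beta-values of those CpGs and runs
#' [interactionAnova()] twice: once with gene-context locations and
#' once with island-context locations. Each taxonomy's p-values are
#' BH-adjusted as a separate family over the testable genes; a gene is
#' significant when either adjusted p falls below \code{alpha}. The
#' reported \code{p_min} is the smaller of the two raw p-values.
#'
#' Only differentially methylated CpGs contribute observations (status
#' is undefined for the rest); genes with fewer than 2 matched CpGs are
#' untestable.
#'
#' @param pairs classified or unclassified matched pairs
#'   ([matchPairs()]): cpg_id, transcript_id, direction, gene_context,
#'   island_context.
#' @param beta beta matrix or \linkS4class{BetaSet} containing the
#'   matched CpGs (all samples).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param present optional presence mask; non-present cells are dropped
#'   from the observations.
#' @return data.frame with one row per gene (transcript): gene_id,
#'   n_cpgs, p_gene_ctx, p_island_ctx, p_min, p_adj_gene_ctx,
#'   p_adj_island_ctx, significant, untestable_reason.
#' @export
runInteractionAnalysis <- function(pairs, beta, alpha = 0.05,
                                   present = NULL) {
    if (is(beta, "BetaSet")) beta <- betaValues(beta)
    genes <- unique(pairs$transcript_id)
    if (length(genes) == 0)
        return(data.frame(gene_id = character(), n_cpgs = integer(),
                          p_gene_ctx = numeric(), p_island_ctx = numeric(),
                          untestable_reason = character(),
                          p_min = numeric(), p_adj_gene_ctx = numeric(),
                          p_adj_island_ctx = numeric(),
                          significant = logical(),
                          stringsAsFactors = FALSE))
    res <- lapply(genes, function(g) {
        sub <- pairs[pairs$transcript_id == g, , drop = FALSE]
        sub <- sub[!duplicated(sub$cpg_id), , drop = FALSE]
        n_cpg <- nrow(sub)
        row <- data.frame(gene_id = g, n_cpgs = n_cpg,
                          p_gene_ctx = NA_real_, p_island_ctx = NA_real_,
                          untestable_reason = "", stringsAsFactors = FALSE)
        if (n_cpg < 2) {
            row$untestable_reason <- "fewer_than_2_cpgs"
            return(row)
        }
        b <- beta[sub$cpg_id, , drop = FALSE]
        if (!is.null(present)) b[!present[sub$cpg_id, ]] <- NA
        ns <- ncol(b)
        obs <- as.vector(t(b))
        status <- rep(sub$direction, each = ns)
        a1 <- interactionAnova(obs, status, rep(sub$gene_context, each = ns))
        a2 <- interactionAnova(obs, status, rep(sub$island_context, each = ns))
        row$p_gene_ctx <- a1$p
        row$p_island_ctx <- a2$p
        if (a1$untestable_reason != "" && a2$untestable_reason != "")
            row$untestable_reason <- a1$untestable_reason
        row
    })
    out <- do.call(rbind, res)
    out$p_min <- pmin(out$p_gene_ctx, out$p_island_ctx, na.rm = TRUE)
    out$p_min[is.na(out$p_gene_ctx) & is.na(out$p_island_ctx)] <- NA
    out$p_adj_gene_ctx <- NA_real_
    out$p_adj_island_ctx <- NA_real_
    t1 <- !is.na(out$p_gene_ctx)
    t2 <- !is.na(out$p_island_ctx)
    out$p_adj_gene_ctx[t1] <- bhAdjust(out$p_gene_ctx[t1])
    out$p_adj_island_ctx[t2] <- bhAdjust(out$p_island_ctx[t2])
    out$significant <- (!is.na(out$p_adj_gene_ctx) &
                        out$p_adj_gene_ctx < alpha) |
                       (!is.na(out$p_adj_island_ctx) &
                        out$p_adj_island_ctx < alpha)
    rownames(out) <- NULL
    out
}
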