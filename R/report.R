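#' PCA summary of a features-by-samples matrix
#'
#' Centers each feature, then eigendecomposes the sample covariance:
#' the variance fractions are the eigenvalue shares and sample
#' coordinates are returned for the first two components. A constant
#' matrix yields all-zero fractions.
#'
#' @param x numeric matrix, features x samples.
#' @return list with \code{variance_fraction} (one per component) and
#'   \code{coords} (data.frame sample, PC1, PC2).
#' @export
pcaSummary <- function(x) {
    x <- as.matrix(x)
    stopifnot(ncol(x) >= 2)
    pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    tot <- sum(v)
    frac <- if (tot == 0) rep(0, length(v)) else v / tot
    if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
    coords <- data.frame(sample = colnames(x),
                         PC1 = pc$x[, 1],
                         PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0,
                         row.names = NULL, stringsAsFactors = FALSE)
    list(variance_fraction = frac, coords = coords)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns (Euclidean distance,
#' average linkage by default). Ties are resolved deterministically by
#' \code{stats::hclust}'s ordering, so the tree depends only on input
#' order.
#'
#' @param x features x samples matrix.
#' @param metric distance metric for \code{stats::dist}.
#' @param linkage linkage for \code{stats::hclust} (default "average").
#' @return list with \code{merge}, \code{height}, \code{order},
#'   \code{labels} (the hclust components).
#' @export
clusterSamples <- function(x, metric = "euclidean", linkage = "average") {
    x <- as.matrix(x)
    stopifnot(ncol(x) >= 2)
    hc <- stats::hclust(stats::dist(t(x), method = metric),
                        method = linkage)
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels)
}

#' Per-sample beta-value density on a fixed grid
#'
#' Gaussian-kernel density of each sample's beta-values evaluated on
#' the grid 0, 0.005, ..., 1. With array-like bimodal data this shows
#' the characteristic unmethylated and methylated modes.
#'
#' @param beta beta matrix or \linkS4class{BetaSet}.
#' @param bandwidth kernel bandwidth; NULL uses "nrd0" per sample.
#' @return long data.frame (sample, beta, density).
#' @export
betaDensity <- function(beta, bandwidth = NULL) {
    if (is(beta, "BetaSet")) beta <- betaValues(beta)
    if (!is.null(bandwidth) && bandwidth <= 0)
        stop("bandwidth must be positive")
    grid_n <- 201L
    out <- lapply(colnames(beta), function(s) {
        v <- beta[, s]
        v <- v[is.finite(v)]
        d <- stats::density(v, bw = if (is.null(bandwidth)) "nrd0"
                                    else bandwidth,
                            from = 0, to = 1, n = grid_n)
        data.frame(sample = s, beta = d$x, density = d$y,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Hyper/hypo counts of a DM call set
#'
#' @param dm DM table from [callDM()].
#' @return list with n_hyper, n_hypo and hyper_fraction (NA when there
#'   are no calls).
#' @export
dmScatterCounts <- function(dm) {
    n_hyper <- sum(dm$direction == "hyper")
    n_hypo <- sum(dm$direction == "hypo")
    tot <- n_hyper + n_hypo
    list(n_hyper = n_hyper, n_hypo = n_hypo,
         hyper_fraction = if (tot == 0) NA_real_ else n_hyper / tot)
}

#' Plot-ready heat-map table of matched CpGs
#'
#' Per-CpG beta rows for the matched CpGs, ordered by delta-beta, with
#' the context columns appended — the tabular form of the combined
#' methylation/context heat map.
#'
#' @param pairs matched pairs ([matchPairs()]).
#' @param beta beta matrix or \linkS4class{BetaSet}.
#' @return data.frame: cpg_id, delta_beta, direction, gene_context,
#'   island_context, then one column per sample.
#' @export
heatmapTable <- function(pairs, beta) {
    if (is(beta, "BetaSet")) beta <- betaValues(beta)
    u <- pairs[!duplicated(pairs$cpg_id), , drop = FALSE]
    u <- u[order(u$delta_beta), , drop = FALSE]
    cbind(u[, c("cpg_id", "delta_beta", "direction", "gene_context",
                "island_context")],
          as.data.frame(beta[u$cpg_id, , drop = FALSE],
                        stringsAsFactors = FALSE),
          row.names = NULL)
}
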