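#' Variance-stabilizing transform for expression intensities
#'
#' Applies a monotone per-sample transform to raw nonnegative bead
#' intensities: \code{log2(x + offset)} (default, offset 1) or
#' \code{asinh(x)}, which is log-linear for large intensities.
#'
#' @param x matrix of nonnegative intensities (or an
#'   \linkS4class{ExprSet}, in which case the "exprs" assay is
#'   transformed in place).
#' @param method "log2_offset" or "arcsinh".
#' @param offset additive offset for the log2 method.
#' @return transformed matrix (or ExprSet).
#' @export
vstExpression <- function(x, method = c("log2_offset", "arcsinh"),
                          offset = 1) {
    method <- match.arg(method)
    if (is(x, "ExprSet")) {
        m <- vstExpression(exprsValues(x), method, offset)
        SummarizedExperiment::assay(x, "exprs") <- m
        return(x)
    }
    x <- as.matrix(x)
    if (any(x < 0, na.rm = TRUE))
        stop("negative intensities cannot be variance-stabilized")
    switch(method,
           log2_offset = log2(x + offset),
           arcsinh = asinh(x))
}

#' Quantile-normalize a matrix across samples
#'
#' Forces every sample (column) onto the common distribution given by
#' the across-sample mean of sorted values, preserving within-sample
#' rank order; tied values receive the average of the quantiles they
#' span. A single-column matrix is returned unchanged. The heavy
#' lifting is done by \code{limma::normalizeQuantiles} with tie
#' averaging.
#'
#' @param x numeric matrix (no missing cells).
#' @return matrix of the same shape and dimnames.
#' @export
quantileNormalize <- function(x) {
    x <- as.matrix(x)
    if (anyNA(x)) stop("quantileNormalize expects a complete matrix")
    if (ncol(x) <= 1L) return(x)
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
}

#' Convert channel intensities to beta-values
#'
#' The standard array convention: \code{beta = M / (M + U + alpha)},
#' which lies in \code{[0, 1)} for nonnegative intensities; the offset
#' alpha regularizes low-intensity probes.
#'
#' @param m methylated-channel intensities (vector or matrix).
#' @param u unmethylated-channel intensities, same shape.
#' @param alpha offset (default 100).
#' @return beta-values, same shape as the inputs.
#' @export
computeBeta <- function(m, u, alpha = 100) {
    stopifnot(all(m >= 0, na.rm = TRUE), all(u >= 0, na.rm = TRUE))
    m / (m + u + alpha)
}

#' Presence filter on detection p-values
#'
#' A probe is "present" in a sample when its detection p-value is below
#' \code{p_threshold}; a probe is retained only when it is present in at
#' least \code{min_present} samples within each phenotype (with 6
#' samples per phenotype the default discards probes present in 4 or
#' fewer of either group). Group summaries downstream use present
#' samples only.
#'
#' @param detection matrix of detection p-values (probes x samples).
#' @param design sample design data.frame ([sampleDesign()]); samples
#'   must match the detection columns.
#' @param p_threshold presence threshold on the detection p (default 0.01).
#' @param min_present minimum present samples per phenotype; default
#'   \code{ceiling(5/6 * group size)} per group.
#' @return list with \code{keep} (logical per probe), \code{present}
#'   (logical matrix) and \code{counts} (probes x phenotypes present
#'   counts).
#' @export
presenceFilter <- function(detection, design, p_threshold = 0.01,
                           min_present = NULL) {
    detection <- as.matrix(detection)
    stopifnot(ncol(detection) == nrow(design))
    phen <- design$phenotype
    sizes <- table(phen)
    if (is.null(min_present)) {
        minp <- ceiling(5 / 6 * as.numeric(sizes))
        names(minp) <- names(sizes)
    } else {
        minp <- stats::setNames(rep(min_present, length(sizes)),
                                names(sizes))
        if (any(as.numeric(sizes) < minp))
            stop("min_present exceeds a phenotype's sample count")
    }
    present <- detection < p_threshold
    counts <- vapply(names(sizes), function(g)
        rowSums(present[, phen == g, drop = FALSE]),
        numeric(nrow(detection)))
    keep <- rowSums(sweep(counts, 2, minp[colnames(counts)], `>=`)) ==
        ncol(counts)
    list(keep = keep, present = present, counts = counts)
}
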