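#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

.CONTEXT_GENE <- c("TSS1500", "TSS200", "UTR5", "FirstExon", "Body", "UTR3")
.CONTEXT_ISLAND <- c("Island", "Shore", "OpenSea")

#' BetaSet: probes-by-samples methylation fractions
#'
#' A \linkS4class{SummarizedExperiment} holding a matrix of beta-values
#' (methylation fractions in \code{[0, 1]}) in assay \code{"beta"}, a
#' parallel matrix of detection p-values in assay \code{"detection"},
#' probe annotation (position, gene links, island context) as
#' \code{rowData}, and the sample design (phenotype, treatment) as
#' \code{colData}.
#'
#' Beta-values follow the usual array convention: 0 is unmethylated and
#' 1 fully methylated, computed from methylated/unmethylated channel
#' intensities as \code{M / (M + U + alpha)}.
#'
#' @seealso [BetaSet()], [computeBeta()], [presenceFilter()]
#' @exportClass BetaSet
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- character()
    if (!all(c("beta", "detection") %in% assayNames(object)))
        msg <- c(msg, "assays 'beta' and 'detection' are required")
    else {
        b <- assay(object, "beta")
        d <- assay(object, "detection")
        if (!all(is.na(b) | (b >= 0 & b <= 1)))
            msg <- c(msg, "beta-values must lie in [0, 1]")
        if (!all(is.na(d) | (d >= 0 & d <= 1)))
            msg <- c(msg, "detection p-values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' ExprSet: probes-by-samples expression intensities
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"exprs"}
#' (nonnegative intensities, or transformed values after
#' [vstExpression()]) and assay \code{"detection"} (per-cell detection
#' p-values). \code{rowData} carries the probe-to-transcript map in
#' column \code{transcript_id}; \code{colData} carries the sample design.
#'
#' @seealso [ExprSet()], [vstExpression()], [fitTwoGroup()]
#' @exportClass ExprSet
setClass("ExprSet", contains = "SummarizedExperiment")

setValidity("ExprSet", function(object) {
    msg <- character()
    if (!all(c("exprs", "detection") %in% assayNames(object)))
        msg <- c(msg, "assays 'exprs' and 'detection' are required")
    else {
        x <- assay(object, "exprs")
        if (any(!is.finite(x[!is.na(x)])))
            msg <- c(msg, "expression values must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix of beta-values, probes x samples.
#' @param detection numeric matrix of detection p-values, same shape.
#' @param rowData probe annotation (a data.frame or DataFrame); typically
#'   the manifest rows for these probes, see [readManifest()].
#' @param colData sample design with columns \code{sample_id},
#'   \code{phenotype}, \code{treatment}; see [sampleDesign()].
#' @return a \linkS4class{BetaSet}.
#' @examples
#' b <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("cg", 1:3), paste0("S", 1:4)))
#' d <- matrix(0, 3, 4, dimnames = dimnames(b))
#' bs <- BetaSet(b, d)
#' dim(bs)
#' @export
BetaSet <- function(beta, detection = NULL, rowData = NULL, colData = NULL) {
    beta <- as.matrix(beta)
    if (is.null(detection))
        detection <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
    detection <- as.matrix(detection)
    stopifnot(identical(dim(beta), dim(detection)))
    args <- list(assays = list(beta = beta, detection = detection))
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- DataFrame(colData)
    se <- do.call(SummarizedExperiment, args)
    new("BetaSet", se)
}

#' Construct an ExprSet
#'
#' @param exprs numeric matrix of intensities or transformed expression
#'   values, probes x samples.
#' @param detection matrix of detection p-values (defaults to all zero,
#'   i.e. every cell detected).
#' @param rowData probe annotation; column \code{transcript_id} maps each
#'   probe to a transcript accession (NA for unmapped probes).
#' @param colData sample design, see [sampleDesign()].
#' @return an \linkS4class{ExprSet}.
#' @export
ExprSet <- function(exprs, detection = NULL, rowData = NULL, colData = NULL) {
    exprs <- as.matrix(exprs)
    if (is.null(detection))
        detection <- matrix(0, nrow(exprs), ncol(exprs), dimnames = dimnames(exprs))
    detection <- as.matrix(detection)
    stopifnot(identical(dim(exprs), dim(detection)))
    args <- list(assays = list(exprs = exprs, detection = detection))
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- DataFrame(colData)
    se <- do.call(SummarizedExperiment, args)
    new("ExprSet", se)
}

#' Sample design table
#'
#' Validates and returns the study design: one row per array sample with
#' its phenotype (e.g. control vs disease stromal cells) and hormonal
#' treatment arm.
#'
#' @param sample_id unique sample identifiers.
#' @param phenotype factor-like, two or more levels (e.g. "EIUM",
#'   "OSIS").
#' @param treatment factor-like (e.g. "control", "IVD"); defaults to
#'   "control" for all samples.
#' @return a data.frame with columns sample_id, phenotype, treatment.
#' @export
sampleDesign <- function(sample_id, phenotype, treatment = NULL) {
    sample_id <- as.character(sample_id)
    if (anyDuplicated(sample_id))
        stop("sample ids must be unique")
    phenotype <- as.character(phenotype)
    if (is.null(treatment)) treatment <- "control"
    if (length(treatment) == 1L)
        treatment <- rep(treatment, length(sample_id))
    stopifnot(length(phenotype) == length(sample_id),
              length(treatment) == length(sample_id))
    tab <- table(phenotype)
    if (any(tab < 2))
        stop("each phenotype needs at least 2 samples")
    data.frame(sample_id = sample_id, phenotype = phenotype,
               treatment = as.character(treatment),
               stringsAsFactors = FALSE)
}

setMethod("show", "BetaSet", function(object) {
    cat("BetaSet:", nrow(object), "probes x", ncol(object), "samples\n")
    b <- assay(object, "beta")
    cat("  beta range:", sprintf("%.3f-%.3f", min(b, na.rm = TRUE),
                                 max(b, na.rm = TRUE)), "\n")
    if ("phenotype" %in% colnames(colData(object))) {
        tab <- table(colData(object)$phenotype)
        cat("  phenotypes:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    invisible(NULL)
})

setMethod("show", "ExprSet", function(object) {
    cat("ExprSet:", nrow(object), "probes x", ncol(object), "samples\n")
    if ("transcript_id" %in% colnames(rowData(object)))
        cat("  mapped probes:",
            sum(!is.na(rowData(object)$transcript_id)), "\n")
    invisible(NULL)
})
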