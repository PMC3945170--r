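#' Match differentially methylated CpGs to differentially expressed
#' transcripts
#'
#' Uses the manifest gene links to pair every differentially methylated
#' CpG with each differentially expressed transcript it is linked to;
#' each (CpG, transcript) link is one pair, so a CpG linked to two DE
#' transcripts yields two pairs. Contexts are carried from the manifest.
#'
#' @param dm DM table from [callDM()].
#' @param de_transcripts character vector of differentially expressed
#'   transcript ids (e.g. from [collapseToTranscripts()] at
#'   \code{p_adj < 0.05}).
#' @param manifest manifest data.frame ([readManifest()]).
#' @return data.frame with cpg_id, transcript_id, direction,
#'   delta_beta, gene_context, island_context.
#' @export
matchPairs <- function(dm, de_transcripts, manifest) {
    links <- parseGeneLinks(manifest$probe_id, manifest$gene_links)
    links <- links[links$transcript_id %in% de_transcripts, , drop = FALSE]
    merged <- merge(dm, links, by.x = "probe_id", by.y = "probe_id")
    if (nrow(merged) == 0)
        return(data.frame(cpg_id = character(), transcript_id = character(),
                          direction = character(), delta_beta = numeric(),
                          gene_context = character(),
                          island_context = character(),
                          stringsAsFactors = FALSE))
    isl <- manifest$island_context[match(merged$probe_id,
                                         manifest$probe_id)]
    out <- data.frame(cpg_id = merged$probe_id,
                      transcript_id = merged$transcript_id,
                      direction = merged$direction,
                      delta_beta = merged$delta_beta,
                      gene_context = merged$gene_context,
                      island_context = isl, stringsAsFactors = FALSE)
    out[order(out$cpg_id, out$transcript_id), , drop = FALSE]
}

#' Spearman correlation class of a matched pair
#'
#' Computes the Spearman rank correlation (average ranks for ties)
#' between a CpG's beta-values and its transcript's expression across
#' samples, after dropping (pairwise) samples where either value is
#' missing or masked non-present. The pair is classified by the sign of
#' rho; rho = 0 or an undefined rho (constant series, < 3 paired
#' observations) is "excluded".
#'
#' @param beta_row numeric vector of beta-values across samples.
#' @param expr_row numeric vector of expression values, same samples.
#' @return list with \code{rho} and \code{corr_class} in
#'   c("positive", "negative", "excluded").
#' @export
classifyCorrelation <- function(beta_row, expr_row) {
    stopifnot(length(beta_row) == length(expr_row))
    ok <- is.finite(beta_row) & is.finite(expr_row)
    if (sum(ok) < 3)
        return(list(rho = NA_real_, corr_class = "excluded"))
    x <- beta_row[ok]; y <- expr_row[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(rho = NA_real_, corr_class = "excluded"))
    rho <- stats::cor(x, y, method = "spearman")
    cls <- if (is.na(rho) || rho == 0) "excluded"
           else if (rho > 0) "positive" else "negative"
    list(rho = rho, corr_class = cls)
}

#' Classify all matched pairs
#'
#' Vectorizes [classifyCorrelation()] over a matched-pair table.
#'
#' @param pairs matched pairs from [matchPairs()].
#' @param beta beta matrix (rows = CpGs) or \linkS4class{BetaSet}.
#' @param expr_by_transcript matrix of expression values with rownames
#'   = transcript ids (one row per DE transcript, e.g. the collapsed
#'   probe's row).
#' @param present optional presence mask for the beta matrix.
#' @return the pairs table with rho and corr_class columns appended.
#' @export
classifyPairs <- function(pairs, beta, expr_by_transcript, present = NULL) {
    if (is(beta, "BetaSet")) beta <- betaValues(beta)
    rho <- numeric(nrow(pairs))
    cls <- character(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        b <- beta[pairs$cpg_id[i], ]
        if (!is.null(present)) b[!present[pairs$cpg_id[i], ]] <- NA
        e <- expr_by_transcript[pairs$transcript_id[i], ]
        cc <- classifyCorrelation(b, e)
        rho[i] <- cc$rho
        cls[i] <- cc$corr_class
    }
    pairs$rho <- rho
    pairs$corr_class <- cls
    pairs
}

#' One-sample two-tailed test of a stratum proportion
#'
#' Tests whether a stratum's negative-correlation fraction equals the
#' fixed overall fraction p0, with the plain normal approximation
#' (no continuity correction): \code{z = (phat - p0) /
#' sqrt(p0 (1 - p0) / n)}, \code{p = 2 pnorm(-|z|)}. Alternatives:
#' "wald" uses \code{phat} in the standard error; "binom" is the exact
#' two-sided binomial test.
#'
#' @param n_neg negative-correlated pairs in the stratum.
#' @param n_total classified pairs in the stratum (pos + neg).
#' @param p0 overall negative fraction to test against.
#' @param method "score" (default), "wald" or "binom".
#' @return list with z and p.
#' @export
proportionTest <- function(n_neg, n_total, p0,
                           method = c("score", "wald", "binom")) {
    method <- match.arg(method)
    stopifnot(n_total >= 1, n_neg >= 0, n_neg <= n_total)
    phat <- n_neg / n_total
    if (p0 <= 0 || p0 >= 1) {
        if (phat == p0) return(list(z = 0, p = 1))
        return(list(z = Inf * sign(phat - p0), p = 0))
    }
    if (method == "binom") {
        p <- stats::binom.test(n_neg, n_total, p = p0)$p.value
        z <- (phat - p0) / sqrt(p0 * (1 - p0) / n_total)
        return(list(z = z, p = p))
    }
    se <- if (method == "score") sqrt(p0 * (1 - p0) / n_total)
          else sqrt(phat * (1 - phat) / n_total)
    if (se == 0) return(list(z = ifelse(phat == p0, 0, Inf), p = 0))
    z <- (phat - p0) / se
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Tabulate correlation classes by context
#'
#' Builds the per-stratum cross-tabulation of positively and negatively
#' correlated matched CpGs (excluded pairs dropped), the neg/pos ratio,
#' and the two-tailed test of each stratum's proportion against the
#' overall proportion. The overall row is included with z = 0, p = 1.
#'
#' @param pairs classified pairs ([classifyPairs()]), or any data.frame
#'   with corr_class and the stratification column.
#' @param stratify "gene" (gene_context) or "island" (island_context).
#' @param method proportion-test flavor, see [proportionTest()].
#' @return data.frame with stratum, n_total, n_pos, n_neg,
#'   ratio_neg_pos, z, p. A stratum with no positive pairs reports an
#'   infinite ratio.
#' @export
tabulateByContext <- function(pairs, stratify = c("gene", "island"),
                              method = "score") {
    stratify <- match.arg(stratify)
    col <- if (stratify == "gene") "gene_context" else "island_context"
    pairs <- pairs[pairs$corr_class %in% c("positive", "negative"), ,
                   drop = FALSE]
    levels <- if (stratify == "gene") .CONTEXT_GENE else .CONTEXT_ISLAND
    counts <- lapply(levels, function(s) {
        sub <- pairs[pairs[[col]] == s, , drop = FALSE]
        c(pos = sum(sub$corr_class == "positive"),
          neg = sum(sub$corr_class == "negative"))
    })
    counts <- do.call(rbind, counts)
    rownames(counts) <- levels
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    overall <- c(pos = sum(pairs$corr_class == "positive"),
                 neg = sum(pairs$corr_class == "negative"))
    proportionTable(counts, overall, method = method)
}

#' Proportion table from explicit counts
#'
#' The arithmetic core behind [tabulateByContext()]: given per-stratum
#' (positive, negative) counts and the overall counts, computes the
#' neg/pos ratio and the two-tailed proportion test per stratum, plus
#' the overall row.
#'
#' @param counts matrix or data.frame with columns pos, neg, one row per
#'   stratum (rownames = stratum labels).
#' @param overall length-2 vector c(pos=, neg=); defaults to the column
#'   sums of counts.
#' @param method proportion-test flavor, see [proportionTest()].
#' @return data.frame with stratum, n_total, n_pos, n_neg,
#'   ratio_neg_pos, z, p (overall row last).
#' @export
proportionTable <- function(counts, overall = NULL, method = "score") {
    counts <- as.matrix(counts)
    stopifnot(all(c("pos", "neg") %in% colnames(counts)))
    if (is.null(overall))
        overall <- c(pos = sum(counts[, "pos"]), neg = sum(counts[, "neg"]))
    p0 <- unname(overall["neg"] / (overall["pos"] + overall["neg"]))
    rows <- lapply(rownames(counts), function(s) {
        np <- counts[s, "pos"]; nn <- counts[s, "neg"]
        n <- np + nn
        pt <- proportionTest(nn, n, p0, method = method)
        data.frame(stratum = s, n_total = n, n_pos = np, n_neg = nn,
                   ratio_neg_pos = if (np == 0) Inf else nn / np,
                   z = pt$z, p = pt$p, stringsAsFactors = FALSE)
    })
    tot <- unname(overall["pos"] + overall["neg"])
    rows[[length(rows) + 1L]] <- data.frame(
        stratum = "Overall", n_total = tot,
        n_pos = unname(overall["pos"]), n_neg = unname(overall["neg"]),
        ratio_neg_pos = if (tot == 0) NA_real_
                        else if (overall["pos"] == 0) Inf
                        else unname(overall["neg"] / overall["pos"]),
        z = 0, p = 1, stringsAsFactors = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
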