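#' Per-probe two-group linear fits
#'
#' Ordinary least squares for the two-group comparison: per probe, the
#' case-minus-control mean difference, the pooled residual variance and
#' its degrees of freedom (n1 + n2 - 2).
#'
#' @param x matrix of (transformed) expression values, probes x samples.
#' @param design sample design; \code{phenotype} defines the groups.
#' @param case,control phenotype labels; default: case is the second
#'   phenotype level alphabetically, control the first.
#' @return data.frame with probe_id, effect, s2, df_resid, n_case,
#'   n_control.
#' @export
fitTwoGroup <- function(x, design, case = NULL, control = NULL) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == nrow(design))
    levs <- sort(unique(design$phenotype))
    if (is.null(control)) control <- levs[1]
    if (is.null(case)) case <- setdiff(levs, control)[1]
    i1 <- design$phenotype == control
    i2 <- design$phenotype == case
    n1 <- sum(i1); n2 <- sum(i2)
    if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
    m1 <- rowMeans(x[, i1, drop = FALSE])
    m2 <- rowMeans(x[, i2, drop = FALSE])
    ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2L
    data.frame(probe_id = rownames(x), effect = m2 - m1,
               s2 = (ss1 + ss2) / df, df_resid = df,
               n_case = n2, n_control = n1,
               row.names = NULL, stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function, for the prior-df moment
# estimator. Solves trigamma(y) = x for y > 0.
.trigammaInverse <- function(x) {
    vapply(x, function(xi) {
        if (!is.finite(xi) || xi <= 0) return(Inf)
        if (xi > 1e7) return(1 / sqrt(xi))
        if (xi < 1e-6) return(1 / xi)
        y <- 0.5 + 1 / xi
        for (iter in 1:50) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / xi) / psigamma(y, 2)
            y <- y + dif
            if (abs(dif / y) < 1e-10) break
        }
        y
    }, numeric(1))
}

#' Empirical-Bayes moderation of two-group t-statistics
#'
#' Shrinks per-probe residual variances toward a common prior and forms
#' moderated t-statistics. The prior degrees of freedom \code{d0} and
#' prior variance \code{s0_sq} are estimated by moment-matching the
#' marginal distribution of \code{log(s2)} under the scaled-inverse-
#' chi-squared hierarchical model (digamma/trigamma inversion); the
#' posterior variance is \code{(d0 s0^2 + df s^2) / (d0 + df)} and the
#' moderated t is referred to a t distribution on \code{d0 + df}
#' degrees of freedom (normal reference when \code{d0} is infinite).
#'
#' A negative moment estimate of the trigamma equation (variances more
#' concordant than any finite-d0 model allows) falls back to
#' \code{d0 = Inf}. Forcing \code{d0 = 0} recovers the ordinary
#' two-sample t.
#'
#' @param fits data.frame from [fitTwoGroup()] (columns effect, s2,
#'   df_resid, n_case, n_control).
#' @param d0 optional forced prior df (0, a positive number, or Inf);
#'   NULL (default) estimates it from the data.
#' @param min_probes minimum number of probes for hyperparameter
#'   estimation (default 10).
#' @return list with \code{params} (d0, s0_sq) and \code{table}: the
#'   input plus s2_post, t_mod, p.
#' @export
moderateT <- function(fits, d0 = NULL, min_probes = 10L) {
    s2 <- fits$s2
    df <- fits$df_resid
    if (is.null(d0) && length(s2) < min_probes)
        stop("need >= ", min_probes, " probes to estimate the prior; ",
             "pass d0 explicitly for smaller problems")
    est <- .estimatePrior(s2, df, d0)
    d0 <- est$d0; s0_sq <- est$s0_sq
    if (is.infinite(d0)) {
        s2_post <- rep(s0_sq, length(s2))
        df_total <- rep(Inf, length(s2))
    } else if (d0 == 0) {
        s2_post <- s2
        df_total <- df
    } else {
        s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
        df_total <- d0 + df
    }
    se <- sqrt(s2_post * (1 / fits$n_case + 1 / fits$n_control))
    t_mod <- ifelse(se == 0, ifelse(fits$effect == 0, 0, Inf * sign(fits$effect)),
                    fits$effect / se)
    p <- ifelse(is.infinite(df_total),
                2 * stats::pnorm(-abs(t_mod)),
                2 * stats::pt(-abs(t_mod), df = df_total))
    p[is.nan(p)] <- 1
    out <- fits
    out$s2_post <- s2_post
    out$t_mod <- t_mod
    out$p <- p
    list(params = list(d0 = d0, s0_sq = s0_sq), table = out)
}

.estimatePrior <- function(s2, df, d0 = NULL) {
    ok <- s2 > 0 & is.finite(s2)
    if (!any(ok)) return(list(d0 = Inf, s0_sq = mean(s2)))
    z <- log(s2[ok])
    dfo <- df[ok]
    e <- z - digamma(dfo / 2) + log(dfo / 2)
    ebar <- mean(e)
    if (!is.null(d0)) {
        if (is.infinite(d0)) return(list(d0 = Inf, s0_sq = exp(ebar)))
        if (d0 == 0) return(list(d0 = 0, s0_sq = exp(ebar)))
        s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
        return(list(d0 = d0, s0_sq = s0_sq))
    }
    n <- length(e)
    rhs <- mean((e - ebar)^2 * n / (n - 1) - trigamma(dfo / 2))
    if (rhs <= 0) {
        warning("variances are under-dispersed; falling back to d0 = Inf")
        return(list(d0 = Inf, s0_sq = exp(ebar)))
    }
    d0 <- 2 * .trigammaInverse(rhs)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone in p-rank,
#' capped at 1); a thin wrapper over \code{stats::p.adjust(method =
#' "BH")} so the pipeline carries a single named adjustment step.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0) return(numeric(0))
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    stats::p.adjust(p, method = "BH")
}

#' Call differential expression
#'
#' Runs the two-group moderated-t pipeline on a transformed expression
#' matrix and BH-adjusts the p-values.
#'
#' @inheritParams fitTwoGroup
#' @param d0 optional forced prior df, see [moderateT()].
#' @return list with \code{params} and \code{table} (adds p_adj).
#' @export
callDE <- function(x, design, case = NULL, control = NULL, d0 = NULL) {
    fits <- fitTwoGroup(x, design, case = case, control = control)
    mod <- moderateT(fits, d0 = d0)
    mod$table$p_adj <- bhAdjust(mod$table$p)
    mod
}

#' Collapse probe-level DE results to transcripts
#'
#' Keeps, per transcript, the probe with the smallest adjusted p-value
#' (ties broken by smaller raw p, then lexicographic probe id); probes
#' with no transcript mapping are discarded.
#'
#' @param de_table DE table with probe_id, p, p_adj.
#' @param probe_map data.frame with probe_id, transcript_id (NA =
#'   unmapped).
#' @return the DE table restricted to one row per transcript, with a
#'   transcript_id column.
#' @export
collapseToTranscripts <- function(de_table, probe_map) {
    merged <- merge(de_table, probe_map[, c("probe_id", "transcript_id")],
                    by = "probe_id")
    merged <- merged[!is.na(merged$transcript_id), , drop = FALSE]
    if (nrow(merged) == 0) return(merged)
    o <- order(merged$transcript_id, merged$p_adj, merged$p,
               merged$probe_id)
    merged <- merged[o, , drop = FALSE]
    merged <- merged[!duplicated(merged$transcript_id), , drop = FALSE]
    rownames(merged) <- NULL
    merged
}

#' Call differential methylation by the delta-beta rule
#'
#' A CpG is differentially methylated when the absolute difference
#' between its phenotype-average beta-values exceeds \code{delta}
#' (strictly), averages taken over present samples only. Direction is
#' "hyper" when the case-phenotype mean exceeds the control mean.
#'
#' @param beta beta-value matrix (probes x samples) or a
#'   \linkS4class{BetaSet}.
#' @param design sample design (ignored when beta is a BetaSet with
#'   colData).
#' @param delta the delta-beta threshold (default 0.15, strict).
#' @param present optional logical matrix of per-cell presence (from
#'   [presenceFilter()]); defaults to all present.
#' @param case,control phenotype labels as in [fitTwoGroup()].
#' @return data.frame with probe_id, mean_control, mean_case,
#'   delta_beta, direction for every emitted CpG. Probes with no present
#'   sample in a group are skipped.
#' @export
callDM <- function(beta, design = NULL, delta = 0.15, present = NULL,
                   case = NULL, control = NULL) {
    if (is(beta, "BetaSet")) {
        if (is.null(design)) design <- designTable(beta)
        beta <- betaValues(beta)
    }
    beta <- as.matrix(beta)
    stopifnot(ncol(beta) == nrow(design))
    if (is.null(present))
        present <- matrix(TRUE, nrow(beta), ncol(beta))
    levs <- sort(unique(design$phenotype))
    if (is.null(control)) control <- levs[1]
    if (is.null(case)) case <- setdiff(levs, control)[1]
    i1 <- design$phenotype == control
    i2 <- design$phenotype == case
    maskMean <- function(cols) {
        b <- beta[, cols, drop = FALSE]
        pr <- present[, cols, drop = FALSE]
        b[!pr] <- NA
        rowMeans(b, na.rm = TRUE)
    }
    m1 <- maskMean(i1)
    m2 <- maskMean(i2)
    ok <- is.finite(m1) & is.finite(m2)
    d <- m2 - m1
    # strict threshold, robust to floating-point dust at the boundary
    emit <- ok & (abs(d) - delta) > 1e-12
    data.frame(probe_id = rownames(beta)[emit],
               mean_control = m1[emit], mean_case = m2[emit],
               delta_beta = d[emit],
               direction = ifelse(d[emit] > 0, "hyper", "hypo"),
               row.names = NULL, stringsAsFactors = FALSE)
}
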