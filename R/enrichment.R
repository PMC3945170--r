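#' Hypergeometric over-representation analysis
#'
#' For each category, compares the number of query genes annotated to
#' it ("actual") with the hypergeometric expectation \code{n K / N}
#' for a query of size n drawn from a background of N genes of which K
#' carry the category. Reports the actual/expected ratio, the
#' normal-deviate z-score \code{(actual - expected) / sd} with
#' \code{sd = sqrt(n (K/N) (1 - K/N) (N - n) / (N - 1))}, the exact
#' upper-tail hypergeometric p (k >= actual), and the directional p
#' (lower tail when z is negative, matching the usual ORA table
#' convention), together with the three percentage columns:
#' actual/n ("in data set"), actual/K ("in category") and K/N
#' ("category in background").
#'
#' @param query character vector of query gene ids (deduplicated).
#' @param categories data.frame with columns gene_id, category; genes
#'   may carry several categories.
#' @param background_size N, the size of the annotated background
#'   universe (defaults to the number of distinct genes in
#'   \code{categories}).
#' @return data.frame with one row per category (K > 0 categories
#'   only), sorted by p_over: category, actual, K, n, N, expected,
#'   ratio, z, p_over, p_directional, pct_in_query, pct_in_category,
#'   pct_category_background.
#' @export
ora <- function(query, categories, background_size = NULL) {
    query <- unique(as.character(query))
    n <- length(query)
    if (n == 0) stop("empty query set")
    N <- if (is.null(background_size))
        length(unique(categories$gene_id)) else background_size
    if (n > N) stop("query larger than background")
    cats <- split(categories$gene_id, categories$category)
    rows <- lapply(names(cats), function(cat) {
        members <- unique(cats[[cat]])
        K <- length(members)
        if (K == 0) return(NULL)
        actual <- sum(query %in% members)
        oraRow(actual, K, n, N, category = cat)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p_over, -out$z), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' One over-representation row from explicit counts
#'
#' The arithmetic used by [ora()], exposed so published cross-tables
#' can be recomputed directly from their printed counts.
#'
#' @param actual query hits in the category.
#' @param K category size in the background.
#' @param n query size.
#' @param N background size.
#' @param category label (default "category").
#' @return one-row data.frame, columns as in [ora()].
#' @export
oraRow <- function(actual, K, n, N, category = "category") {
    stopifnot(actual >= 0, actual <= min(K, n), K <= N, n <= N)
    p_frac <- K / N
    expected <- n * p_frac
    sd_h <- sqrt(n * p_frac * (1 - p_frac) * (N - n) / (N - 1))
    z <- if (sd_h == 0) 0 else (actual - expected) / sd_h
    p_over <- stats::phyper(actual - 1, K, N - K, n, lower.tail = FALSE)
    p_dir <- if (z < 0) stats::phyper(actual, K, N - K, n) else p_over
    data.frame(category = category, actual = actual, K = K, n = n, N = N,
               expected = expected,
               ratio = if (expected == 0) NA_real_ else actual / expected,
               z = z, p_over = p_over, p_directional = p_dir,
               pct_in_query = 100 * actual / n,
               pct_in_category = 100 * actual / K,
               pct_category_background = 100 * K / N,
               stringsAsFactors = FALSE)
}

#' Rank category terms shared by two gene lists
#'
#' Runs [ora()] for both query lists against the same category map and
#' returns the terms hit (actual >= 1) in both, ranked by the worse
#' (larger) of the two enrichment p-values, ascending — terms strongly
#' over-represented in both lists come first.
#'
#' @param query_a,query_b character vectors of gene ids.
#' @param categories data.frame gene_id, category (the term map).
#' @param background_size N for both tests.
#' @return data.frame category, p_a, p_b, p_rank (= max of the two),
#'   sorted by p_rank; zero rows when no term is shared.
#' @export
intersectRank <- function(query_a, query_b, categories,
                          background_size = NULL) {
    ea <- ora(query_a, categories, background_size)
    eb <- ora(query_b, categories, background_size)
    ea <- ea[ea$actual >= 1, c("category", "p_over")]
    eb <- eb[eb$actual >= 1, c("category", "p_over")]
    shared <- merge(ea, eb, by = "category",
                    suffixes = c("_a", "_b"))
    if (nrow(shared) == 0)
        return(data.frame(category = character(), p_a = numeric(),
                          p_b = numeric(), p_rank = numeric(),
                          stringsAsFactors = FALSE))
    out <- data.frame(category = shared$category,
                      p_a = shared$p_over_a, p_b = shared$p_over_b,
                      p_rank = pmax(shared$p_over_a, shared$p_over_b),
                      stringsAsFactors = FALSE)
    out <- out[order(out$p_rank, out$category), , drop = FALSE]
    rownames(out) <- NULL
    out
}
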