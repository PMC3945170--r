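# Independent brute-force oracles used across the suite. Each one
# recomputes a quantity from its textbook definition, deliberately
# avoiding the package's own code paths.

# Benjamini-Hochberg step-up from the definition:
# adj(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1, in sort order.
bhBrute <- function(p) {
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m))
        adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
    out <- numeric(m)
    out[o] <- adj
    out
}

# Average ranks by counting, then Pearson on the ranks.
rankBrute <- function(x) {
    vapply(seq_along(x), function(i) {
        sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    }, numeric(1))
}

spearmanBrute <- function(x, y) {
    rx <- rankBrute(x); ry <- rankBrute(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Least-squares F for the interaction term via explicit pseudoinverse
# normal equations; ranks from singular values.
interactionFOracle <- function(y, status, location) {
    status <- factor(status); location <- factor(location)
    X_full <- stats::model.matrix(~ status * location)
    X_add <- stats::model.matrix(~ status + location)
    sse <- function(X) {
        beta <- MASS::ginv(t(X) %*% X) %*% t(X) %*% y
        sum((y - X %*% beta)^2)
    }
    rk <- function(X) sum(svd(X)$d > 1e-8 * max(dim(X)))
    ddf <- rk(X_full) - rk(X_add)
    df2 <- length(y) - rk(X_full)
    if (ddf < 1 || df2 < 1) return(NULL)
    s_full <- sse(X_full); s_add <- sse(X_add)
    list(F = ((s_add - s_full) / ddf) / (s_full / df2),
         df1 = ddf, df2 = df2)
}

# Classical balanced two-way interaction F from cell means.
balancedInteractionF <- function(y, status, location) {
    status <- factor(status); location <- factor(location)
    a <- nlevels(status); b <- nlevels(location)
    r <- length(y) / (a * b)
    cell <- tapply(y, list(status, location), mean)
    mi <- tapply(y, status, mean); mj <- tapply(y, location, mean)
    gm <- mean(y)
    ss_int <- r * sum((cell - outer(mi, rep(1, b)) -
                       outer(rep(1, a), mj) + gm)^2)
    sse <- sum((y - cell[cbind(status, location)])^2)
    df1 <- (a - 1) * (b - 1)
    df2 <- a * b * (r - 1)
    list(F = (ss_int / df1) / (sse / df2), df1 = df1, df2 = df2)
}

# Hypergeometric upper tail by pmf summation with choose().
hyperTailBrute <- function(actual, K, N, n) {
    ks <- actual:min(K, n)
    sum(choose(K, ks) * choose(N - K, n - ks) / choose(N, n))
}

# Naive agglomerative average linkage on a small point set: returns the
# sorted merge heights.
avgLinkHeightsBrute <- function(x) {
    # x: samples in rows
    clusters <- as.list(seq_len(nrow(x)))
    d <- as.matrix(dist(x))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- c(NA, NA); bestd <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (i >= j) next
            dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
            if (dd < bestd) { bestd <- dd; best <- c(i, j) }
        }
        heights <- c(heights, bestd)
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    heights
}

# Distance-scan island context for one position.
islandContextBrute <- function(pos, islands, shore_bp = 4000) {
    if (nrow(islands) == 0) return("OpenSea")
    for (i in seq_len(nrow(islands)))
        if (pos >= islands[i, 1] && pos <= islands[i, 2]) return("Island")
    dmin <- Inf
    for (i in seq_len(nrow(islands))) {
        dmin <- min(dmin, abs(pos - islands[i, 1]), abs(pos - islands[i, 2]))
    }
    if (dmin <= shore_bp) "Shore" else "OpenSea"
}
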