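test_that("two-group fits recover hand-computed pooled statistics", {
    design <- sampleDesign(paste0("S", 1:6), rep(c("ctl", "dis"), each = 3))
    x <- rbind(cg1 = c(1, 1, 1, 2, 2, 2))
    f <- fitTwoGroup(x, design, case = "dis", control = "ctl")
    expect_equal(f$effect, 1)
    expect_equal(f$s2, 0)
    d2 <- sampleDesign(paste0("S", 1:4), rep(c("ctl", "dis"), each = 2))
    x2 <- rbind(cg1 = c(0, 2, 1, 3))
    f2 <- fitTwoGroup(x2, d2, case = "dis", control = "ctl")
    expect_equal(f2$effect, 1)
    expect_equal(f2$s2, 2)    # pooled: (2 + 2) / 2
    expect_equal(f2$df_resid, 2L)
    # permuting samples within groups changes nothing
    perm <- c(2, 1, 4, 3)
    f3 <- fitTwoGroup(x2[, perm, drop = FALSE], d2[perm, ],
                      case = "dis", control = "ctl")
    expect_equal(f3$effect, f2$effect)
    expect_equal(f3$s2, f2$s2)
})

test_that("moderated t reduces to ordinary t at d0 = 0 and z at d0 = Inf", {
    set.seed(8)
    design <- sampleDesign(paste0("S", 1:12),
                           rep(c("A", "B"), each = 6))
    x <- matrix(rnorm(50 * 12), 50, 12,
                dimnames = list(paste0("p", 1:50), design$sample_id))
    fits <- fitTwoGroup(x, design)
    m0 <- moderateT(fits, d0 = 0)
    # ordinary two-sample pooled t
    t_ord <- fits$effect / sqrt(fits$s2 * (1 / 6 + 1 / 6))
    expect_equal(m0$table$t_mod, t_ord, tolerance = 1e-12)
    expect_equal(m0$table$p, 2 * pt(-abs(t_ord), df = 10),
                 tolerance = 1e-12)
    mInf <- moderateT(fits, d0 = Inf)
    t_z <- fits$effect / sqrt(mInf$params$s0_sq * (1 / 6 + 1 / 6))
    expect_equal(mInf$table$t_mod, t_z, tolerance = 1e-12)
    expect_equal(mInf$table$p, 2 * pnorm(-abs(t_z)), tolerance = 1e-12)
    # estimated-d0 moderated t lies between its own d0 = 0 and d0 = Inf
    # limits (posterior variance is a convex combination)
    mest <- moderateT(fits)
    t_zlim <- fits$effect / sqrt(mest$params$s0_sq * (1 / 6 + 1 / 6))
    expect_true(all(
        abs(mest$table$t_mod) >= pmin(abs(t_ord), abs(t_zlim)) - 1e-10 &
        abs(mest$table$t_mod) <= pmax(abs(t_ord), abs(t_zlim)) + 1e-10))
})

test_that("prior hyperparameters are recovered under the assumed model", {
    set.seed(9)
    d0 <- 4; s0_sq <- 2; df <- 10; n <- 5000
    s2_true <- s0_sq * d0 / rchisq(n, d0)
    s2_obs <- s2_true * rchisq(n, df) / df
    fits <- data.frame(effect = 0, s2 = s2_obs, df_resid = df,
                       n_case = 6, n_control = 6)
    est <- moderateT(fits)$params
    expect_gte(est$d0, 3); expect_lte(est$d0, 5)
    expect_gte(est$s0_sq, 1.8); expect_lte(est$s0_sq, 2.2)
})

test_that("moderation matches the reference empirical-Bayes shrinkage", {
    set.seed(10)
    s2 <- rchisq(300, 8) / 8 * exp(rnorm(300, 0, 0.5))
    fits <- data.frame(effect = rnorm(300), s2 = s2, df_resid = 8,
                       n_case = 5, n_control = 5)
    mine <- moderateT(fits)
    ref <- limma::squeezeVar(s2, df = 8)
    expect_equal(mine$params$d0, ref$df.prior, tolerance = 1e-6)
    expect_equal(mine$params$s0_sq, ref$var.prior, tolerance = 1e-6)
    expect_equal(mine$table$s2_post, ref$var.post, tolerance = 1e-6)
})

test_that("identical variances fall back to the d0 = Inf branch", {
    fits <- data.frame(effect = rnorm(20), s2 = 1.7, df_resid = 10,
                       n_case = 6, n_control = 6)
    expect_warning(m <- moderateT(fits), "d0 = Inf")
    expect_true(is.infinite(m$params$d0))
    expect_equal(m$table$s2_post, rep(m$params$s0_sq, 20))
})

test_that("BH adjustment equals the brute-force step-up definition", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    p_eq <- rep(0.2, 7)
    expect_equal(bhAdjust(p_eq), p_eq)
    expect_identical(bhAdjust(numeric(0)), numeric(0))
    set.seed(11)
    for (n in c(2, 17, 1000)) {
        p <- runif(n)^2
        expect_equal(bhAdjust(p), bhBrute(p), tolerance = 1e-12)
    }
    # monotone nondecreasing in p-rank
    p <- runif(200)
    adj <- bhAdjust(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("probe collapse keeps the best probe per transcript", {
    de <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                     p = c(0.05, 0.001, 0.01, 0.02, 0.001),
                     p_adj = c(0.2, 0.01, 0.05, 0.05, 0.3),
                     stringsAsFactors = FALSE)
    map <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                      transcript_id = c("T1", "T1", "T2", "T2", NA),
                      stringsAsFactors = FALSE)
    out <- collapseToTranscripts(de, map)
    expect_equal(nrow(out), 2)
    expect_equal(out$probe_id[out$transcript_id == "T1"], "p2")
    # T2 tie on p_adj broken by raw p
    expect_equal(out$probe_id[out$transcript_id == "T2"], "p3")
    # unmapped probe discarded
    expect_false("p5" %in% out$probe_id)
})

test_that("delta-beta calling is strict and direction-correct", {
    design <- sampleDesign(paste0("S", 1:4), rep(c("ctl", "dis"), each = 2))
    beta <- rbind(cg_up = c(0.50, 0.50, 0.66, 0.66),
                  cg_edge = c(0.50, 0.50, 0.65, 0.65),
                  cg_dn = c(0.80, 0.80, 0.55, 0.55))
    dm <- callDM(beta, design, delta = 0.15, case = "dis",
                 control = "ctl")
    expect_setequal(dm$probe_id, c("cg_up", "cg_dn"))  # 0.15 is not > 0.15
    expect_equal(dm$direction[dm$probe_id == "cg_up"], "hyper")
    expect_equal(dm$delta_beta[dm$probe_id == "cg_up"], 0.16)
    expect_equal(dm$direction[dm$probe_id == "cg_dn"], "hypo")
    expect_equal(dm$delta_beta[dm$probe_id == "cg_dn"], -0.25)
})

test_that("group means use present samples only", {
    design <- sampleDesign(paste0("S", 1:4), rep(c("ctl", "dis"), each = 2))
    beta <- rbind(cg1 = c(0.5, 0.9, 0.7, 0.7))
    present <- rbind(c(TRUE, FALSE, TRUE, TRUE))
    dm <- callDM(beta, design, delta = 0.15, present = present,
                 case = "dis", control = "ctl")
    expect_equal(dm$mean_control, 0.5)   # the 0.9 cell is masked
    expect_equal(dm$delta_beta, 0.2)
    # a probe with no present sample in one group is skipped
    present2 <- rbind(c(FALSE, FALSE, TRUE, TRUE))
    dm2 <- callDM(beta, design, present = present2, case = "dis",
                  control = "ctl")
    expect_equal(nrow(dm2), 0)
})

test_that("null simulations keep raw DE p-values calibrated", {
    set.seed(12)
    design <- sampleDesign(paste0("S", 1:12), rep(c("A", "B"), each = 6))
    fr <- vapply(1:20, function(i) {
        x <- matrix(rnorm(2000 * 12), 2000, 12,
                    dimnames = list(paste0("p", 1:2000), design$sample_id))
        de <- suppressWarnings(callDE(x, design))  # d0 = Inf fallback
        mean(de$table$p < 0.05)
    }, numeric(1))
    expect_gte(mean(fr), 0.04)
    expect_lte(mean(fr), 0.06)
})
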