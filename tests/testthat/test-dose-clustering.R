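test_that("the Chebyshev metric equals the brute-force maximum coordinate gap", {
    expect_equal(as.numeric(dist(rbind(c(0, 0, 1), c(0, 0, 0)),
                                 method = "maximum")), 1)
    set.seed(1)
    for (i in 1:50) {
        a <- runif(10); b <- runif(10)
        expect_equal(as.numeric(dist(rbind(a, b), method = "maximum")),
                     max(abs(a - b)))
    }
})

test_that("identical profiles land in one cluster at distance zero", {
    m <- rbind(p1 = c(0, 0.5, 1), p2 = c(0, 0.5, 1), p3 = c(1, 1, 1),
               p4 = c(1, 1, 0.9))
    colnames(m) <- c(0, 1, 100)
    cl <- cluster_profiles(m, k = 2)
    expect_identical(cl$cluster[cl$strain_id == "p1"],
                     cl$cluster[cl$strain_id == "p2"])
})

test_that("clustering is invariant to strain input order", {
    set.seed(2)
    m <- matrix(runif(40 * 6), 40, 6,
                dimnames = list(sprintf("s%02d", 1:40), 1:6))
    c1 <- cluster_profiles(m, k = 4)
    c2 <- cluster_profiles(m[sample(40), ], k = 4)
    expect_identical(c1$strain_id, c2$strain_id)
    expect_identical(c1$cluster, c2$cluster)
})

test_that("planted archetypes are recovered from simulated dose responses", {
    skip_if_no_mclust()
    cfg <- sim_config(n_strains = 150L, seed = 21L, media = "SC",
                      noise_sd = 0.05, timepoints = seq(0, 48, by = 4))
    p <- make_strain_panel(cfg)
    g <- simulate_growth(p, cfg, n_replicates = 2L)
    am <- compute_augc_matrix(build_curves(g, size_col = "area"))
    am <- am[rownames(am) != "WT_SPIKE", ]
    cl <- cluster_profiles(am, k = 5)
    truth <- setNames(p$archetype, p$strain_id)[cl$strain_id]
    expect_gte(mclust::adjustedRandIndex(cl$cluster, truth), 0.9)
})

test_that("behavior labels read mean profiles the way the archetypes are defined", {
    means <- rbind(c(0.02, 0.3, 0.8, 1.0),    # needs inducer, keeps rising
                   c(1.0, 1.0, 1.0, 0.95),    # grows without inducer
                   c(0.05, 0.9, 1.0, 0.3),    # needs inducer, then toxic
                   c(1.0, 1.0, 0.9, 0.4),     # grows, high dose toxic
                   c(0.05, 0.08, 0.1, 0.08))  # never grows
    expect_identical(unname(label_behavior(means, doses = c(0, 1, 10, 100))),
                     c("dependent", "constitutive", "dependent_toxic",
                       "constitutive_toxic", "nonfunctional"))
    expect_identical(unname(label_behavior(rbind(c(NA, NA)))), "unclassified")
})

test_that("expression association behaves correctly under null and planted signal", {
    set.seed(4)
    n <- 1000L
    expr <- rlnorm(n, log(100), 1)
    a_null <- runif(n)
    res <- expression_association(a_null, expr)
    expect_lt(abs(res$spearman$rho), 0.1)
    expect_gt(res$ks$p.value, 1e-3)

    # perfectly monotone decreasing growth in expression
    res2 <- expression_association(max(expr) - rank(expr), expr)
    expect_equal(res2$spearman$rho, -1)

    # planted rank correlation of -0.5 is estimated within +/- 0.06
    z <- scale(log(expr))[, 1]
    a_cor <- -0.5 * z + sqrt(1 - 0.25) * rnorm(n)
    res3 <- expression_association(a_cor, expr)
    rho_true <- (6 / pi) * asin(-0.5 / 2)  # Spearman implied by Pearson -0.5
    expect_lt(abs(res3$spearman$rho - rho_true), 0.06)
})

test_that("binned statistics refuse underpopulated bins", {
    expect_error(expression_association(runif(30), rlnorm(30)),
                 "refusing binned statistics")
})

test_that("the induced-vs-native linear fit recovers exact coefficients", {
    x <- seq(5, 200, length.out = 20)
    y <- 87.96 + 4.79 * x
    fit <- fit_expression_linear(y, x, cutoff = 250)
    expect_equal(fit$slope, 4.79, tolerance = 1e-10)
    expect_equal(fit$intercept, 87.96, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)

    # constant response: zero slope, zero R^2
    fit0 <- fit_expression_linear(rep(50, 10), seq(1, 100, length.out = 10))
    expect_equal(fit0$slope, 0, tolerance = 1e-10)
    expect_equal(fit0$r_squared, 0, tolerance = 1e-10)

    # genes at/above the cutoff are excluded from the fit
    x2 <- c(x, 300, 400)
    y2 <- c(y, 0, 0)
    fit2 <- fit_expression_linear(y2, x2, cutoff = 250)
    expect_equal(fit2$slope, 4.79, tolerance = 1e-10)
    expect_identical(fit2$excluded, c(21L, 22L))
})

test_that("OLS matches the normal-equations oracle on a 5-point fixture", {
    x <- c(1, 3, 4, 7, 9); y <- c(2.1, 2.9, 4.2, 6.8, 9.1)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    fit <- fit_expression_linear(y, x, cutoff = 100)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
})
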