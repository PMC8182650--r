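test_that("Aux scores follow the ratio-of-ratios definition", {
    g <- data.frame(strain_id = c("even", "aux", "scaled"),
                    G_M0 = c(100, 100, 1000),
                    G_M1 = c(100, 400, 1000),
                    G_R0 = c(100, 300, 1000),
                    G_R1 = c(100, 300, 1000))
    sc <- aux_scores(g)
    expect_equal(sc$aux_score[sc$strain_id == "even"], 1)
    expect_equal(sc$aux_score[sc$strain_id == "aux"], 4)
    # output is ranked, largest score first
    expect_identical(sc$strain_id[1L], "aux")

    # invariant under a global per-strain rescaling of growth
    g10 <- g; g10[, -1] <- g10[, -1] * 10
    expect_equal(aux_scores(g10)$aux_score, sc$aux_score)
})

test_that("zero growth totals are floored and flagged, missing strains dropped", {
    g <- data.frame(strain_id = c("z", "m"),
                    G_M0 = c(0, 10), G_M1 = c(50, NA),
                    G_R0 = c(100, 10), G_R1 = c(100, 10))
    expect_warning(sc <- aux_scores(g, pseudogrowth = 1), "omitted")
    expect_identical(sc$strain_id, "z")
    expect_true(sc$floored)
    expect_equal(sc$aux_score, 50)
})

test_that("the toxicity caller reproduces the printed formulas", {
    # synthetic screen engineered so the OLS fit is y = 0.5 x exactly:
    # points paired symmetrically around the line
    set.seed(6)
    x <- runif(200, 1000, 9000)
    y <- 0.5 * x
    # the strain of interest: x = 4000, y = 500
    xs <- c(x, 4000); ys <- c(y, 500)
    tox <- toxicity_call(xs, ys, threshold = 2000)
    m <- attr(tox, "m"); b <- attr(tox, "b")
    expect_equal(m, 0.5, tolerance = 1e-6)
    expect_equal(b, 0, tolerance = 1e-6)
    k <- nrow(tox)
    expect_equal(tox$y_corrected[k], 1000, tolerance = 1e-3)
    expect_equal(tox$distance[k], 3000 / sqrt(2), tolerance = 1e-3)
    expect_true(tox$toxic_flag[k])
    # points on the fitted line have distance 0 and are never toxic
    on_line <- seq_len(k - 1L)
    expect_true(all(tox$distance[on_line] < 1e-6))
    expect_false(any(tox$toxic_flag[on_line]))
    # the default distance threshold is 2000 size units
    expect_equal(formals(toxicity_call)$threshold, 2000)
})

test_that("a perfect diagonal yields zero toxic calls", {
    set.seed(7)
    x <- runif(500, 1000, 9000)
    tox <- toxicity_call(x, x)
    expect_identical(sum(tox$toxic_flag), 0L)
})

test_that("strains above the diagonal are never called toxic", {
    set.seed(8)
    x <- runif(300, 1000, 9000)
    y <- x + rnorm(300, 0, 50)
    y[1] <- x[1] + 5000  # grows much better with inducer
    tox <- toxicity_call(x, y)
    expect_false(tox$toxic_flag[1])
})

test_that("a degenerate fit aborts with a diagnostic", {
    set.seed(9)
    x <- runif(100, 1000, 9000)
    y <- 10000 - x + rnorm(100, 0, 10)  # negative slope
    expect_error(toxicity_call(x, y), "degenerate")
})

test_that("planted toxicity is recovered with high sensitivity and low FDP", {
    scr <- simulate_toxicity_screen(n_strains = 2000L, seed = 4L)
    tox <- toxicity_call(scr$x, scr$y, strain_id = scr$strain_id)
    sens <- sum(tox$toxic_flag & scr$true_toxic) / sum(scr$true_toxic)
    fdp <- if (sum(tox$toxic_flag)) {
        sum(tox$toxic_flag & !scr$true_toxic) / sum(tox$toxic_flag)
    } else 0
    expect_gte(sens, 0.9)
    expect_lte(fdp, 0.1)
})

test_that("reversibility classes follow the printed cutoff semantics", {
    r <- classify_reversibility(c(0.40, 0.55, 0.60, 0.75, 0.80), rep(1, 5))
    expect_identical(r$class,
                     c("reversible", "reversible", "partially_reversible",
                       "partially_reversible", "not_reversible"))
    r0 <- classify_reversibility(1, 0)
    expect_identical(r0$class, "undefined")
    expect_true(is.na(r0$ratio))
})

test_that("dependence classes follow the documented cutoffs", {
    doses <- c(0, 1, 10, 100)
    expect_identical(classify_dependence(c(0.01, 0.02, 0.03, 0.02),
                                         doses)$class, "no_growth")
    expect_identical(classify_dependence(c(0.05, 0.6, 1, 1), doses)$class,
                     "dependent")
    expect_identical(classify_dependence(c(0.5, 0.8, 1, 1), doses)$class,
                     "partially_dependent")
    expect_identical(classify_dependence(c(0.95, 1, 1, 1), doses)$class,
                     "constitutive")
    expect_error(classify_dependence(1, 0), "single-dose")
    expect_error(classify_dependence(c(1, 1), c(1, 10)), "dose 0")
})

test_that("SDL calls require the score below cutoff in every replicate", {
    s0 <- cbind(rep(1, 3), rep(1, 3))
    s1000 <- rbind(c(1.0, 1.0),    # no effect
                   c(0.9, 0.9),    # log2(0.9) = -0.152 in both
                   c(0.9, 1.1))    # fails the 2/2 rule
    sdl <- sdl_call(s1000, s0, strain_id = c("a", "b", "c"))
    expect_identical(sdl$sdl_flag, c(FALSE, TRUE, FALSE))
    expect_equal(sdl$score_rep1[2], log2(0.9))

    # zero denominators leave the strain excluded and flagged
    sdl2 <- sdl_call(cbind(0.5, 0.5), cbind(0, 1))
    expect_true(sdl2$undefined_flag)
    expect_false(sdl2$sdl_flag)

    # ratio - 1 scale is selectable
    sdl3 <- sdl_call(s1000, s0, score = "ratio_minus_1")
    expect_equal(sdl3$score_rep1[2], -0.1)
    expect_identical(sdl3$sdl_flag, c(FALSE, TRUE, FALSE))
})
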