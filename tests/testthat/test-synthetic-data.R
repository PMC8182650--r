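test_that("strain panels are deterministic and satisfy barcode invariants", {
    cfg <- sim_config(n_strains = 100L, seed = 1L)
    p1 <- make_strain_panel(cfg)
    p2 <- make_strain_panel(cfg)
    expect_identical(p1, p2)

    expect_true(all(nchar(p1$barcode) == 12L))
    expect_false(anyDuplicated(p1$barcode) > 0L)
    expect_identical(sum(p1$is_spike_in_wt), 1L)
    expect_true(all(p1$native_expression >= 0))

    # all-pairs brute-force scan agrees with the compiled check
    expect_gte(min_pairwise_hamming_oracle(p1$barcode), 5)
    expect_identical(min_pairwise_hamming(p1$barcode),
                     as.integer(min_pairwise_hamming_oracle(p1$barcode)))
})

test_that("an unsatisfiable barcode constraint fails explicitly", {
    expect_error(estrascreen:::cpp_sample_barcodes(5000L, 3L, 3L),
                 "could not sample")
})

test_that("growth curves follow their archetypes", {
    cfg <- sim_config(n_strains = 80L, seed = 3L, media = "SC",
                      noise_sd = 0)
    p <- make_strain_panel(cfg)
    g <- simulate_growth(p, cfg, n_replicates = 1L)

    dep <- p$strain_id[p$archetype == "dependent"]
    final0 <- g[g$strain_id %in% dep & g$dose_nM == 0 &
                g$time_h == max(g$time_h), ]
    expect_true(all(final0$true_area < 0.05 * cfg$carrying_capacity))

    const <- p$strain_id[p$archetype == "constitutive" & !p$aux_flag]
    for (s in head(const, 5L)) {
        a <- vapply(cfg$doses, function(d) {
            cc <- g[g$strain_id == s & g$dose_nM == d, ]
            cc <- cc[order(cc$time_h), ]
            augc(cc$time_h, cc$area)
        }, numeric(1))
        expect_lte(max(a) / min(a), 1.2)
    }

    non <- p$strain_id[p$archetype == "nonfunctional"]
    skip_if(length(non) == 0L)
    gnon <- g[g$strain_id %in% non & g$time_h == max(g$time_h), ]
    expect_true(all(gnon$true_area < 0.1 * cfg$carrying_capacity))
})

test_that("auxotroph-flagged strains require inducer only on minimal medium", {
    cfg <- sim_config(n_strains = 60L, seed = 9L, media = c("SC", "YNB"),
                      noise_sd = 0, doses = c(0, 100))
    p <- make_strain_panel(cfg)
    aux <- p$strain_id[p$aux_flag & p$archetype == "constitutive"]
    skip_if(length(aux) == 0L)
    g <- simulate_growth(p, cfg, n_replicates = 1L)
    fin <- g[g$strain_id == aux[1L] & g$time_h == max(g$time_h), ]
    ynb0 <- fin$true_area[fin$medium == "YNB" & fin$dose_nM == 0]
    ynb100 <- fin$true_area[fin$medium == "YNB" & fin$dose_nM == 100]
    sc0 <- fin$true_area[fin$medium == "SC" & fin$dose_nM == 0]
    expect_lt(ynb0, 0.05 * cfg$carrying_capacity)
    expect_gt(ynb100, 0.5 * cfg$carrying_capacity)
    expect_gt(sc0, 0.5 * cfg$carrying_capacity)
})

test_that("multiplicative size noise has the configured relative spread", {
    cfg <- sim_config(n_strains = 2L, seed = 5L, media = "SC",
                      doses = c(0, 100), timepoints = c(0, 24),
                      noise_sd = 0.1)
    p <- make_strain_panel(cfg)
    g <- simulate_growth(p, cfg, n_replicates = 1000L)
    grown <- g[g$true_area > 0.5 * cfg$carrying_capacity, ]
    rel <- tapply(grown$area / grown$true_area,
                  paste(grown$strain_id, grown$dose_nM, grown$time_h),
                  stats::sd)
    expect_true(all(rel > 0.08 & rel < 0.12))
})

test_that("rendered plates record exact pixel areas and are reproducible", {
    areas <- matrix(0, 8, 12)
    areas[3, 4] <- 150; areas[5, 9] <- 80; areas[7, 2] <- 220
    rp <- render_plate_image(areas, pitch = 20L, pixel_noise = 0,
                             gradient = 0)
    for (idx in list(c(3, 4, 150), c(5, 9, 80), c(7, 2, 220))) {
        got <- rp$truth$true_pixel_area[rp$truth$row == idx[1] - 1 &
                                        rp$truth$col == idx[2] - 1]
        expect_lt(abs(got - idx[3]) / idx[3], 0.10)
    }
    # empty cells render no foreground at all
    expect_true(all(rp$truth$true_pixel_area[
        !(rp$truth$row + 1) %in% c(3, 5, 7)] == 0))

    cfg <- tiny_config()
    p <- make_strain_panel(cfg)
    g <- simulate_growth(p, cfg, n_replicates = 2L)
    g <- g[g$dose_nM == 100, ]
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    r1 <- render_plate_series(g, cfg, d1)
    r2 <- render_plate_series(g, cfg, d2)
    expect_identical(unname(tools::md5sum(r1$files)),
                     unname(tools::md5sum(r2$files)))
})

test_that("simulated FASTQ runs have exact structure and spike-in level", {
    cfg <- sim_config(n_strains = 50L, seed = 8L, read_depth = 1e5,
                      per_base_error = 0)
    p <- make_strain_panel(cfg)
    pool <- simulate_pool(p, cfg)
    d <- withr::local_tempdir()
    run <- simulate_barseq_run(p, pool, cfg, d)

    fq <- read_fastq(run$samples$fastq_path[1L])
    expect_identical(nrow(fq), as.integer(cfg$read_depth))
    # at zero error every read carries both flanks verbatim
    expect_true(all(grepl("^GCACCAGGAACCATATA[ACGT]{12}GATCCGCTCGCACCG",
                          fq$seq)))

    # 3% spike-in: the wild-type true count is binomial around depth * 0.03
    n <- cfg$read_depth; pr <- cfg$spike_in_fraction
    expect_lt(abs(run$true_counts["WT_SPIKE", 1L] - n * pr),
              3 * sqrt(n * pr * (1 - pr)))
})

test_that("a sample with all-zero abundances is rejected", {
    cfg <- sim_config(n_strains = 10L, seed = 2L, read_depth = 100)
    p <- make_strain_panel(cfg)
    pool <- simulate_pool(p, cfg)
    pool$weights0[] <- 0
    expect_error(simulate_barseq_run(p, pool, cfg, withr::local_tempdir()),
                 "all-zero abundances")
})
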