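make_index_fixture <- function(n = 20L, seed = 1L) {
    set.seed(seed)
    bc <- estrascreen:::cpp_sample_barcodes(n, 12L, 5L)
    build_index(data.frame(strain_id = sprintf("S%03d", seq_len(n)),
                           barcode = as.character(bc),
                           stringsAsFactors = FALSE))
}

mutate_at <- function(seq, positions) {
    v <- strsplit(seq, "")[[1]]
    for (p in positions) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1L]
    paste(v, collapse = "")
}

write_reads <- function(reads,
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
    path <- file.path(dir, "s1.fastq")
    write_fastq(reads, path)
    data.frame(sample_id = "s1", fastq_path = path, time_h = 0,
               stringsAsFactors = FALSE)
}

test_that("index construction validates barcodes and records distances", {
    idx <- make_index_fixture(100L)
    expect_identical(length(idx$strain_id), 100L)
    expect_identical(idx$min_pairwise_distance,
                     as.integer(min_pairwise_hamming_oracle(idx$barcode)))
    expect_gte(idx$min_pairwise_distance, 5L)

    expect_error(build_index(data.frame(strain_id = c("a", "b"),
                                        barcode = rep("ACGTACGTACGT", 2))),
                 "duplicate barcodes.*a, b")
    expect_warning(build_index(data.frame(strain_id = c("a", "b"),
                                          barcode = c("AAAAAAAAAAAA",
                                                      "AAAAAAAAAAAT"))),
                   "may be ambiguous")
})

test_that("reads are assigned within the mismatch budget and refused beyond it", {
    idx <- make_index_fixture()
    up <- idx$up_flank; down <- idx$down_flank
    bc <- idx$barcode[3L]
    filler <- strrep("A", 10)

    perfect <- paste0(up, bc, down, filler)
    two_mm <- paste0(up, mutate_at(bc, c(2, 7)), down, filler)
    three_mm <- paste0(up, mutate_at(bc, c(2, 7, 11)), down, filler)
    sheet <- write_reads(c(perfect, two_mm, three_mm))
    cm <- count_reads(sheet, idx)
    expect_identical(unname(cm[3L, 1L]), 2L)   # perfect + 2-mismatch
    tot <- attr(cm, "totals")
    expect_identical(tot$assigned, 2L)
    expect_identical(tot$unassigned, 1L)
    expect_identical(tot$assigned + tot$ambiguous + tot$unassigned,
                     tot$total)
})

test_that("flank tolerance accepts one mismatch and small offsets, no more", {
    idx <- make_index_fixture()
    bc <- idx$barcode[1L]
    up1 <- mutate_at(idx$up_flank, 5)          # 1 flank mismatch: ok
    up2 <- mutate_at(idx$up_flank, c(5, 9))    # 2 mismatches: rejected
    reads <- c(paste0("GG", idx$up_flank, bc, idx$down_flank),  # offset +2
               paste0(up1, bc, idx$down_flank, "AAAA"),
               paste0(up2, bc, idx$down_flank, "AAAA"))
    sheet <- write_reads(reads)
    cm <- count_reads(sheet, idx)
    expect_identical(unname(cm[1L, 1L]), 2L)
    expect_identical(attr(cm, "totals")$unassigned, 1L)
})

test_that("every assignment decision matches the exhaustive Hamming oracle", {
    cfg <- sim_config(n_strains = 120L, seed = 13L, read_depth = 2e4,
                      per_base_error = 0.02)
    p <- make_strain_panel(cfg)
    pool <- simulate_pool(p, cfg)
    run <- simulate_barseq_run(p, pool, cfg, withr::local_tempdir())
    idx <- build_index(p)

    reads <- read_fastq(run$samples$fastq_path[1L])$seq
    called <- estrascreen:::cpp_call_reads(reads, idx$barcode, idx$up_flank,
                                           idx$down_flank, 2L, 1L, 2L)
    qs <- estrascreen:::cpp_extract_barcodes(reads, idx$up_flank,
                                             idx$down_flank, 12L, 1L, 2L)
    has_bc <- !is.na(qs)
    expect_true(all(called$status[!has_bc] == 3L))

    uq <- unique(qs[has_bc])
    ora <- barcode_assign_oracle(uq, idx$barcode, max_mm = 2L)
    exp_status <- ifelse(ora$hits == 1L, 1L, ifelse(ora$hits > 1L, 2L, 3L))
    map <- match(qs[has_bc], uq)
    expect_identical(called$status[has_bc], exp_status[map])
    one <- has_bc & called$status == 1L
    expect_identical(called$strain[one], ora$strain[map[called$status[has_bc] == 1L]])
})

test_that("at zero sequencing error counts equal the generator truth exactly", {
    cfg <- sim_config(n_strains = 80L, seed = 17L, read_depth = 3e4,
                      per_base_error = 0)
    p <- make_strain_panel(cfg)
    pool <- simulate_pool(p, cfg)
    run <- simulate_barseq_run(p, pool, cfg, withr::local_tempdir())
    cm <- count_reads(run$samples, build_index(p))
    expect_identical(array(unclass(cm), dim(cm)),
                     array(run$true_counts, dim(run$true_counts)))
    tot <- attr(cm, "totals")
    expect_true(all(tot$assigned == tot$total))
})

test_that("fitness log2FC has the documented exact properties", {
    counts <- rbind(WT_SPIKE = c(1000, 1000, 1000, 1000),
                    flat = c(500, 500, 500, 500),
                    halved = c(400, 400, 400, 200),
                    doubled = c(300, 300, 300, 600))
    samples <- data.frame(sample_id = paste0("s", 1:4),
                          time_h = c(0, 0, 0, 24))
    fit <- fitness_log2fc(counts, samples = samples, floor_quantile = 0)
    expect_equal(unname(fit["flat", 4L]), 0)
    expect_equal(unname(fit["halved", 4L]), -1)
    expect_equal(unname(fit["doubled", 4L]), 1)
    # t0 columns average to exactly 0 per strain
    expect_equal(unname(rowMeans(fit[, 1:3])), rep(0, 4))
    # wild-type row is identically 0
    expect_equal(unname(fit["WT_SPIKE", ]), rep(0, 4))

    # halving depth (expected counts) leaves the ratios unchanged
    fit2 <- fitness_log2fc(counts / 2, samples = samples, floor_quantile = 0)
    expect_equal(unclass(fit2), unclass(fit), ignore_attr = TRUE)

    # a zero wild-type count is a spike-in failure
    bad <- counts; bad["WT_SPIKE", 2L] <- 0
    expect_error(fitness_log2fc(bad, samples = samples), "spike-in failure")
})

test_that("flooring lifts counts below the pooled t0 quantile", {
    set.seed(5)
    counts <- rbind(WT_SPIKE = rep(5000, 4),
                    matrix(rpois(40 * 4, 100), 40, 4,
                           dimnames = list(sprintf("s%02d", 1:40), NULL)))
    counts["s01", ] <- c(2, 2, 2, 2)
    samples <- data.frame(sample_id = paste0("s", 1:4),
                          time_h = c(0, 0, 0, 24))
    fit <- fitness_log2fc(counts, samples = samples, floor_quantile = 0.05)
    fl <- quantile(as.numeric(counts[, 1:3]), 0.05, names = FALSE)
    expect_equal(attr(fit, "floor"), fl)
    expect_true(all(attr(fit, "floored")["s01", ]))
})

test_that("fitness clustering recovers planted condition patterns", {
    skip_if_no_mclust()
    samples <- data.frame(
        sample_id = c("T0_1", "T0_2", "T0_3", "SC0", "SC100", "YNB0", "YNB100"),
        medium = c("SC", "SC", "SC", "SC", "SC", "YNB", "YNB"),
        dose_nM = c(0, 0, 0, 0, 100, 0, 100),
        time_h = c(0, 0, 0, 36, 36, 48, 48))
    n <- 90L
    truth <- rep(c("neutral", "ynb_dependent", "inducer_toxic"), each = n / 3L)
    prof <- matrix(0, n, 7L, dimnames = list(sprintf("s%02d", 1:n), samples$sample_id))
    prof[truth == "ynb_dependent", "YNB0"] <- -2
    prof[truth == "inducer_toxic", c("SC100", "YNB100")] <- -1.5
    fitness <- structure(prof, class = c("fitness_matrix", "matrix"),
                         samples = samples)
    fc <- cluster_fitness(fitness, k = 3L)
    expect_gte(mclust::adjustedRandIndex(fc$cluster,
                                         truth[match(fc$strain_id, rownames(prof))]),
               0.9)
    pat <- setNames(fc$pattern, fc$strain_id)
    expect_true(all(pat[truth == "ynb_dependent"] == "ynb_dependent"))
    expect_true(all(pat[truth == "inducer_toxic"] == "inducer_toxic"))
    expect_true(all(pat[truth == "neutral"] == "neutral"))
})

test_that("an all-neutral pool forms one dominant flat cluster", {
    samples <- data.frame(sample_id = paste0("s", 1:5),
                          medium = "SC", dose_nM = c(0, 0, 0, 0, 100),
                          time_h = c(0, 0, 0, 24, 24))
    set.seed(10)
    m <- matrix(rnorm(60 * 5, 0, 0.03), 60, 5,
                dimnames = list(sprintf("s%02d", 1:60), samples$sample_id))
    fitness <- structure(m, class = c("fitness_matrix", "matrix"),
                         samples = samples)
    fc <- cluster_fitness(fitness, k = 2L)
    main <- which.max(tabulate(fc$cluster))
    prof <- attr(fc, "cluster_profile")
    expect_true(all(abs(prof[main, ]) < 0.1))

    # duplicated strain rows sit at correlation distance zero
    m2 <- m; m2[2, ] <- m2[1, ]
    fitness2 <- structure(m2, class = c("fitness_matrix", "matrix"),
                          samples = samples)
    fc2 <- cluster_fitness(fitness2, k = 2L)
    expect_identical(fc2$cluster[1L], fc2$cluster[2L])
})
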