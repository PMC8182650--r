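#' Default pooled-growth sample design
#'
#' Three shared time-zero replicates plus one endpoint sample per condition
#' arm (SC/YNB crossed with 0/100 nM inducer). SC arms run to 36 h and YNB
#' arms to 48 h, matching the sampling horizons of the competitive-growth
#' assays the simulator emulates.
#'
#' @return data.frame with `sample_id`, `medium`, `dose_nM`, `time_h`,
#'   `replicate`.
#' @export
barseq_design <- function() {
    data.frame(
        sample_id = c("T0_1", "T0_2", "T0_3",
                      "SC_d0_t36", "SC_d100_t36", "YNB_d0_t48", "YNB_d100_t48"),
        medium = c("SC", "SC", "SC", "SC", "SC", "YNB", "YNB"),
        dose_nM = c(0, 0, 0, 0, 100, 0, 100),
        time_h = c(0, 0, 0, 36, 36, 48, 48),
        replicate = c(1L, 2L, 3L, 1L, 1L, 1L, 1L),
        stringsAsFactors = FALSE
    )
}

#' Plant competitive-fitness trajectories for a strain pool
#'
#' Emulates a pooled culture of the non-essential panel: most strains are
#' neutral; auxotroph-flagged strains deplete in the YNB arm without
#' inducer, and strains with an injected toxicity effect deplete in the
#' 100 nM arms of both media. Depletion grows linearly with culture time to
#' a per-strain endpoint strength (log2 units). Starting abundances are
#' log-normal (a wide, sequencing-library-like spread) with the wild-type
#' spike-in fixed at `config$spike_in_fraction` of cells.
#'
#' @param panel a [make_strain_panel()] panel.
#' @param config a [sim_config()].
#' @param design sample sheet as from [barseq_design()].
#' @return list with `samples`, `weights0` (named t0 cell fractions), and
#'   `expected_lfc` (strains x samples matrix of planted log2 fold-changes
#'   relative to the wild type).
#' @export
simulate_pool <- function(panel, config = sim_config(), design = barseq_design()) {
    validate_strain_panel(panel)
    stopifnot(all(c("sample_id", "medium", "dose_nM", "time_h", "replicate")
                  %in% names(design)))
    set.seed(stage_seed(config$seed, "pool"))
    n <- nrow(panel)
    wt <- which(panel$is_spike_in_wt)

    w0 <- rlnorm(n, meanlog = 0, sdlog = 1.2)
    w0[wt] <- 0
    w0 <- w0 / sum(w0) * (1 - config$spike_in_fraction)
    w0[wt] <- config$spike_in_fraction
    names(w0) <- panel$strain_id

    aux_strength <- ifelse(panel$aux_flag, runif(n, 0.4, 1.0), 0)
    tox_strength <- panel$toxicity_effect

    lfc <- matrix(0, n, nrow(design),
                  dimnames = list(panel$strain_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
        med <- design$medium[j]; dose <- design$dose_nM[j]
        tfrac <- if (design$time_h[j] > 0) {
            tmax <- max(design$time_h[design$medium == med &
                                      design$dose_nM == dose])
            design$time_h[j] / tmax
        } else 0
        phi <- numeric(n)
        if (med == "YNB" && dose == 0) phi <- phi - aux_strength * tfrac
        if (dose > 0) phi <- phi - tox_strength * tfrac
        lfc[, j] <- phi
    }
    lfc[wt, ] <- 0
    list(samples = design, weights0 = w0, expected_lfc = lfc)
}

#' Write simulated BAR-seq FASTQ runs with known true counts
#'
#' For each sample, strain cell fractions are the t0 weights scaled by the
#' planted log2 fold-changes, reads are drawn multinomially at
#' `config$read_depth`, and each read is laid out as
#' `[upstream flank][12-nt barcode][downstream flank][random filler]` with
#' independent per-base substitution errors at `config$per_base_error`.
#' Qualities are constant Phred+33 'I'. True pre-error counts are logged.
#'
#' @param panel a [make_strain_panel()] panel.
#' @param pool result of [simulate_pool()].
#' @param config a [sim_config()].
#' @param dir output directory for FASTQ files.
#' @param read_length total read length (>= 44 + 1 filler base).
#' @return list with `samples` (sample sheet including `fastq_path`),
#'   `true_counts` (strains x samples matrix, pre-error), `expected_lfc`.
#' @export
simulate_barseq_run <- function(panel, pool, config = sim_config(), dir,
                                read_length = 60L) {
    validate_strain_panel(panel)
    flank_len <- nchar(BARSEQ_UP_FLANK) + 12L + nchar(BARSEQ_DOWN_FLANK)
    if (read_length <= flank_len)
        stop("read_length must exceed ", flank_len)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    samples <- pool$samples
    depth <- as.integer(config$read_depth)
    n <- nrow(panel)
    true_counts <- matrix(0L, n, nrow(samples),
                          dimnames = list(panel$strain_id, samples$sample_id))
    paths <- character(nrow(samples))

    for (j in seq_len(nrow(samples))) {
        w <- pool$weights0 * 2^pool$expected_lfc[, j]
        if (sum(w) <= 0) stop("sample ", samples$sample_id[j],
                              " has all-zero abundances")
        set.seed(stage_seed(config$seed, paste0("fastq_", samples$sample_id[j])))
        cnt <- as.integer(rmultinom(1L, depth, w / sum(w)))
        true_counts[, j] <- cnt
        strain_of_read <- sample(rep.int(seq_len(n), cnt))
        reads <- paste0(BARSEQ_UP_FLANK, panel$barcode[strain_of_read],
                        BARSEQ_DOWN_FLANK,
                        random_filler(depth, read_length - flank_len))
        reads <- cpp_mutate_reads(reads, config$per_base_error)
        paths[j] <- file.path(dir, paste0(samples$sample_id[j], ".fastq"))
        write_fastq(reads, paths[j],
                    ids = sprintf("%s_r%07d", samples$sample_id[j],
                                  seq_len(depth)))
    }
    samples$fastq_path <- paths
    list(samples = samples, true_counts = true_counts,
         expected_lfc = pool$expected_lfc)
}

# n random filler strings of the given length, built column-wise so the
# whole block is one vectorized paste
random_filler <- function(n, len) {
    if (len <= 0) return(rep("", n))
    cols <- replicate(len, sample(c("A", "C", "G", "T"), n, replace = TRUE),
                      simplify = FALSE)
    do.call(paste0, cols)
}
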