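#' Build a barcode index for mismatch-tolerant strain assignment
#'
#' Validates that the 12-nt barcodes are unique DNA strings, computes the
#' all-pairs minimum Hamming distance, and records the mismatch budget.
#' Assignment with up to `max_mismatch` mismatches is provably unambiguous
#' only when the minimum distance is at least `2 * max_mismatch + 1`; a
#' warning is emitted otherwise.
#'
#' @param strains data.frame with `strain_id` and `barcode` columns (or a
#'   named character vector of barcodes).
#' @param max_mismatch barcode mismatch budget.
#' @param up_flank,down_flank universal primer sequences flanking the
#'   barcode in each read.
#' @return object of class `barcode_index`.
#' @export
build_index <- function(strains, max_mismatch = 2L,
                        up_flank = BARSEQ_UP_FLANK,
                        down_flank = BARSEQ_DOWN_FLANK) {
    if (is.data.frame(strains)) {
        stopifnot(all(c("strain_id", "barcode") %in% names(strains)))
        ids <- strains$strain_id; bc <- strains$barcode
    } else {
        bc <- unname(strains); ids <- names(strains)
        if (is.null(ids)) stop("barcode vector must be named by strain")
    }
    if (!all(grepl("^[ACGT]+$", bc)))
        stop("barcodes must be DNA strings over A/C/G/T")
    if (length(unique(nchar(bc))) != 1L)
        stop("barcodes must have a single common length")
    dup <- bc[duplicated(bc)]
    if (length(dup)) {
        offenders <- ids[bc %in% dup]
        stop("duplicate barcodes shared by strains: ",
             paste(offenders, collapse = ", "))
    }
    min_dist <- if (length(bc) >= 2L) cpp_min_pairwise_hamming(bc) else NA_integer_
    if (!is.na(min_dist) && min_dist < 2L * max_mismatch + 1L)
        warning("minimum pairwise barcode distance ", min_dist,
                " < ", 2L * max_mismatch + 1L,
                ": assignment at max_mismatch = ", max_mismatch,
                " may be ambiguous")
    structure(list(strain_id = ids, barcode = bc,
                   barcode_length = nchar(bc[1L]),
                   min_pairwise_distance = min_dist,
                   max_mismatch = as.integer(max_mismatch),
                   up_flank = up_flank, down_flank = down_flank),
              class = "barcode_index")
}

#' @export
print.barcode_index <- function(x, ...) {
    cat(sprintf("Barcode index: %d strains, %d-nt barcodes, min distance %s, max mismatch %d\n",
                length(x$strain_id), x$barcode_length,
                x$min_pairwise_distance, x$max_mismatch))
    invisible(x)
}

#' Count strain barcodes in pre-demultiplexed FASTQ samples
#'
#' Per read: the upstream flank is located (up to `flank_mismatch`
#' mismatches, scanning `flank_offset` positions around the expected
#' start), the following barcode is extracted, the downstream flank is
#' verified under the same tolerance, and the barcode is assigned to the
#' unique strain within `max_mismatch` Hamming distance. Reads matching no
#' strain are `unassigned`; reads within the budget of two or more strains
#' are `ambiguous` and discarded (never fractionally assigned). Per-sample
#' totals always satisfy assigned + ambiguous + unassigned = total.
#'
#' @param samples data.frame sample sheet with `sample_id` and
#'   `fastq_path` (optionally `medium`, `dose_nM`, `time_h`, `replicate`,
#'   carried into the result).
#' @param index a [build_index()].
#' @param flank_mismatch mismatches tolerated per flank.
#' @param flank_offset positional slack for the upstream flank.
#' @return object of class `count_matrix`: integer matrix (strains x
#'   samples) with `samples` (metadata) and `totals` (assigned, ambiguous,
#'   unassigned, total per sample) attributes.
#' @export
count_reads <- function(samples, index, flank_mismatch = 1L,
                        flank_offset = 2L) {
    stopifnot(inherits(index, "barcode_index"),
              all(c("sample_id", "fastq_path") %in% names(samples)))
    n <- length(index$strain_id)
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(index$strain_id, samples$sample_id))
    totals <- data.frame(sample_id = samples$sample_id, assigned = 0L,
                         ambiguous = 0L, unassigned = 0L, total = 0L)
    for (j in seq_len(nrow(samples))) {
        reads <- read_fastq(samples$fastq_path[j])$seq
        called <- cpp_call_reads(reads, index$barcode, index$up_flank,
                                 index$down_flank, index$max_mismatch,
                                 as.integer(flank_mismatch),
                                 as.integer(flank_offset))
        assigned <- called$strain[called$status == 1L]
        counts[, j] <- tabulate(assigned, nbins = n)
        totals$assigned[j] <- sum(called$status == 1L)
        totals$ambiguous[j] <- sum(called$status == 2L)
        totals$unassigned[j] <- sum(called$status == 3L)
        totals$total[j] <- length(reads)
        stopifnot(totals$assigned[j] + totals$ambiguous[j] +
                  totals$unassigned[j] == totals$total[j])
    }
    structure(counts, class = c("count_matrix", "matrix"),
              samples = samples, totals = totals)
}

#' @export
print.count_matrix <- function(x, ...) {
    tot <- attr(x, "totals")
    cat(sprintf("Barcode counts: %d strains x %d samples; %.1f%% of reads assigned\n",
                nrow(x), ncol(x), 100 * sum(tot$assigned) / sum(tot$total)))
    invisible(x)
}

#' Competitive fitness as spike-in- and t0-normalized log2 fold-change
#'
#' Counts are floored at the `floor_quantile` quantile of the pooled
#' time-zero count distribution (the sequencing background: depletion
#' below that level is not distinguishable from noise). Each strain's
#' floored count is divided by the wild-type spike-in count in the same
#' sample, and the resulting ratio is normalized to the mean of the
#' time-zero samples on the log2 scale (the geometric mean ratio), so
#' every strain's t0 columns average to exactly 0.
#'
#' @param counts a [count_reads()] matrix; its `samples` attribute (or the
#'   `samples` argument) must flag time-zero samples via `time_h == 0`.
#' @param wt_strain row name of the wild-type spike-in.
#' @param floor_quantile quantile of pooled t0 counts used as the floor;
#'   0 disables flooring.
#' @param samples optional sample sheet overriding the attribute.
#' @return object of class `fitness_matrix`: strains x samples matrix of
#'   log2 fold-changes, with `floor`, `floored` (logical matrix),
#'   `samples` and `wt_strain` attributes. The wild-type row is 0 by
#'   construction.
#' @export
fitness_log2fc <- function(counts, wt_strain = "WT_SPIKE",
                           floor_quantile = 0.05, samples = NULL) {
    samples <- samples %||% attr(counts, "samples")
    if (is.null(samples)) stop("sample metadata required")
    stopifnot(ncol(counts) == nrow(samples), "time_h" %in% names(samples))
    if (!wt_strain %in% rownames(counts))
        stop("wild-type strain '", wt_strain, "' absent from counts")
    t0 <- samples$time_h == 0
    if (!any(t0)) stop("no time-zero samples in the design")
    if (any(counts[wt_strain, ] == 0))
        stop("wild-type spike-in has zero counts in some sample; ",
             "spike-in failure")

    floor_level <- if (floor_quantile > 0) {
        quantile(as.numeric(counts[, t0]), floor_quantile, names = FALSE)
    } else 0
    floored <- counts < floor_level
    cf <- pmax(counts, floor_level)
    r <- sweep(cf, 2L, cf[wt_strain, ], "/")
    l2 <- log2(r)
    baseline <- rowMeans(l2[, t0, drop = FALSE])
    lfc <- l2 - baseline
    structure(lfc, class = c("fitness_matrix", "matrix"),
              floor = floor_level, floored = floored,
              samples = samples, wt_strain = wt_strain)
}

#' Cluster log2 fold-change fitness profiles across samples
#'
#' Hierarchical clustering (correlation distance, average linkage) of
#' strain fitness profiles, cut at `k` clusters. Each cluster is annotated
#' by the condition pattern of its mean profile over the non-t0 samples:
#' `neutral` (no mean depletion beyond `depletion_cutoff`),
#' `ynb_dependent` (depleted only in YNB without inducer, the
#' auxotroph-like signature), `inducer_toxic` (depleted only in induced
#' arms), or `mixed`.
#'
#' @param fitness a [fitness_log2fc()] matrix.
#' @param k number of clusters.
#' @param depletion_cutoff mean log2FC below which a condition arm counts
#'   as depleted.
#' @return data.frame with `strain_id`, `cluster`, `pattern`; cluster
#'   condition summaries in attribute `cluster_profile`.
#' @export
cluster_fitness <- function(fitness, k = 3L, depletion_cutoff = -0.5) {
    samples <- attr(fitness, "samples")
    if (k > nrow(fitness)) stop("k exceeds the number of strains")
    m <- fitness[order(rownames(fitness)), , drop = FALSE]
    v <- apply(m, 1L, stats::sd)
    # zero-variance profiles (flat, typically all-neutral) have no defined
    # correlation; give them a tiny deterministic tilt towards zero profile
    safe <- m
    if (any(v == 0))
        safe[v == 0, ] <- safe[v == 0, , drop = FALSE] +
            matrix(seq_len(ncol(m)) * 1e-9, sum(v == 0), ncol(m),
                   byrow = TRUE)
    d <- as.dist(1 - cor(t(safe)))
    hc <- hclust(d, method = "average")
    cl <- cutree(hc, k = k)

    arm <- ifelse(samples$time_h == 0, "t0",
                  paste0(samples$medium, "_d", samples$dose_nM))
    arms <- setdiff(unique(arm), "t0")
    prof <- t(vapply(seq_len(k), function(ci) {
        rows <- m[cl == ci, , drop = FALSE]
        vapply(arms, function(a) mean(rows[, arm == a, drop = FALSE]),
               numeric(1))
    }, numeric(length(arms))))
    colnames(prof) <- arms; rownames(prof) <- seq_len(k)

    pattern <- apply(prof, 1L, function(p) {
        depleted <- names(p)[p < depletion_cutoff]
        uninduced_ynb <- grepl("^YNB_d0$", depleted)
        induced <- grepl("_d(?!0$)", depleted, perl = TRUE) |
            !grepl("_d0$", depleted)
        if (!length(depleted)) "neutral"
        else if (all(uninduced_ynb)) "ynb_dependent"
        else if (all(induced)) "inducer_toxic"
        else "mixed"
    })
    res <- data.frame(strain_id = rownames(m), cluster = unname(cl),
                      pattern = pattern[cl], stringsAsFactors = FALSE)
    structure(res, class = c("fitness_clusters", "data.frame"),
              cluster_profile = prof, hclust = hc)
}
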