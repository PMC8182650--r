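# Independent oracles and small fixture builders shared across the suite.

# brute-force Hamming distance via character vectors (independent of the
# compiled implementation)
hamming_oracle <- function(a, b) {
    va <- strsplit(a, "")[[1]]
    vb <- strsplit(b, "")[[1]]
    sum(va != vb)
}

min_pairwise_hamming_oracle <- function(barcodes) {
    n <- length(barcodes)
    best <- Inf
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            best <- min(best, hamming_oracle(barcodes[i], barcodes[j]))
    best
}

# vectorized exhaustive Hamming assignment oracle: for each query barcode,
# the number of index barcodes within max_mm and the unique hit if any.
# Implemented with one-hot encodings and matrix products, a route fully
# independent of the compiled per-read scan.
barcode_assign_oracle <- function(queries, barcodes, max_mm = 2L,
                                  chunk = 5000L) {
    enc <- function(x) {
        L <- nchar(x[1L])
        m <- matrix(unlist(strsplit(x, "")), ncol = L, byrow = TRUE)
        do.call(cbind, lapply(c("A", "C", "G", "T"), function(l) m == l)) * 1
    }
    B <- enc(barcodes)
    L <- nchar(barcodes[1L])
    hits <- integer(length(queries))
    strain <- rep(NA_integer_, length(queries))
    for (start in seq(1L, length(queries), by = chunk)) {
        sel <- start:min(start + chunk - 1L, length(queries))
        Q <- enc(queries[sel])
        d <- L - tcrossprod(Q, B)   # Hamming distances, queries x index
        within <- d <= max_mm
        hits[sel] <- rowSums(within)
        one <- hits[sel] == 1L
        strain[sel][one] <- apply(within[one, , drop = FALSE], 1L, which)
    }
    list(hits = hits, strain = strain)
}

# trapezoid rule written out longhand
trapz_oracle <- function(x, y) {
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# small, fast simulation settings reused by several files
tiny_config <- function(...) {
    sim_config(n_strains = 24L, doses = c(0, 1, 10, 100),
               timepoints = seq(0, 24, by = 4), media = "SC",
               read_depth = 2e4, seed = 42L, ...)
}

skip_if_no_mclust <- function() {
    testthat::skip_if_not_installed("mclust")
}
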