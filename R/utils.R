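#' Derive a reproducible per-stage seed from a global seed
#'
#' All stochastic stages draw their seed from the single global seed via a
#' stage-name hash, so stages can be re-run independently without replaying
#' the whole stream. Result always fits a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 9973L
    as.integer((abs(as.numeric(seed)) %% 1e6) * 2011 + h)
}

hill_response <- function(dose, ec50, hill) {
    ifelse(dose <= 0, 0, dose^hill / (dose^hill + ec50^hill))
}

#' Brute-force Hamming distance between two equal-length strings
#' @param a,b character scalars of equal length.
#' @return integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
    va <- strsplit(a, "")[[1]]
    vb <- strsplit(b, "")[[1]]
    stopifnot(length(va) == length(vb))
    sum(va != vb)
}

#' Minimum pairwise Hamming distance of a barcode set
#' @param barcodes character vector of equal-length strings.
#' @return integer minimum all-pairs distance (NA for fewer than 2 strings).
#' @export
min_pairwise_hamming <- function(barcodes) {
    cpp_min_pairwise_hamming(as.character(barcodes))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
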