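#' Area under a growth curve
#'
#' Trapezoidal integral of colony size over time; the scalar growth summary
#' that folds lag, rate and capacity into one number without committing to
#' a parametric curve.
#'
#' @param times hours, strictly increasing.
#' @param sizes sizes on the same grid.
#' @return numeric scalar (dimensionless x h).
#' @export
augc <- function(times, sizes) {
    stopifnot(length(times) == length(sizes), !is.unsorted(times, strictly = TRUE))
    if (length(times) < 2L) return(0)
    pracma::trapz(times, sizes)
}

#' Compute a reference-scaled strain-by-dose AUGC matrix
#'
#' Curves are truncated to their common time window, integrated with
#' [augc()], and each strain's value is divided by the reference strain's
#' AUGC at the same dose. When the reference is missing at a dose the
#' median AUGC of the other strains at that dose is used instead, with a
#' warning; the scaling actually applied is recorded in the matrix
#' attributes.
#'
#' @param curves a [build_curves()] table; must cover a single medium.
#' @param reference_strain strain id used for scaling.
#' @param value_col `"smoothed"` (default) or `"size"`.
#' @return matrix (strains x doses) of class `augc_matrix` with attributes
#'   `reference` (per-dose reference AUGC), `reference_strain`, `medium`,
#'   `n_rep` (replicate counts), `window` (common time window).
#' @export
compute_augc_matrix <- function(curves, reference_strain = "WT_SPIKE",
                                value_col = "smoothed") {
    stopifnot(inherits(curves, "data.frame"),
              value_col %in% names(curves))
    med <- unique(curves$medium)
    if (length(med) != 1L)
        stop("curves span multiple media; filter to one medium first")
    t_lo <- max(tapply(curves$time_h,
                       interaction(curves$strain_id, curves$dose_nM, drop = TRUE),
                       min))
    t_hi <- min(tapply(curves$time_h,
                       interaction(curves$strain_id, curves$dose_nM, drop = TRUE),
                       max))
    if (t_hi <= t_lo) stop("curves share no common time window")
    keep <- curves$time_h >= t_lo & curves$time_h <= t_hi
    curves <- curves[keep, ]

    strains <- sort(unique(curves$strain_id))
    doses <- sort(unique(curves$dose_nM))
    A <- matrix(NA_real_, length(strains), length(doses),
                dimnames = list(strains, as.character(doses)))
    n_rep <- A
    for (s in seq_along(strains)) {
        for (d in seq_along(doses)) {
            cc <- curves[curves$strain_id == strains[s] &
                         curves$dose_nM == doses[d], ]
            if (!nrow(cc)) next
            cc <- cc[order(cc$time_h), ]
            A[s, d] <- augc(cc$time_h, cc[[value_col]])
            n_rep[s, d] <- cc$n_rep[1L]
        }
    }
    ref <- if (reference_strain %in% strains) {
        A[reference_strain, ]
    } else {
        warning("reference strain '", reference_strain,
                "' absent; falling back to per-dose median AUGC")
        apply(A, 2L, median, na.rm = TRUE)
    }
    bad <- !is.finite(ref) | ref <= 0
    if (any(bad)) {
        warning("reference AUGC missing or zero at ",
                sum(bad), " dose(s); per-dose median used there")
        ref[bad] <- apply(A[, bad, drop = FALSE], 2L, median, na.rm = TRUE)
    }
    scaled <- sweep(A, 2L, ref, "/")
    structure(scaled, class = c("augc_matrix", "matrix"),
              reference = ref, reference_strain = reference_strain,
              medium = med, n_rep = n_rep, window = c(t_lo, t_hi))
}

#' @export
print.augc_matrix <- function(x, ...) {
    cat(sprintf("AUGC matrix: %d strains x %d doses (%s), window %g-%g h, ref '%s'\n",
                nrow(x), ncol(x), attr(x, "medium"),
                attr(x, "window")[1], attr(x, "window")[2],
                attr(x, "reference_strain")))
    invisible(x)
}
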