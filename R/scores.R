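#' Aux scores: inducer benefit on minimal relative to complete medium
#'
#' For strain i with total growth G measured on minimal medium (YNB, M) and
#' complete medium (SC, R) at 0 and 1 nM inducer,
#' `Aux score_i = (G_iM1 / G_iM0) / (G_iR1 / G_iR0)`: the fold-benefit of
#' induction on minimal medium divided by the fold-benefit on complete
#' medium. Strains indifferent to the inducer score 1; auxotroph-like
#' strains, which need the induced gene product only on minimal medium,
#' score well above 1. The score is invariant to any per-strain rescaling
#' of growth units.
#'
#' Zero growth totals are floored to `pseudogrowth` (and flagged) so the
#' ratio stays defined; strains missing any of the four conditions are
#' dropped with a warning.
#'
#' @param growth data.frame with columns `strain_id`, `G_M0`, `G_M1`,
#'   `G_R0`, `G_R1` (total growth on YNB/SC at 0/1 nM).
#' @param pseudogrowth floor applied to nonpositive growth totals.
#' @return data.frame sorted by decreasing `aux_score`, with the four
#'   (floored) growth totals and a `floored` flag.
#' @export
aux_scores <- function(growth, pseudogrowth = 1) {
    need <- c("strain_id", "G_M0", "G_M1", "G_R0", "G_R1")
    stopifnot(all(need %in% names(growth)))
    gcols <- need[-1L]
    complete <- stats::complete.cases(growth[, gcols])
    if (any(!complete)) {
        warning(sum(!complete), " strain(s) omitted: missing growth totals")
        growth <- growth[complete, ]
    }
    floored <- rep(FALSE, nrow(growth))
    for (cc in gcols) {
        low <- growth[[cc]] <= 0
        floored <- floored | low
        growth[[cc]][low] <- pseudogrowth
    }
    out <- data.frame(strain_id = growth$strain_id,
                      growth[, gcols],
                      aux_score = (growth$G_M1 / growth$G_M0) /
                                  (growth$G_R1 / growth$G_R0),
                      floored = floored,
                      stringsAsFactors = FALSE)
    out[order(-out$aux_score), , drop = FALSE]
}

#' Call overexpression toxicity from growth at 0 versus 100 nM inducer
#'
#' Growth at 100 nM (`y`) is first corrected for any systematic, non-toxic
#' effect of the inducer: strains at the growth extremes (top `trim_top`
#' and bottom `trim_bottom` quantiles of either axis) are removed, an OLS
#' line `y = m x + b` is fit to the remainder, and every strain's
#' `y_corrected = (y - b) / m` maps the 100 nM measurement back onto the
#' 0 nM scale. Toxicity is then the perpendicular distance from the
#' diagonal `y_corrected = x`,
#' `distance = |a x + b_line y_corrected + c| / sqrt(a^2 + b_line^2)` with
#' `(a, b_line, c) = (1, -1, 0)`; a strain is toxic when the distance
#' exceeds `threshold` (in the same size units as the inputs) *and* it
#' lies below the diagonal (reduced growth under induction). Strains above
#' the diagonal are never flagged.
#'
#' @param x growth at 0 nM per strain.
#' @param y growth at 100 nM per strain.
#' @param strain_id optional strain identifiers.
#' @param trim_top,trim_bottom extreme-growth trim fractions applied to
#'   each axis separately (union removed) before fitting.
#' @param threshold diagonal-distance cutoff for the toxic call.
#' @return data.frame of class `toxicity_calls` with `x`, `y`,
#'   `y_corrected`, `distance`, `used_in_fit`, `toxic_flag`; fit
#'   coefficients in attributes `m`, `b`.
#' @export
toxicity_call <- function(x, y, strain_id = NULL, trim_top = 0.02,
                          trim_bottom = 0.04, threshold = 2000) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 50L) stop("need at least 50 strains for a stable linear fit")
    if (is.null(strain_id)) strain_id <- sprintf("STR%05d", seq_len(n))

    lo_x <- quantile(x, trim_bottom); hi_x <- quantile(x, 1 - trim_top)
    lo_y <- quantile(y, trim_bottom); hi_y <- quantile(y, 1 - trim_top)
    used <- x > lo_x & x < hi_x & y > lo_y & y < hi_y
    fit <- lm(yy ~ xx, data = data.frame(xx = x[used], yy = y[used]))
    b <- unname(coef(fit)[1L]); m <- unname(coef(fit)[2L])
    if (!is.finite(m) || m <= 0)
        stop("degenerate toxicity fit: slope m = ", signif(m, 3),
             " (expected a positive 0 vs 100 nM relationship)")

    y_corrected <- (y - b) / m
    a <- 1; b_line <- -1; c0 <- 0
    distance <- abs(a * x + b_line * y_corrected + c0) / sqrt(a^2 + b_line^2)
    toxic <- distance > threshold & y_corrected < x
    res <- data.frame(strain_id = strain_id, x = x, y = y,
                      y_corrected = y_corrected, distance = distance,
                      used_in_fit = used, toxic_flag = toxic,
                      stringsAsFactors = FALSE)
    structure(res, class = c("toxicity_calls", "data.frame"),
              m = m, b = b, threshold = threshold,
              trim = c(top = trim_top, bottom = trim_bottom))
}

#' @export
print.toxicity_calls <- function(x, ...) {
    cat(sprintf("Toxicity calls: %d/%d toxic (fit y = %.3f x + %.1f, threshold %g)\n",
                sum(x$toxic_flag), nrow(x), attr(x, "m"), attr(x, "b"),
                attr(x, "threshold")))
    invisible(x)
}

#' Classify reversibility of a growth phenotype after inducer removal
#'
#' Ratio of growth without inducer to growth with inducer, classed by the
#' printed cutoffs: ratio <= 0.55 reversible; 0.55 < ratio <= 0.75
#' partially reversible; ratio > 0.75 not reversible. A zero `growth_with`
#' leaves the ratio undefined and the class flagged `undefined`.
#'
#' @param growth_without growth after transfer to inducer-free medium.
#' @param growth_with growth under continued induction.
#' @param strain_id optional identifiers.
#' @return data.frame with `ratio` and `class`.
#' @export
classify_reversibility <- function(growth_without, growth_with,
                                   strain_id = NULL) {
    stopifnot(length(growth_without) == length(growth_with))
    if (is.null(strain_id))
        strain_id <- sprintf("STR%05d", seq_along(growth_with))
    ratio <- ifelse(growth_with > 0, growth_without / growth_with, NA_real_)
    cls <- ifelse(is.na(ratio), "undefined",
           ifelse(ratio <= 0.55, "reversible",
           ifelse(ratio <= 0.75, "partially_reversible", "not_reversible")))
    data.frame(strain_id = strain_id, ratio = ratio, class = cls,
               stringsAsFactors = FALSE)
}

#' Classify inducer dependence from an AUGC dose profile
#'
#' `no_growth` when the profile never reaches `growth_floor`; otherwise
#' the ratio of AUGC at dose 0 to the profile maximum decides:
#' `constitutive` at or above `high_cutoff`, `dependent` at or below
#' `low_cutoff`, `partially_dependent` in between.
#'
#' @param augc_profile AUGC values over the dose grid.
#' @param doses matching dose grid; must contain 0 and at least one other
#'   dose.
#' @param growth_floor absolute AUGC floor below which nothing grew.
#' @param low_cutoff,high_cutoff ratio cutoffs.
#' @return list with `class`, `ratio`, and the cutoffs applied.
#' @export
classify_dependence <- function(augc_profile, doses, growth_floor = 0.1,
                                low_cutoff = 0.25, high_cutoff = 0.75) {
    stopifnot(length(augc_profile) == length(doses))
    if (length(doses) < 2L) stop("a single-dose profile cannot be classified")
    if (!any(doses == 0)) stop("dose 0 must be present")
    peak <- max(augc_profile, na.rm = TRUE)
    if (!is.finite(peak) || peak < growth_floor)
        return(list(class = "no_growth", ratio = NA_real_,
                    cutoffs = c(low = low_cutoff, high = high_cutoff,
                                floor = growth_floor)))
    ratio <- augc_profile[doses == 0][1L] / peak
    cls <- if (ratio >= high_cutoff) "constitutive"
           else if (ratio <= low_cutoff) "dependent"
           else "partially_dependent"
    list(class = cls, ratio = unname(ratio),
         cutoffs = c(low = low_cutoff, high = high_cutoff,
                     floor = growth_floor))
}

#' Call synthetic dosage lethality from replicated two-dose colony sizes
#'
#' Per replicate screen, the score is `log2(size_1000 / size_0)` (set
#' `score = "ratio_minus_1"` for the alternative `ratio - 1` scale); an
#' interaction is called only when the score falls below `cutoff` in every
#' replicate. Replicates with a zero denominator leave the strain excluded
#' and flagged.
#'
#' @param size_1000 matrix (strains x replicates) of normalized colony
#'   sizes at 1,000 nM inducer; a vector is treated as one replicate.
#' @param size_0 matching sizes at 0 nM.
#' @param strain_id optional identifiers.
#' @param cutoff score cutoff for the call.
#' @param score scoring scale.
#' @return data.frame with per-replicate scores, `sdl_flag` and
#'   `undefined_flag`.
#' @export
sdl_call <- function(size_1000, size_0, strain_id = NULL, cutoff = -0.08,
                     score = c("log2_ratio", "ratio_minus_1")) {
    score <- match.arg(score)
    size_1000 <- as.matrix(size_1000); size_0 <- as.matrix(size_0)
    stopifnot(all(dim(size_1000) == dim(size_0)))
    n <- nrow(size_1000); nrep <- ncol(size_1000)
    if (is.null(strain_id)) strain_id <- sprintf("STR%05d", seq_len(n))

    ratio <- size_1000 / size_0
    ratio[size_0 <= 0] <- NA_real_
    sc <- if (score == "log2_ratio") log2(ratio) else ratio - 1
    undefined <- apply(sc, 1L, anyNA)
    sdl <- !undefined & apply(sc < cutoff, 1L, all)
    out <- data.frame(strain_id = strain_id, sc,
                      sdl_flag = sdl, undefined_flag = undefined,
                      stringsAsFactors = FALSE)
    names(out)[1L + seq_len(nrep)] <- sprintf("score_rep%d", seq_len(nrep))
    attr(out, "cutoff") <- cutoff
    attr(out, "score") <- score
    out
}
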