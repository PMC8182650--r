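#' Association between native expression and growth without inducer
#'
#' Bins strains into equal-count bins on log native expression, compares
#' the AUGC distributions of the lowest and highest bins with a two-sample
#' Kolmogorov-Smirnov test, reports the Spearman correlation on the
#' unbinned pairs, and runs a two-sided t-test between configurable
#' expression quantile groups (bottom vs top decile by default).
#'
#' @param augc_values per-strain AUGC at one dose (typically 0 nM).
#' @param expression matched native expression values (> 0, TPM).
#' @param n_bins number of equal-count expression bins.
#' @param group_quantiles two quantiles defining the t-test groups.
#' @param min_bin_size refuse binned statistics below this per-bin count.
#' @return object of class `association_result`: `bins` (per-bin n, median
#'   AUGC, expression range), `ks` (statistic, p.value), `spearman` (rho,
#'   p.value), `ttest` (statistic, p.value, group sizes).
#' @export
expression_association <- function(augc_values, expression, n_bins = 6L,
                                   group_quantiles = c(0.1, 0.9),
                                   min_bin_size = 10L) {
    stopifnot(length(augc_values) == length(expression))
    ok <- is.finite(augc_values) & is.finite(expression)
    augc_values <- augc_values[ok]; expression <- expression[ok]
    if (any(expression <= 0))
        stop("expression must be positive for log-scale binning")
    le <- log(expression)
    breaks <- quantile(le, probs = seq(0, 1, length.out = n_bins + 1L),
                       names = FALSE)
    breaks[1L] <- breaks[1L] - 1e-9
    bin <- cut(le, breaks = unique(breaks), include.lowest = TRUE,
               labels = FALSE)
    counts <- tabulate(bin, nbins = max(bin))
    if (length(counts) < n_bins || any(counts < min_bin_size))
        stop("fewer than ", min_bin_size,
             " strains in some expression bin; refusing binned statistics")

    ks <- suppressWarnings(ks.test(augc_values[bin == 1L],
                                   augc_values[bin == n_bins]))
    sp <- suppressWarnings(cor.test(expression, augc_values,
                                    method = "spearman", exact = FALSE))
    qs <- quantile(expression, group_quantiles, names = FALSE)
    g_lo <- augc_values[expression <= qs[1L]]
    g_hi <- augc_values[expression >= qs[2L]]
    tt <- t.test(g_lo, g_hi)

    bins <- data.frame(bin = seq_len(n_bins), n = counts,
                       expr_min = exp(breaks[-length(breaks)]),
                       expr_max = exp(breaks[-1L]),
                       median_augc = vapply(seq_len(n_bins), function(b)
                           median(augc_values[bin == b]), numeric(1)))
    structure(list(bins = bins,
                   ks = list(statistic = unname(ks$statistic),
                             p.value = ks$p.value),
                   spearman = list(rho = unname(sp$estimate),
                                   p.value = sp$p.value),
                   ttest = list(statistic = unname(tt$statistic),
                                p.value = tt$p.value,
                                n = c(length(g_lo), length(g_hi)),
                                group_quantiles = group_quantiles)),
              class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
    cat(sprintf("Expression-growth association: KS D=%.3f (p=%.3g), Spearman rho=%.3f (p=%.3g)\n",
                x$ks$statistic, x$ks$p.value,
                x$spearman$rho, x$spearman$p.value))
    cat(sprintf("  t-test between expression deciles: t=%.2f (p=%.3g)\n",
                x$ttest$statistic, x$ttest$p.value))
    invisible(x)
}

#' Linear fit of maximum induced expression against native expression
#'
#' Ordinary least squares of maximum induced TPM on native TPM, restricted
#' to genes whose native expression is below `cutoff` (the regime where
#' the synthetic promoter's output scales with the native level); genes at
#' or above the cutoff are excluded and reported.
#'
#' @param max_induced maximum induced expression per gene (TPM).
#' @param native native expression per gene (TPM).
#' @param cutoff native-expression cutoff (TPM).
#' @return list with `slope`, `intercept`, `r_squared`, `n_used`,
#'   `excluded` (indices at/above cutoff), and the `lm` fit.
#' @export
fit_expression_linear <- function(max_induced, native, cutoff = 250) {
    stopifnot(length(max_induced) == length(native))
    use <- which(native < cutoff)
    if (!length(use)) stop("all genes are at or above the native-expression cutoff")
    if (length(use) < 3L) stop("need at least 3 genes below the cutoff")
    fit <- lm(y ~ x, data = data.frame(x = native[use], y = max_induced[use]))
    r2 <- if (stats::var(max_induced[use]) == 0) 0 else summary(fit)$r.squared
    list(slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         r_squared = r2,
         n_used = length(use),
         excluded = setdiff(seq_along(native), use),
         fit = fit)
}
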