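#' Assemble colony size series into smoothed growth curves
#'
#' Replicate colonies are pooled per (strain, medium, dose) and a LOESS
#' smoother (degree 2, configurable span) is fit over the pooled points;
#' negative smoothed values are clipped to 0. Groups with fewer than three
#' distinct timepoints cannot be smoothed: they are flagged and carry the
#' per-time replicate means instead.
#'
#' @param tab colony-size table with columns `strain_id`, `medium`,
#'   `dose_nM`, `time_h` and a size column.
#' @param size_col which size column to use.
#' @param span LOESS span.
#' @return data.frame of class `growth_curves`: one row per (strain,
#'   medium, dose, time) with `size` (replicate mean), `smoothed`, `n_rep`
#'   (colonies pooled) and `smoothed_ok`.
#' @export
build_curves <- function(tab, size_col = "normalized_size", span = 0.5) {
    stopifnot(all(c("strain_id", "medium", "dose_nM", "time_h", size_col)
                  %in% names(tab)))
    tab <- tab[!is.na(tab[[size_col]]), ]
    if (!nrow(tab)) stop("no usable size measurements to build curves from")
    key <- interaction(tab$strain_id, tab$medium, tab$dose_nM, drop = TRUE)
    groups <- sort(unique(as.character(key)))
    out <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
        g <- tab[as.character(key) == groups[gi], ]
        g <- g[order(g$time_h), ]
        times <- sort(unique(g$time_h))
        mean_size <- vapply(times, function(t)
            mean(g[[size_col]][g$time_h == t]), numeric(1))
        n_rep <- as.integer(round(nrow(g) / length(times)))
        if (length(times) < 3L) {
            smoothed <- mean_size
            ok <- FALSE
        } else {
            fit <- try(loess(y ~ t, data = data.frame(t = g$time_h,
                                                      y = g[[size_col]]),
                             span = span, degree = 2,
                             family = "gaussian"), silent = TRUE)
            if (inherits(fit, "try-error")) {
                smoothed <- mean_size
                ok <- FALSE
            } else {
                smoothed <- pmax(predict(fit, newdata = data.frame(t = times)), 0)
                ok <- TRUE
            }
        }
        out[[gi]] <- data.frame(strain_id = g$strain_id[1L],
                                medium = g$medium[1L],
                                dose_nM = g$dose_nM[1L],
                                time_h = times, size = mean_size,
                                smoothed = smoothed, n_rep = n_rep,
                                smoothed_ok = ok, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("growth_curves", "data.frame")
    res
}
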