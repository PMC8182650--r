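#' Normalize colony sizes for plate, positional and competition effects
#'
#' Applied per plate image, i.e. per (`plate_id`, `time_h`):
#'
#' 1. plate effect — divide by the plate's median measurable colony size
#'    over interior positions;
#' 2. positional effect — divide by a moving-window median surface over
#'    grid neighborhoods (`spatial_window` cells square) and then by row
#'    and column medians;
#' 3. competition effect — colonies with at least `dead_neighbors` dead
#'    (8-neighborhood) neighbors are capped at the local window median, so
#'    colonies inflated by dead neighbors cannot dominate;
#' 4. edges — perimeter row/column colonies are flagged `edge_flag` and
#'    `excluded_flag`; they still receive a normalized size (the border
#'    carries the reference strain, which later stages use for scaling)
#'    but are excluded from downstream statistics.
#'
#' The interior median of normalized sizes is re-scaled to exactly 1, and
#' the whole pipeline is invariant to a global rescaling of the plate's
#' sizes. A plate image with under half of its interior positions
#' measurable is flagged `low_quality_flag` with a warning (an expected
#' state for early timepoints and for no-inducer plates full of dependent
#' strains, so low quality marks rather than excludes).
#'
#' @param tab raw colony-size table as from [quantify_plate()] (rows for
#'   one or more plates/timepoints), needing columns `plate_id`, `time_h`,
#'   `row`, `col`, `raw_size`.
#' @param spatial_window moving-median window size in grid cells (odd).
#' @param dead_threshold normalized size below which a colony counts as
#'   dead.
#' @param dead_neighbors dead-neighbor count triggering the competition cap.
#' @return the input with `normalized_size`, `edge_flag`, `excluded_flag`
#'   and `low_quality_flag` columns added.
#' @export
normalize_sizes <- function(tab, spatial_window = 7L, dead_threshold = 0.1,
                            dead_neighbors = 3L) {
    stopifnot(all(c("plate_id", "time_h", "row", "col", "raw_size") %in%
                  names(tab)))
    if (spatial_window %% 2L != 1L) stop("spatial_window must be odd")
    tab$normalized_size <- NA_real_
    tab$edge_flag <- FALSE
    tab$excluded_flag <- FALSE
    tab$low_quality_flag <- FALSE
    key <- paste(tab$plate_id, tab$time_h)
    for (k in unique(key)) {
        idx <- which(key == k)
        res <- normalize_one_plate(tab[idx, ], spatial_window,
                                   dead_threshold, dead_neighbors)
        tab$normalized_size[idx] <- res$normalized_size
        tab$edge_flag[idx] <- res$edge_flag
        tab$excluded_flag[idx] <- res$excluded_flag
        tab$low_quality_flag[idx] <- res$low_quality_flag
    }
    tab
}

normalize_one_plate <- function(p, spatial_window, dead_threshold,
                                dead_neighbors) {
    nr <- max(p$row) + 1L; nc <- max(p$col) + 1L
    m <- matrix(NA_real_, nr, nc)
    m[cbind(p$row + 1L, p$col + 1L)] <- p$raw_size
    edge <- matrix(row(m) %in% c(1L, nr) | col(m) %in% c(1L, nc), nr, nc)
    interior_meas <- !edge & !is.na(m) & m > 0
    low_quality <- FALSE
    if (sum(interior_meas) < 0.5 * sum(!edge)) {
        warning("plate ", p$plate_id[1L], " t=", p$time_h[1L],
                ": under 50% measurable interior colonies; marked low-quality")
        low_quality <- TRUE
    }

    plate_med <- median(m[interior_meas])
    s <- if (isTRUE(plate_med > 0)) m / plate_med else m * NA_real_

    if (isTRUE(plate_med > 0) && any(interior_meas)) {
        # median filter captures the smooth spatial trend; the wider mean
        # filter steadies the residual jitter of the windowed medians so
        # that per-colony biology is not divided out
        surf <- moving_mean(moving_median(s, spatial_window),
                            spatial_window + 2L)
        ok <- !is.na(surf) & surf > 0
        s[ok] <- s[ok] / surf[ok]
        # row/column artifacts (failed pin rows, agar ridges, surface
        # boundary lag) are corrected only when the row/col median deviates
        # from 1 by more than ~2 standard errors of that median, so
        # sampling jitter on plates with real per-colony spread is left
        # alone
        s <- s / rc_factor(s, 1L)
        s <- sweep(s, 2L, rc_factor(s, 2L), "/")

        dead <- !is.na(s) & s < dead_threshold
        ndead <- neighbor_count(dead)
        capped <- which(!is.na(s) & ndead >= dead_neighbors)
        if (length(capped)) {
            live_med <- moving_median(ifelse(dead, NA, s), spatial_window)
            cap <- live_med[capped]
            s[capped] <- pmin(s[capped], ifelse(is.na(cap), s[capped], cap))
        }

        final_med <- median(s[!edge & !is.na(s) & s > 0])
        if (isTRUE(final_med > 0)) s <- s / final_med
    }

    pos <- cbind(p$row + 1L, p$col + 1L)
    list(normalized_size = s[pos],
         edge_flag = edge[pos],
         excluded_flag = edge[pos],
         low_quality_flag = rep(low_quality, nrow(p)))
}

# NA-aware moving median over a w x w cell neighborhood
moving_median <- function(m, w) {
    nr <- nrow(m); nc <- ncol(m)
    h <- (w - 1L) %/% 2L
    offs <- expand.grid(dy = -h:h, dx = -h:h)
    stack <- array(NA_real_, dim = c(nr, nc, nrow(offs)))
    for (o in seq_len(nrow(offs))) {
        dy <- offs$dy[o]; dx <- offs$dx[o]
        ys <- seq_len(nr) + dy; xs <- seq_len(nc) + dx
        oky <- ys >= 1L & ys <= nr; okx <- xs >= 1L & xs <= nc
        stack[oky, okx, o] <- m[ys[oky], xs[okx]]
    }
    apply(stack, c(1L, 2L), function(v) {
        v <- v[!is.na(v) & v > 0]
        if (length(v)) median(v) else NA_real_
    })
}

# significant row (margin = 1) or column (margin = 2) median factors;
# medians within ~2 standard errors of 1 are treated as sampling noise
rc_factor <- function(s, margin, z = 2) {
    med <- apply(s, margin, function(v) {
        v <- v[!is.na(v) & v > 0]
        if (length(v) < 3L) return(1)
        m <- median(v)
        se <- 1.2533 * mad(v) / (m * sqrt(length(v)))
        if (!is.finite(m) || m <= 0 || abs(m - 1) <= z * se) 1 else m
    })
    med
}

# NA-aware moving mean over a w x w cell neighborhood
moving_mean <- function(m, w) {
    nr <- nrow(m); nc <- ncol(m)
    h <- (w - 1L) %/% 2L
    acc <- matrix(0, nr, nc)
    cnt <- matrix(0, nr, nc)
    for (dy in -h:h) for (dx in -h:h) {
        ys <- seq_len(nr) + dy; xs <- seq_len(nc) + dx
        oky <- ys >= 1L & ys <= nr; okx <- xs >= 1L & xs <= nc
        v <- m[ys[oky], xs[okx], drop = FALSE]
        ok <- !is.na(v)
        acc[oky, okx][ok] <- acc[oky, okx][ok] + v[ok]
        cnt[oky, okx] <- cnt[oky, okx] + ok
    }
    out <- acc / cnt
    out[cnt == 0] <- NA_real_
    out
}

# count of TRUE values among the 8 neighbors of each cell
neighbor_count <- function(b) {
    nr <- nrow(b); nc <- ncol(b)
    out <- matrix(0L, nr, nc)
    for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        ys <- seq_len(nr) + dy; xs <- seq_len(nc) + dx
        oky <- ys >= 1L & ys <= nr; okx <- xs >= 1L & xs <= nc
        out[oky, okx] <- out[oky, okx] + b[ys[oky], xs[okx]]
    }
    out
}
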