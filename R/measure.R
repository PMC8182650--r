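#' Measure colony sizes as pixels above an adaptive local threshold
#'
#' For each grid cell, background and contrast are estimated from a window
#' spanning `window_factor` grid pitches around the cell center (low and
#' high quantiles of the window intensities); the threshold sits a fixed
#' fraction of the local contrast above the local background, which makes
#' raw sizes invariant to constant intensity offsets. A cell whose window
#' shows no contrast (below `min_contrast`) is scored 0 rather than
#' thresholding pure noise.
#'
#' @param image 2-D grayscale matrix in `[0, 1]`.
#' @param grid a [detect_grid()] model.
#' @param window_factor background-window half-size in grid pitches.
#' @param min_contrast minimum local contrast for a cell to be scored.
#' @param thr_frac threshold position as a fraction of local contrast.
#' @return data.frame with `row`, `col` (0-based, origin top-left) and
#'   `raw_size` (pixel count).
#' @export
measure_colonies <- function(image, grid, window_factor = 2,
                             min_contrast = 0.08, thr_frac = 0.5) {
    stopifnot(inherits(grid, "grid_model"))
    H <- nrow(image); W <- ncol(image)
    hw_r <- floor(grid$pitch_row / 2); hw_c <- floor(grid$pitch_col / 2)
    big_r <- ceiling(window_factor * grid$pitch_row)
    big_c <- ceiling(window_factor * grid$pitch_col)
    out <- expand.grid(row = 0:(grid$n_rows - 1L), col = 0:(grid$n_cols - 1L),
                       KEEP.OUT.ATTRS = FALSE)
    out$raw_size <- 0L
    for (k in seq_len(nrow(out))) {
        cy <- grid$row_centers[out$row[k] + 1L]
        cx <- grid$col_centers[out$col[k] + 1L]
        if (cy < 1 || cy > H || cx < 1 || cx > W)
            stop("grid cell center outside image at row ", out$row[k],
                 ", col ", out$col[k])
        wy <- max(1L, round(cy - big_r)):min(H, round(cy + big_r))
        wx <- max(1L, round(cx - big_c)):min(W, round(cx + big_c))
        win <- image[wy, wx]
        qs <- quantile(win, c(0.10, 0.995), names = FALSE)
        contrast <- qs[2] - qs[1]
        if (contrast < min_contrast) next
        thr <- qs[1] + thr_frac * contrast
        cy_rng <- max(1L, round(cy - hw_r)):min(H, round(cy + hw_r))
        cx_rng <- max(1L, round(cx - hw_c)):min(W, round(cx + hw_c))
        out$raw_size[k] <- sum(image[cy_rng, cx_rng] > thr)
    }
    out
}

#' Quantify one plate image into a raw colony-size table
#'
#' Convenience wrapper: [detect_grid()] then [measure_colonies()], with the
#' plate's metadata attached in the output schema shared by the whole
#' pipeline.
#'
#' @param image 2-D grayscale matrix, or a TIFF/PNG file path.
#' @param n_rows,n_cols expected grid dimensions.
#' @param plate_id,medium,dose_nM,time_h plate metadata.
#' @param grid optional pre-detected [detect_grid()] model (reused across
#'   the timepoints of one plate, whose early images may be too empty for
#'   detection).
#' @param ... passed to [measure_colonies()].
#' @return data.frame with columns `plate_id`, `medium`, `dose_nM`,
#'   `time_h`, `row`, `col`, `raw_size`.
#' @export
quantify_plate <- function(image, n_rows, n_cols, plate_id = "plate1",
                           medium = "SC", dose_nM = 0, time_h = 0,
                           grid = NULL, ...) {
    if (is.character(image)) image <- read_plate_image(image)
    if (is.null(grid)) grid <- detect_grid(image, n_rows, n_cols)
    tab <- measure_colonies(image, grid, ...)
    data.frame(plate_id = plate_id, medium = medium, dose_nM = dose_nM,
               time_h = time_h, tab, stringsAsFactors = FALSE)
}

#' Read a grayscale plate image from TIFF or PNG
#' @param path image file.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_plate_image <- function(path) {
    img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        tiff::readTIFF(path)
    } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
            stop("the 'png' package is required to read PNG images")
        png::readPNG(path)
    } else stop("unsupported image format: ", path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
}
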