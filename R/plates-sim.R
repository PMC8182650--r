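#' Grid dimensions of a colony plate format
#' @param format 384 (16 x 24) or 1536 (32 x 48).
#' @return list with `n_rows`, `n_cols`.
#' @export
plate_layout <- function(format = 384) {
    format <- as.integer(format)
    if (format == 384L) return(list(n_rows = 16L, n_cols = 24L))
    if (format == 1536L) return(list(n_rows = 32L, n_cols = 48L))
    stop("unsupported plate format: ", format, " (use 384 or 1536)")
}

#' Array strains onto one or more plates, wild type on the perimeter
#'
#' Interior positions are filled row-major with (strain, replicate) pairs,
#' spilling onto additional array plates when one plate's interior is not
#' enough; every perimeter position of every plate carries the reference
#' wild-type strain, the convention that lets downstream normalization
#' exclude edges while the growth-curve stage still finds a same-plate
#' reference.
#'
#' @param strain_ids strains to array (excluding the border reference).
#' @param layout a [plate_layout()].
#' @param n_replicates replicate positions per strain.
#' @param reference_strain strain id used for the border positions.
#' @return data.frame `array` (1-based array-plate index), `row`, `col`
#'   (0-based, origin top-left), `strain_id`, `replicate` (0 for border
#'   reference colonies).
#' @export
plate_map <- function(strain_ids, layout, n_replicates = 4L,
                      reference_strain = "WT_SPIKE") {
    nr <- layout$n_rows; nc <- layout$n_cols
    pos <- expand.grid(row = 0:(nr - 1L), col = 0:(nc - 1L),
                       KEEP.OUT.ATTRS = FALSE)
    edge <- pos$row %in% c(0L, nr - 1L) | pos$col %in% c(0L, nc - 1L)
    interior <- pos[!edge, ]
    interior <- interior[order(interior$row, interior$col), ]
    per_plate <- nrow(interior) %/% n_replicates
    if (per_plate < 1L)
        stop(sprintf("%d replicates exceed the %d interior positions",
                     n_replicates, nrow(interior)))
    chunks <- split(strain_ids,
                    ceiling(seq_along(strain_ids) / per_plate))
    out <- vector("list", length(chunks))
    for (a in seq_along(chunks)) {
        want <- expand.grid(replicate = seq_len(n_replicates),
                            strain_id = chunks[[a]],
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        filled <- interior[seq_len(nrow(want)), ]
        out[[a]] <- rbind(
            data.frame(array = a, row = filled$row, col = filled$col,
                       strain_id = want$strain_id,
                       replicate = want$replicate,
                       stringsAsFactors = FALSE),
            data.frame(array = a, row = pos$row[edge], col = pos$col[edge],
                       strain_id = reference_strain, replicate = 0L,
                       stringsAsFactors = FALSE)
        )
    }
    do.call(rbind, out)
}

#' Render one plate image from a matrix of colony areas
#'
#' Colonies are drawn as near-circular domed intensity disks on a flat
#' background with an optional smooth left-to-right gradient and i.i.d.
#' Gaussian pixel noise. A pixel belongs to a colony when its centre falls
#' inside the disk of the requested area, and the exact rendered pixel
#' count is returned as ground truth.
#'
#' @param areas n_rows x n_cols matrix of colony areas in pixels (0 = empty).
#' @param pitch grid pitch in pixels.
#' @param bg background intensity in `[0, 1]`.
#' @param fg colony plateau intensity.
#' @param dome extra intensity at the colony centre.
#' @param gradient background intensity increase from left to right edge.
#' @param pixel_noise standard deviation of additive pixel noise.
#' @return list with `image` (matrix in `[0, 1]`), `truth` (data.frame
#'   `row`, `col`, `true_pixel_area`, 0-based coordinates), `row_centers`,
#'   `col_centers`, `pitch`.
#' @export
render_plate_image <- function(areas, pitch = 20L, bg = 0.1, fg = 0.6,
                               dome = 0.15, gradient = 0.05,
                               pixel_noise = 0.02) {
    stopifnot(is.matrix(areas), all(areas >= 0))
    nr <- nrow(areas); nc <- ncol(areas)
    margin <- pitch
    H <- nr * pitch + 2L * margin
    W <- nc * pitch + 2L * margin
    row_centers <- margin + (seq_len(nr) - 0.5) * pitch
    col_centers <- margin + (seq_len(nc) - 0.5) * pitch

    img <- matrix(bg, H, W) +
        matrix(gradient * (seq_len(W) - 1) / (W - 1), H, W, byrow = TRUE)

    rmax <- 0.45 * pitch
    radius <- pmin(sqrt(areas / pi), rmax)
    truth <- expand.grid(row = 0:(nr - 1L), col = 0:(nc - 1L),
                         KEEP.OUT.ATTRS = FALSE)
    truth$true_pixel_area <- 0L
    for (i in seq_len(nr)) {
        for (j in seq_len(nc)) {
            r <- radius[i, j]
            if (r <= 0) next
            cy <- row_centers[i]; cx <- col_centers[j]
            ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
            xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
            d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
            inside <- d2 <= r^2
            img[ys, xs][inside] <- fg + dome * (1 - d2[inside] / r^2)
            truth$true_pixel_area[truth$row == i - 1L & truth$col == j - 1L] <-
                sum(inside)
        }
    }
    if (pixel_noise > 0)
        img <- img + matrix(stats::rnorm(H * W, 0, pixel_noise), H, W)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, truth = truth, row_centers = row_centers,
         col_centers = col_centers, pitch = pitch)
}

#' Render a simulated growth table into a plate-image time series
#'
#' For every (medium, dose) combination present in the growth table, lays
#' strains out on the requested plate format ([plate_map()]), converts
#' growth areas to rendered pixel areas (the carrying capacity maps to the
#' largest disk that fits the grid pitch), renders one 16-bit grayscale
#' TIFF per timepoint, and writes the plate map and a per-colony
#' ground-truth table (TSV) plus a JSON run manifest.
#'
#' @param growth a [simulate_growth()] table.
#' @param config the [sim_config()] used to generate it.
#' @param dir output directory (created if needed).
#' @param format plate format, 384 or 1536.
#' @param pitch grid pitch in pixels.
#' @param ... passed to [render_plate_image()].
#' @return invisibly, a list with `map`, `truth` (both data.frames), and
#'   `files` (paths of written images).
#' @export
render_plate_series <- function(growth, config, dir, format = 384L,
                                pitch = 20L, ...) {
    stopifnot(is.data.frame(growth))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    layout <- plate_layout(format)
    strains <- setdiff(unique(growth$strain_id), "WT_SPIKE")
    n_rep <- max(growth$replicate)
    map <- plate_map(strains, layout, n_replicates = n_rep)
    area_scale <- pi * (0.4 * pitch)^2 / config$carrying_capacity

    combos <- unique(growth[, c("medium", "dose_nM")])
    files <- character(0)
    truth_all <- list()
    plate_i <- 0L
    for (k in seq_len(nrow(combos))) {
        med <- combos$medium[k]; dose <- combos$dose_nM[k]
        sub <- growth[growth$medium == med & growth$dose_nM == dose, ]
        for (a in sort(unique(map$array))) {
            map_a <- map[map$array == a, ]
            plate_i <- plate_i + 1L
            plate_id <- sprintf("P%03d_%s_d%g_a%d", plate_i, med, dose, a)
            for (tp in sort(unique(sub$time_h))) {
                at_t <- sub[sub$time_h == tp, ]
                # border reference colonies reuse the wild-type
                # replicate-1 curve
                key <- ifelse(map_a$replicate == 0L,
                              paste(map_a$strain_id, 1L),
                              paste(map_a$strain_id, map_a$replicate))
                idx <- match(key, paste(at_t$strain_id, at_t$replicate))
                if (anyNA(idx))
                    stop("growth table lacks entries for mapped strains")
                areas <- matrix(0, layout$n_rows, layout$n_cols)
                areas[cbind(map_a$row + 1L, map_a$col + 1L)] <-
                    at_t$area[idx] * area_scale
                set.seed(stage_seed(config$seed,
                                    paste0("render_", plate_id, "_", tp)))
                rp <- render_plate_image(areas, pitch = pitch, ...)
                f <- file.path(dir, sprintf("%s_t%05.1f.tif", plate_id, tp))
                tiff::writeTIFF(rp$image, f, bits.per.sample = 16L,
                                compression = "none")
                files <- c(files, f)
                tr <- rp$truth
                tr$plate_id <- plate_id; tr$medium <- med
                tr$dose_nM <- dose; tr$time_h <- tp
                tr <- merge(tr, map_a, by = c("row", "col"), all.x = TRUE)
                truth_all[[length(truth_all) + 1L]] <- tr
            }
        }
    }
    truth <- do.call(rbind, truth_all)
    truth <- truth[order(truth$plate_id, truth$time_h, truth$row, truth$col), ]
    write_tsv(map, file.path(dir, "plate_map.tsv"))
    write_tsv(truth, file.path(dir, "render_truth.tsv"))
    jsonlite::write_json(
        list(seed = config$seed, format = format, pitch = pitch,
             n_plates = plate_i, n_images = length(files),
             area_scale = area_scale),
        file.path(dir, "render_manifest.json"), auto_unbox = TRUE, digits = NA)
    invisible(list(map = map, truth = truth, files = files))
}
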